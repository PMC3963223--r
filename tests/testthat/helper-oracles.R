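# Independent oracles and small generators used across the suite.
# These deliberately avoid the package's Dijkstra machinery.

# Floyd-Warshall all-pairs distances from a ppi_network's edge list.
fw_distances <- function(network) {
  n <- length(network$nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (e in seq_along(network$from)) {
    i <- network$from[e]
    j <- network$to[e]
    w <- network$weight[e]
    D[i, j] <- min(D[i, j], w)
    D[j, i] <- D[i, j]
  }
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  dimnames(D) <- list(network$nodes, network$nodes)
  D
}

# adjacency list of (neighbour index, weight) pairs
adj_list <- function(network) {
  n <- length(network$nodes)
  adj <- replicate(n, list(nbr = integer(0), wt = integer(0)),
                   simplify = FALSE)
  for (e in seq_along(network$from)) {
    i <- network$from[e]; j <- network$to[e]; w <- network$weight[e]
    adj[[i]]$nbr <- c(adj[[i]]$nbr, j); adj[[i]]$wt <- c(adj[[i]]$wt, w)
    adj[[j]]$nbr <- c(adj[[j]]$nbr, i); adj[[j]]$wt <- c(adj[[j]]$wt, w)
  }
  adj
}

# exhaustive enumeration of simple paths: minimum total weight s -> t
enum_min_distance <- function(network, s, t) {
  adj <- adj_list(network)
  si <- match(s, network$nodes)
  ti <- match(t, network$nodes)
  best <- Inf
  visited <- rep(FALSE, length(network$nodes))
  rec <- function(v, w) {
    if (v == ti) {
      best <<- min(best, w)
      return(invisible())
    }
    visited[v] <<- TRUE
    a <- adj[[v]]
    for (m in seq_along(a$nbr)) {
      u <- a$nbr[m]
      if (!visited[u] && w + a$wt[m] <= best) rec(u, w + a$wt[m])
    }
    visited[v] <<- FALSE
  }
  rec(si, 0)
  best
}

# random scored network over n nodes; includes score-1000 (weight-0) edges
# when score_lo permits
random_test_network <- function(n, p, seed, score_lo = 1L, score_hi = 1000L) {
  set.seed(seed)
  pairs <- which(upper.tri(diag(n)), arr.ind = TRUE)
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) < 1L) return(NULL)
  ids <- sprintf("V%03d", seq_len(n))
  build_network(data.frame(
    protein_a = ids[pairs[, 1L]],
    protein_b = ids[pairs[, 2L]],
    score = sample(seq.int(score_lo, score_hi), nrow(pairs), replace = TRUE),
    stringsAsFactors = FALSE))
}

# structural validity of a path_record against its network
expect_valid_path <- function(p, network) {
  expect_s3_class(p, "path_record")
  expect_identical(p$nodes[1L], p$source)
  expect_identical(p$nodes[length(p$nodes)], p$target)
  expect_false(anyDuplicated(p$nodes) > 0L)
  idx <- match(p$nodes, network$nodes)
  expect_false(anyNA(idx))
  ekey <- paste(pmin(network$from, network$to),
                pmax(network$from, network$to))
  w <- 0
  for (m in seq_len(length(idx) - 1L)) {
    k <- paste(min(idx[m], idx[m + 1L]), max(idx[m], idx[m + 1L]))
    pos <- match(k, ekey)
    expect_false(is.na(pos),
                 info = "consecutive path nodes must be adjacent")
    w <- w + network$weight[pos]
  }
  expect_equal(p$total_weight, w)
}
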