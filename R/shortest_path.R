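# ---- internal engine ---------------------------------------------------
# CSR adjacency for the Rcpp Dijkstra kernel; built once per network and
# reused across the many single-source queries of the permutation stage.
sp_engine <- function(network) {
  n <- length(network$nodes)
  from <- c(network$from, network$to)
  to <- c(network$to, network$from)
  w <- c(network$weight, network$weight)
  o <- order(from, to)
  from <- from[o]; to <- to[o]; w <- w[o]
  deg <- tabulate(from, nbins = n)
  list(n = n, nodes = network$nodes,
       indptr = c(0L, cumsum(deg)),
       nbr = to - 1L, wt = w)
}

# walk the predecessor tree back from dst to src (indices)
walk_pred <- function(pred, src, dst) {
  path <- dst
  v <- dst
  while (v != src) {
    v <- pred[v]
    if (v == 0L) return(NULL)
    path <- c(v, path)
  }
  path
}

# one deterministic shortest path per connected unordered pair of sidx
# (sorted integer node indices). Returns index paths plus bookkeeping.
pair_paths_idx <- function(eng, sidx) {
  k <- length(sidx)
  paths <- vector("list", (k * (k - 1L)) %/% 2L)
  tw <- numeric(length(paths))
  m <- 0L
  skipped <- 0L
  for (i in seq_len(k - 1L)) {
    res <- .sp_sssp(eng$n, eng$indptr, eng$nbr, eng$wt, sidx[i])
    for (j in seq.int(i + 1L, k)) {
      t <- sidx[j]
      if (is.infinite(res$dist[t])) {
        skipped <- skipped + 1L
      } else {
        m <- m + 1L
        paths[[m]] <- walk_pred(res$pred, sidx[i], t)
        tw[m] <- res$dist[t]
      }
    }
  }
  list(paths = paths[seq_len(m)], total_weight = tw[seq_len(m)],
       pairs_total = (k * (k - 1L)) %/% 2L,
       pairs_connected = m, pairs_skipped = skipped)
}

# betweenness counts (length-n integer vector) from index paths; nodes in
# `exclude_idx` (the seed role) are never counted as inner nodes.
counts_from_paths_idx <- function(eng, pp, exclude_idx) {
  inner <- unlist(lapply(pp$paths, function(p) {
    if (length(p) > 2L) p[-c(1L, length(p))] else integer(0)
  }), use.names = FALSE)
  counts <- tabulate(inner, nbins = eng$n)
  counts[exclude_idx] <- 0L
  counts
}

# all-shortest-paths variant: a node is credited once per seed pair if it is
# interior to ANY minimum-weight path of that pair (membership test
# d_s(v) + d_t(v) == d(s, t)).
asp_counts_idx <- function(eng, sidx) {
  k <- length(sidx)
  dmat <- matrix(0, nrow = k, ncol = eng$n)
  for (i in seq_len(k)) {
    dmat[i, ] <- .sp_sssp(eng$n, eng$indptr, eng$nbr, eng$wt, sidx[i])$dist
  }
  counts <- integer(eng$n)
  skipped <- 0L
  connected <- 0L
  for (i in seq_len(k - 1L)) {
    for (j in seq.int(i + 1L, k)) {
      D <- dmat[i, sidx[j]]
      if (is.infinite(D)) { skipped <- skipped + 1L; next }
      connected <- connected + 1L
      on <- which(dmat[i, ] + dmat[j, ] == D)
      counts[on] <- counts[on] + 1L
    }
  }
  counts[sidx] <- 0L
  list(counts = counts, pairs_total = (k * (k - 1L)) %/% 2L,
       pairs_connected = connected, pairs_skipped = skipped)
}

counts_to_table <- function(eng, counts, pairs_total, pairs_connected) {
  pos <- which(counts > 0L)
  df <- data.frame(gene = eng$nodes[pos], betweenness = counts[pos],
                   stringsAsFactors = FALSE)
  o <- order(-df$betweenness, df$gene, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, seed_pairs_total = pairs_total,
            seed_pairs_connected = pairs_connected,
            class = c("betweenness_table", "data.frame"))
}

# ---- public operations -------------------------------------------------

#' Deterministic Dijkstra shortest path between two nodes
#'
#' Computes one minimum-weight path under the `1000 - score` edge weights.
#' Ties among equal-weight paths are broken deterministically: fewest edges
#' first, then smallest node id at each predecessor choice, so repeated runs
#' (and permuted input files) yield the same path. Weight-0 edges
#' (score 1000) are handled exactly.
#'
#' @param network A `ppi_network`.
#' @param source,target Distinct node identifiers present in the network.
#' @return A `path_record` (list with `source`, `target`, `nodes`,
#'   `total_weight`), or `NULL` when `target` is unreachable.
#' @examples
#' net <- build_network(data.frame(protein_a = c("A", "B"),
#'                                 protein_b = c("B", "C"),
#'                                 score = c(990L, 990L)))
#' dijkstra_path(net, "A", "C")$nodes # "A" "B" "C"
#' @export
dijkstra_path <- function(network, source, target) {
  if (identical(source, target)) stop("source and target must differ")
  s <- match(source, network$nodes)
  t <- match(target, network$nodes)
  if (is.na(s) || is.na(t)) stop("source and target must be network nodes")
  eng <- sp_engine(network)
  res <- .sp_sssp(eng$n, eng$indptr, eng$nbr, eng$wt, s)
  if (is.infinite(res$dist[t])) return(NULL)
  idx <- walk_pred(res$pred, s, t)
  structure(list(source = source, target = target,
                 nodes = network$nodes[idx],
                 total_weight = res$dist[t]),
            class = "path_record")
}

#' @export
print.path_record <- function(x, ...) {
  cat("path_record: ", paste(x$nodes, collapse = " - "),
      "  (weight ", x$total_weight, ")\n", sep = "")
  invisible(x)
}

#' Shortest paths between all pairs of mapped seed genes
#'
#' Runs the deterministic Dijkstra once per unordered pair of mapped seeds
#' (`C(k, 2)` queries). Unreachable pairs are skipped and tallied.
#'
#' @param network A `ppi_network`.
#' @param seeds A `seed_gene_set` (or character vector of node ids).
#' @return List of `path_record`s with attributes `pairs_total`,
#'   `pairs_connected`, `pairs_skipped`.
#' @export
seed_pair_paths <- function(network, seeds) {
  seeds <- as_seed_set(seeds, network)
  if (length(seeds$mapped) < 2L) stop("need at least 2 mapped seed genes")
  sidx <- sort(match(seeds$mapped, network$nodes))
  eng <- sp_engine(network)
  pp <- pair_paths_idx(eng, sidx)
  out <- vector("list", pp$pairs_connected)
  for (m in seq_along(out)) {
    idx <- pp$paths[[m]]
    out[[m]] <- structure(list(source = eng$nodes[idx[1L]],
                               target = eng$nodes[idx[length(idx)]],
                               nodes = eng$nodes[idx],
                               total_weight = pp$total_weight[m]),
                          class = "path_record")
  }
  attr(out, "pairs_total") <- pp$pairs_total
  attr(out, "pairs_connected") <- pp$pairs_connected
  attr(out, "pairs_skipped") <- pp$pairs_skipped
  out
}

#' Inner-node path betweenness
#'
#' Counts, for every non-seed node, the number of seed-pair shortest paths
#' on which it occurs as an inner node (a node other than the two
#' endpoints). Seed genes are never counted, even when they sit in the
#' interior of another pair's path: candidates must be novel.
#'
#' @param paths List of `path_record`s from [seed_pair_paths()].
#' @param seeds The `seed_gene_set` (or character vector) whose members are
#'   excluded from counting.
#' @return A `betweenness_table`: `data.frame(gene, betweenness)` restricted
#'   to counts > 0, sorted by descending count then gene id, with attributes
#'   `seed_pairs_total` and `seed_pairs_connected`.
#' @export
count_betweenness <- function(paths, seeds) {
  seed_ids <- if (inherits(seeds, "seed_gene_set")) seeds$mapped
              else as.character(seeds)
  inner <- unlist(lapply(paths, function(p) {
    n <- p$nodes
    if (length(n) > 2L) n[-c(1L, length(n))] else character(0)
  }), use.names = FALSE)
  inner <- inner[!(inner %in% seed_ids)]
  if (length(inner)) {
    tb <- table(inner)
    df <- data.frame(gene = names(tb), betweenness = as.integer(tb),
                     stringsAsFactors = FALSE)
  } else {
    df <- data.frame(gene = character(0), betweenness = integer(0),
                     stringsAsFactors = FALSE)
  }
  o <- order(-df$betweenness, df$gene, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            seed_pairs_total = attr(paths, "pairs_total"),
            seed_pairs_connected = attr(paths, "pairs_connected"),
            class = c("betweenness_table", "data.frame"))
}

#' Extract the shortest-path genes
#'
#' The shortest-path genes are the non-seed nodes with betweenness greater
#' than zero, ordered by descending betweenness with lexicographic (C
#' locale) tie-break on the gene id.
#'
#' @param table A `betweenness_table`.
#' @return The table restricted to counts > 0 in that order (a
#'   `data.frame(gene, betweenness)`).
#' @export
shortest_path_genes <- function(table) {
  df <- as.data.frame(table)[table$betweenness > 0L, , drop = FALSE]
  o <- order(-df$betweenness, df$gene, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Observed betweenness for a seed set, in one call
#'
#' Convenience wrapper: seed-pair shortest paths followed by inner-node
#' counting, with an optional all-shortest-paths mode in which a node is
#' credited once per pair if it is interior to any minimum-weight path of
#' that pair (the default counts the single deterministic path per pair).
#'
#' @param network A `ppi_network`.
#' @param seeds A `seed_gene_set` or character vector.
#' @param path_mode `"single"` (default) or `"all-shortest"`.
#' @return A `betweenness_table`.
#' @export
betweenness_table <- function(network, seeds,
                              path_mode = c("single", "all-shortest")) {
  path_mode <- match.arg(path_mode)
  seeds <- as_seed_set(seeds, network)
  if (length(seeds$mapped) < 2L) stop("need at least 2 mapped seed genes")
  sidx <- sort(match(seeds$mapped, network$nodes))
  eng <- sp_engine(network)
  if (path_mode == "single") {
    pp <- pair_paths_idx(eng, sidx)
    counts <- counts_from_paths_idx(eng, pp, sidx)
    counts_to_table(eng, counts, pp$pairs_total, pp$pairs_connected)
  } else {
    ac <- asp_counts_idx(eng, sidx)
    counts_to_table(eng, ac$counts, ac$pairs_total, ac$pairs_connected)
  }
}

#' Write a betweenness table as TSV
#'
#' `gene_id<TAB>betweenness`, descending by count.
#'
#' @param table A `betweenness_table` (or compatible data frame).
#' @param file Output path.
#' @export
write_betweenness <- function(table, file) {
  write.table(as.data.frame(table), file, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(file)
}

#' Write per-pair paths as TSV
#'
#' Columns `source target total_weight path` with the path comma-joined.
#'
#' @param paths List of `path_record`s.
#' @param file Output path.
#' @export
write_paths <- function(paths, file) {
  df <- data.frame(
    source = vapply(paths, `[[`, character(1L), "source"),
    target = vapply(paths, `[[`, character(1L), "target"),
    total_weight = vapply(paths, `[[`, numeric(1L), "total_weight"),
    path = vapply(paths, function(p) paste(p$nodes, collapse = ","),
                  character(1L)))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
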