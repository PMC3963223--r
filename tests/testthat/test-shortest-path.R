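test_that("unique and tied paths resolve as expected on tiny graphs", {
  fx <- fixture_networks()
  p <- dijkstra_path(fx$path$network, "A", "C")
  expect_identical(p$nodes, c("A", "B", "C"))
  expect_equal(p$total_weight, 20)
  expect_valid_path(p, fx$path$network)

  # triangle: A-B 5, B-C 5, A-C 20 -> two-hop route wins
  tri <- fx$triangle$network
  p2 <- dijkstra_path(tri, "A", "C")
  expect_identical(p2$nodes, c("A", "B", "C"))
  expect_equal(p2$total_weight, 10)
  expect_equal(p2$total_weight, enum_min_distance(tri, "A", "C"))

  expect_null(dijkstra_path(fx$disconnected$network, "A", "C"))
  expect_error(dijkstra_path(tri, "A", "A"), "differ")
})

test_that("distances match Floyd-Warshall on random graphs", {
  # includes weight-0 edges (score 1000) via the full score range
  for (seed in 1:12) {
    net <- random_test_network(25, 0.15, seed = seed)
    if (is.null(net)) next
    D <- fw_distances(net)
    eng <- seedpath:::sp_engine(net)
    for (s in seq_len(min(6L, length(net$nodes)))) {
      res <- seedpath:::.sp_sssp(eng$n, eng$indptr, eng$nbr, eng$wt, s)
      expect_equal(res$dist, unname(D[s, ]))
    }
  }
})

test_that("distances match exhaustive path enumeration on tiny graphs", {
  for (seed in 1:8) {
    net <- random_test_network(8, 0.35, seed = 100 + seed)
    if (is.null(net) || length(net$nodes) < 2L) next
    ids <- net$nodes
    for (s in ids[1L]) {
      for (t in ids[-1L]) {
        p <- dijkstra_path(net, s, t)
        d <- enum_min_distance(net, s, t)
        if (is.null(p)) {
          expect_true(is.infinite(d))
        } else {
          expect_equal(p$total_weight, d)
          expect_valid_path(p, net)
        }
      }
    }
  }
})

test_that("adding an edge never increases a distance", {
  net <- random_test_network(20, 0.12, seed = 5)
  D <- fw_distances(net)
  ids <- net$nodes
  set.seed(9)
  extra <- data.frame(protein_a = ids[1L], protein_b = ids[7L], score = 999L)
  df <- data.frame(protein_a = ids[net$from], protein_b = ids[net$to],
                   score = net$score)
  net2 <- suppressWarnings(build_network(rbind(df, extra)))
  D2 <- fw_distances(net2)
  eng <- seedpath:::sp_engine(net2)
  for (s in 1:5) {
    res <- seedpath:::.sp_sssp(eng$n, eng$indptr, eng$nbr, eng$wt, s)
    expect_true(all(res$dist <= D[s, match(net2$nodes, ids)] + 1e-9))
    expect_equal(res$dist, unname(D2[s, ]))
  }
})

test_that("seed-pair enumeration covers C(k,2) pairs and skips unreachable", {
  fx <- fixture_networks()
  paths <- seed_pair_paths(fx$path$network, c("A", "C"))
  expect_length(paths, 1L)
  expect_identical(paths[[1L]]$nodes, c("A", "B", "C"))

  # equilateral triangle: adjacent seeds, zero inner nodes everywhere
  tri <- build_network(data.frame(protein_a = c("A", "B", "A"),
                                  protein_b = c("B", "C", "C"),
                                  score = c(990L, 990L, 990L)))
  paths3 <- seed_pair_paths(tri, c("A", "B", "C"))
  expect_length(paths3, 3L)
  expect_true(all(lengths(lapply(paths3, `[[`, "nodes")) == 2L))
  expect_identical(attr(paths3, "pairs_total"), 3L)

  pd <- seed_pair_paths(fx$disconnected$network, c("A", "C"))
  expect_length(pd, 0L)
  expect_identical(attr(pd, "pairs_skipped"), 1L)

  expect_error(seed_pair_paths(fx$path$network, "A"), "at least 2")
})

test_that("betweenness counts inner nodes and excludes seed genes", {
  fx <- fixture_networks()
  tab <- count_betweenness(seed_pair_paths(fx$path$network, c("A", "C")),
                           c("A", "C"))
  expect_identical(tab$gene, "B")
  expect_identical(tab$betweenness, 1L)

  # two given paths sharing inner node B accumulate a count of 2
  mkpath <- function(nodes) structure(list(source = nodes[1L],
                                           target = nodes[length(nodes)],
                                           nodes = nodes, total_weight = 0),
                                      class = "path_record")
  tab2 <- count_betweenness(list(mkpath(c("A", "B", "C")),
                                 mkpath(c("A", "B", "D"))),
                            c("A", "C", "D"))
  expect_identical(tab2$gene, "B")
  expect_identical(tab2$betweenness, 2L)
  # on the full star all three pairs route through B
  star <- build_network(data.frame(protein_a = c("A", "B", "B"),
                                   protein_b = c("B", "C", "D"),
                                   score = c(950L, 950L, 950L)))
  tab2b <- count_betweenness(seed_pair_paths(star, c("A", "C", "D")),
                             c("A", "C", "D"))
  expect_identical(tab2b$betweenness, 3L)

  # a seed sitting inside another pair's path is never counted
  chain <- build_network(data.frame(protein_a = c("A", "S"),
                                    protein_b = c("S", "C"),
                                    score = c(950L, 950L)))
  tab3 <- count_betweenness(seed_pair_paths(chain, c("A", "S", "C")),
                            c("A", "S", "C"))
  expect_identical(nrow(tab3), 0L)
})

test_that("planted hub accrues exactly one count per seed pair", {
  fx <- fixture_networks()
  hub <- fx$planted_hub
  tab <- betweenness_table(hub$network, hub$seeds)
  expect_identical(tab$gene, "H")
  expect_identical(tab$betweenness, 6L) # C(4,2)
  expect_identical(attr(tab, "seed_pairs_connected"), 6L)
})

test_that("shortest-path genes are ordered by count with lexicographic ties", {
  tab <- structure(data.frame(gene = c("X", "B", "A"),
                              betweenness = c(1L, 1L, 2L)),
                   class = c("betweenness_table", "data.frame"))
  out <- shortest_path_genes(tab)
  expect_identical(out$gene, c("A", "B", "X"))
  expect_identical(out$betweenness, c(2L, 1L, 1L))
  empty <- structure(data.frame(gene = character(0),
                                betweenness = integer(0)),
                     class = c("betweenness_table", "data.frame"))
  expect_identical(nrow(shortest_path_genes(empty)), 0L)
})

test_that("two runs on the same inputs give identical betweenness tables", {
  net <- random_test_network(40, 0.1, seed = 21)
  seeds <- net$nodes[c(1, 5, 9, 13, 17)]
  t1 <- betweenness_table(net, seeds)
  t2 <- betweenness_table(net, seeds)
  expect_identical(t1, t2)
})

test_that("all-shortest mode credits every tied route, single mode one", {
  # diamond A-B-D and A-C-D with equal weights
  dia <- build_network(data.frame(protein_a = c("A", "B", "A", "C"),
                                  protein_b = c("B", "D", "C", "D"),
                                  score = c(900L, 900L, 900L, 900L)))
  single <- betweenness_table(dia, c("A", "D"), path_mode = "single")
  expect_identical(single$gene, "B") # smaller id preferred on the tie
  asp <- betweenness_table(dia, c("A", "D"), path_mode = "all-shortest")
  expect_identical(asp$gene, c("B", "C"))
  expect_identical(asp$betweenness, c(1L, 1L))
})
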