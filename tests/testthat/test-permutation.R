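test_that("null sets have the seed-set size and are reproducible", {
  net <- random_test_network(10, 0.4, seed = 3)
  seeds <- net$nodes[1:3]
  cfg <- permutation_config(5, 0.1, rng_seed = 99)
  sets <- sample_null_sets(net, seeds, cfg)
  expect_length(sets, 5L)
  expect_true(all(lengths(sets) == 3L))
  expect_true(all(vapply(sets, function(s) !anyDuplicated(s), logical(1))))
  expect_true(all(unlist(sets) %in% net$nodes))
  expect_identical(sets, sample_null_sets(net, seeds, cfg))

  # non-seed universe excludes the real seeds
  cfg2 <- permutation_config(20, 0.1, rng_seed = 7, null_universe = "non-seed")
  sets2 <- sample_null_sets(net, seeds, cfg2)
  expect_false(any(unlist(sets2) %in% seeds))
})

test_that("a universe of exactly seed-set size forces the whole universe", {
  net <- build_network(data.frame(protein_a = c("A", "B"),
                                  protein_b = c("B", "C"),
                                  score = c(900L, 900L)))
  cfg <- permutation_config(4, 0.1, rng_seed = 1)
  sets <- sample_null_sets(net, c("A", "B", "C"), cfg)
  expect_true(all(vapply(sets, function(s)
    setequal(s, c("A", "B", "C")), logical(1))))

  cfg2 <- permutation_config(2, 0.1, rng_seed = 1,
                             null_universe = "non-seed")
  expect_error(sample_null_sets(net, c("A", "B", "C"), cfg2), "smaller")
})

test_that("null betweenness reduces to the observed one on the real seeds", {
  net <- random_test_network(30, 0.15, seed = 8)
  seeds <- net$nodes[c(2, 6, 10, 14)]
  obs <- betweenness_table(net, seeds)
  nb <- null_betweenness(net, seeds, obs$gene)
  expect_identical(unname(nb), obs$betweenness)

  # mutually adjacent null set: no inner nodes anywhere
  tri <- build_network(data.frame(protein_a = c("A", "B", "A"),
                                  protein_b = c("B", "C", "C"),
                                  score = c(990L, 990L, 990L)))
  expect_identical(unname(null_betweenness(tri, c("A", "B", "C"), "A")), 0L)

  # path graph A-B-C-D-E with endpoints as the null set
  chain <- build_network(data.frame(protein_a = c("A", "B", "C", "D"),
                                    protein_b = c("B", "C", "D", "E"),
                                    score = rep(900L, 4)))
  nb2 <- null_betweenness(chain, c("A", "E"), c("B", "C", "D"))
  expect_identical(unname(nb2), c(1L, 1L, 1L))
})

test_that("the FDR is the strict exceedance fraction, recomputable", {
  obs <- structure(data.frame(gene = c("P", "Q"),
                              betweenness = c(5L, 454L)),
                   class = c("betweenness_table", "data.frame"))
  cfg <- permutation_config(1000, 0.1, rng_seed = 1)
  set.seed(31)
  nulls <- lapply(seq_len(1000), function(i) {
    c(P = sample(0:10, 1), Q = 0L)
  })
  res <- compute_fdr(obs, nulls, cfg)
  exceed <- sum(vapply(nulls, function(v) v[["P"]] > 5L, logical(1)))
  expect_equal(unname(res$fdr["P"]), exceed / 1000)
  expect_equal(unname(res$fdr["Q"]), 0) # nothing ever beats 454
  # recomputable from the stored null counts
  expect_equal(unname(rowMeans(res$null_counts > obs$betweenness)),
               unname(res$fdr))
})

test_that("a null count equal to the observed count contributes zero", {
  obs <- structure(data.frame(gene = "P", betweenness = 5L),
                   class = c("betweenness_table", "data.frame"))
  cfg <- permutation_config(4, 0.1, rng_seed = 1)
  nulls <- list(c(P = 5L), c(P = 5L), c(P = 6L), c(P = 0L))
  res <- compute_fdr(obs, nulls, cfg)
  expect_equal(unname(res$fdr["P"]), 0.25) # only the strict exceedance
})

test_that("an 83/1000 exceedance yields FDR 0.083", {
  obs <- structure(data.frame(gene = "PCNA_like", betweenness = 5L),
                   class = c("betweenness_table", "data.frame"))
  cfg <- permutation_config(1000, 0.1, rng_seed = 1)
  nulls <- c(rep(list(c(PCNA_like = 6L)), 83),
             rep(list(c(PCNA_like = 5L)), 917))
  res <- compute_fdr(obs, nulls, cfg)
  expect_equal(unname(res$fdr[1L]), 0.083)
})

test_that("FDR is non-increasing in the observed betweenness", {
  cfg <- permutation_config(200, 0.1, rng_seed = 1)
  set.seed(17)
  counts <- matrix(sample(0:20, 200, replace = TRUE), nrow = 1)
  fdrs <- vapply(0:20, function(b) {
    obs <- structure(data.frame(gene = "g", betweenness = b),
                     class = c("betweenness_table", "data.frame"))
    rownames(counts) <- "g"
    unname(compute_fdr(obs, counts, cfg)$fdr)
  }, numeric(1))
  expect_true(all(diff(fdrs) <= 0))
})

test_that("candidate filtering is inclusive at the threshold and ordered", {
  obs <- structure(data.frame(gene = c("A", "B", "C", "D"),
                              betweenness = c(100L, 200L, 50L, 70L)),
                   class = c("betweenness_table", "data.frame"))
  cfg <- permutation_config(100, 0.1, rng_seed = 1)
  res <- list(fdr = c(A = 0.02, B = 0.02, C = 0.10, D = 0.11))
  class(res) <- "permutation_result"
  out <- filter_candidates(res, obs, cfg)
  expect_identical(out$gene, c("B", "A", "C")) # boundary 0.10 kept, 0.11 out
  expect_identical(out$fdr, c(0.02, 0.02, 0.10))

  empty <- structure(list(fdr = setNames(numeric(0), character(0))),
                     class = "permutation_result")
  eobs <- structure(data.frame(gene = character(0),
                               betweenness = integer(0)),
                    class = c("betweenness_table", "data.frame"))
  expect_identical(nrow(filter_candidates(empty, eobs, cfg)), 0L)
})

test_that("the permutation stage is a pure function of its inputs", {
  sim <- generate_synthetic(synthetic_spec(n_nodes = 80, n_seeds = 6,
                                           n_connectors = 2, rng_seed = 12))
  cfg <- permutation_config(50, 0.1, rng_seed = 5)
  r1 <- permutation_test(sim$network, sim$seeds, cfg, quiet = TRUE)
  r2 <- permutation_test(sim$network, sim$seeds, cfg, quiet = TRUE)
  expect_identical(r1$observed, r2$observed)
  expect_identical(r1$result$null_counts, r2$result$null_counts)
  expect_identical(r1$candidates, r2$candidates)

  # and consistent with assembling the stage from its parts
  sets <- sample_null_sets(sim$network, sim$seeds, cfg)
  M <- vapply(sets, function(s)
    null_betweenness(sim$network, s, r1$observed$gene),
    integer(nrow(r1$observed)))
  expect_identical(unname(r1$result$null_counts), unname(M))
})

test_that("including the real set among the nulls keeps FDR below one", {
  net <- random_test_network(30, 0.15, seed = 8)
  seeds <- net$nodes[c(2, 6, 10, 14)]
  obs <- betweenness_table(net, seeds)
  if (nrow(obs)) {
    cfg <- permutation_config(3, 0.1, rng_seed = 1)
    nulls <- list(
      null_betweenness(net, seeds, obs$gene),              # identity: delta=0
      null_betweenness(net, net$nodes[c(1, 3, 5, 7)], obs$gene),
      null_betweenness(net, net$nodes[c(11, 13, 15, 17)], obs$gene))
    res <- compute_fdr(obs, nulls, cfg)
    expect_true(all(res$fdr < 1))
  }
})
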