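#' Permutation-test configuration
#'
#' Bundles the knobs of the permutation stage. Defaults follow the study
#' design this pipeline implements: 1000 random gene sets and an FDR cut of
#' 0.1 (inclusive).
#'
#' @param n_permutations Number of random seed sets (>= 1).
#' @param fdr_threshold Candidate cut-off in \[0, 1\]; genes with FDR no
#'   more than this value are retained by [filter_candidates()].
#' @param rng_seed Integer root seed; every random draw of the stage derives
#'   from it, so the whole stage is reproducible.
#' @param null_universe `"all"` samples random sets from all network nodes
#'   (the default reading); `"non-seed"` excludes the real seeds.
#' @return An object of class `permutation_config`.
#' @export
permutation_config <- function(n_permutations = 1000L, fdr_threshold = 0.1,
                               rng_seed = 1L,
                               null_universe = c("all", "non-seed")) {
  null_universe <- match.arg(null_universe)
  n_permutations <- as.integer(n_permutations)
  stopifnot(length(n_permutations) == 1L, n_permutations >= 1L,
            length(fdr_threshold) == 1L,
            fdr_threshold >= 0, fdr_threshold <= 1,
            length(rng_seed) == 1L, is.finite(rng_seed))
  structure(list(n_permutations = n_permutations,
                 fdr_threshold = fdr_threshold,
                 rng_seed = as.integer(rng_seed),
                 null_universe = null_universe),
            class = "permutation_config")
}

#' @export
print.permutation_config <- function(x, ...) {
  cat("permutation_config: ", x$n_permutations, " permutations, FDR <= ",
      x$fdr_threshold, ", universe = ", x$null_universe,
      ", rng_seed = ", x$rng_seed, "\n", sep = "")
  invisible(x)
}

# per-permutation seeds derived once from the root seed, so results do not
# depend on the order in which permutations are evaluated
derive_perm_seeds <- function(config) {
  with_seed(config$rng_seed,
            sample.int(.Machine$integer.max - 1L, config$n_permutations))
}

null_universe_ids <- function(network, seeds, config) {
  if (config$null_universe == "all") network$nodes
  else setdiff(network$nodes, seeds$mapped)
}

#' Sample random seed sets for the permutation null
#'
#' Draws `n_permutations` node sets, each of the same size as the mapped
#' seed set, uniformly without replacement within each set and independently
#' across sets. Fully reproducible from the config's `rng_seed`.
#'
#' @param network A `ppi_network`.
#' @param seeds A `seed_gene_set` (or character vector of node ids).
#' @param config A [permutation_config()].
#' @return List of `n_permutations` character vectors of node ids.
#' @export
sample_null_sets <- function(network, seeds, config) {
  seeds <- as_seed_set(seeds, network)
  universe <- null_universe_ids(network, seeds, config)
  k <- length(seeds$mapped)
  if (length(universe) < k) {
    stop("null universe (", length(universe),
         " nodes) smaller than the seed set (", k, ")")
  }
  perm_seeds <- derive_perm_seeds(config)
  lapply(perm_seeds, function(s) with_seed(s, sample(universe, k)))
}

#' Betweenness of selected genes under one null seed set
#'
#' Runs the seed-pair shortest-path machinery with `null_set` playing the
#' seed role (null-set members are excluded as countable inner nodes, the
#' same rule applied to real seeds) and returns the counts of the genes of
#' interest, zero when absent from every path interior.
#'
#' @param network A `ppi_network`.
#' @param null_set Character vector of node ids (>= 2).
#' @param genes_of_interest Character vector of gene ids to report.
#' @param path_mode `"single"` or `"all-shortest"`, as in
#'   [betweenness_table()].
#' @return Named integer vector over `genes_of_interest`.
#' @export
null_betweenness <- function(network, null_set, genes_of_interest,
                             path_mode = c("single", "all-shortest")) {
  path_mode <- match.arg(path_mode)
  tab <- betweenness_table(network, null_set, path_mode = path_mode)
  out <- setNames(integer(length(genes_of_interest)), genes_of_interest)
  hit <- match(genes_of_interest, tab$gene)
  out[!is.na(hit)] <- tab$betweenness[hit[!is.na(hit)]]
  out
}

#' Permutation FDR from observed and null betweenness
#'
#' For every observed shortest-path gene `p`,
#' `FDR(p) = #\{i : null_i(p) > observed(p)\} / n_permutations` --
#' the fraction of random seed sets under which the gene's betweenness
#' STRICTLY exceeds its observed value. A null count equal to the observed
#' count contributes nothing. No smoothing is applied, so FDR can be
#' exactly 0.
#'
#' @param observed A `betweenness_table` for the real seed set.
#' @param null_tables List of per-permutation named count vectors (genes
#'   absent from a table count as 0), or an equivalent genes x permutations
#'   matrix.
#' @param config The [permutation_config()] used to generate the nulls.
#' @return An object of class `permutation_result`: list with `fdr` (named
#'   numeric over the observed genes), `null_counts` (genes x permutations
#'   integer matrix) and `config`.
#' @export
compute_fdr <- function(observed, null_tables, config) {
  genes <- observed$gene
  obs <- observed$betweenness
  if (is.matrix(null_tables)) {
    if (ncol(null_tables) != config$n_permutations) {
      stop("null_tables has ", ncol(null_tables),
           " columns but config expects ", config$n_permutations)
    }
    M <- null_tables[match(genes, rownames(null_tables)), , drop = FALSE]
    M[is.na(M)] <- 0L
  } else {
    if (length(null_tables) != config$n_permutations) {
      stop("got ", length(null_tables), " null tables but config expects ",
           config$n_permutations)
    }
    M <- matrix(0L, nrow = length(genes), ncol = config$n_permutations)
    for (i in seq_along(null_tables)) {
      v <- null_tables[[i]]
      hit <- match(genes, names(v))
      col <- integer(length(genes))
      col[!is.na(hit)] <- as.integer(v[hit[!is.na(hit)]])
      M[, i] <- col
    }
  }
  dimnames(M) <- list(genes, NULL)
  fdr <- rowMeans(M > obs)
  structure(list(fdr = setNames(fdr, genes), null_counts = M,
                 config = config),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("permutation_result:", length(x$fdr), "genes,",
      x$config$n_permutations, "permutations\n")
  invisible(x)
}

#' Filter candidates by permutation FDR
#'
#' Retains genes whose FDR is no more than the configured threshold
#' (inclusive), sorted by ascending FDR, then descending betweenness, then
#' gene id.
#'
#' @param result A `permutation_result`.
#' @param observed The matching `betweenness_table`.
#' @param config A [permutation_config()] (supplies `fdr_threshold`).
#' @return `data.frame(gene, betweenness, fdr)` of retained candidates.
#' @export
filter_candidates <- function(result, observed, config) {
  df <- data.frame(gene = observed$gene,
                   betweenness = observed$betweenness,
                   fdr = unname(result$fdr[match(observed$gene,
                                                 names(result$fdr))]),
                   stringsAsFactors = FALSE)
  df <- df[!is.na(df$fdr) & df$fdr <= config$fdr_threshold, , drop = FALSE]
  o <- order(df$fdr, -df$betweenness, df$gene, method = "radix")
  df <- df[o, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Run the full permutation stage
#'
#' Observed betweenness, null sampling, per-permutation null betweenness,
#' FDR and candidate filtering in one pure function of
#' `(network, seeds, config)`.
#'
#' @inheritParams sample_null_sets
#' @param path_mode `"single"` or `"all-shortest"`.
#' @param quiet Suppress the progress message.
#' @return List with `observed` (betweenness table), `result`
#'   (`permutation_result`), `candidates` (filtered data frame), `seeds`
#'   and `config`.
#' @export
permutation_test <- function(network, seeds, config = permutation_config(),
                             path_mode = c("single", "all-shortest"),
                             quiet = FALSE) {
  path_mode <- match.arg(path_mode)
  seeds <- as_seed_set(seeds, network)
  if (length(seeds$mapped) < 2L) stop("need at least 2 mapped seed genes")
  eng <- sp_engine(network)
  sidx <- sort(match(seeds$mapped, network$nodes))

  observed <- if (path_mode == "single") {
    pp <- pair_paths_idx(eng, sidx)
    counts_to_table(eng, counts_from_paths_idx(eng, pp, sidx),
                    pp$pairs_total, pp$pairs_connected)
  } else {
    ac <- asp_counts_idx(eng, sidx)
    counts_to_table(eng, ac$counts, ac$pairs_total, ac$pairs_connected)
  }

  universe <- null_universe_ids(network, seeds, config)
  k <- length(sidx)
  if (length(universe) < k) {
    stop("null universe smaller than the seed set")
  }
  uidx <- match(universe, network$nodes)
  perm_seeds <- derive_perm_seeds(config)
  gidx <- match(observed$gene, eng$nodes)

  M <- matrix(0L, nrow = length(gidx), ncol = config$n_permutations,
              dimnames = list(observed$gene, NULL))
  sp_message("permutation_test: ", config$n_permutations, " permutations of ",
             k, " seeds over ", length(universe), " nodes", quiet = quiet)
  for (i in seq_len(config$n_permutations)) {
    nidx <- sort(with_seed(perm_seeds[i], sample(uidx, k)))
    counts <- if (path_mode == "single") {
      counts_from_paths_idx(eng, pair_paths_idx(eng, nidx), nidx)
    } else {
      asp_counts_idx(eng, nidx)$counts
    }
    M[, i] <- counts[gidx]
  }
  result <- compute_fdr(observed, M, config)
  list(observed = observed,
       result = result,
       candidates = filter_candidates(result, observed, config),
       seeds = seeds,
       config = config)
}

#' Write the per-gene FDR table as TSV
#'
#' `gene_id<TAB>betweenness<TAB>fdr` for every shortest-path gene, in the
#' observed table's order.
#'
#' @param result A `permutation_result`.
#' @param observed The matching `betweenness_table`.
#' @param file Output path.
#' @export
write_fdr_table <- function(result, observed, file) {
  df <- data.frame(gene = observed$gene,
                   betweenness = observed$betweenness,
                   fdr = unname(result$fdr[match(observed$gene,
                                                 names(result$fdr))]))
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
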