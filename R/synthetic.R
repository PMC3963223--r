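#' Specification for a synthetic benchmark network
#'
#' Describes a random scored interaction network with a known seed-gene set
#' and, for the `planted_connector` topology, ground-truth connector nodes
#' constructed to lie on the unique minimum-weight route of many seed pairs.
#'
#' Planted construction ("spoke" design): seeds are partitioned among
#' connector hubs and attached to their hub by high-score edges
#' (`score_planted`, default 900--1000, weights 0--100); consecutive hubs
#' are chained by score-1000 edges (weight 0); all remaining connectivity
#' is an Erdos-Renyi background over the non-connector nodes with scores in
#' `score_background` (default 151--700, weights >= 300). Any route between
#' two seeds through their hubs therefore weighs at most 200, while any
#' alternative uses at least one background edge of weight >= 300 -- so the
#' planted route is strictly shortest and unique, independent of the
#' Dijkstra tie-break. Degree-matched decoy nodes receive extra background
#' edges until they match their paired connector's degree, giving a fair
#' negative control for calibration.
#'
#' @param n_nodes Total node count (> n_seeds + n_connectors + n_decoys).
#' @param topology `"planted_connector"`, `"erdos_renyi"` or
#'   `"barabasi_albert"`.
#' @param n_seeds Number of seed genes (>= 2; for the planted topology at
#'   least `2 * n_connectors` so every hub serves >= 1 seed pair).
#' @param n_connectors Planted connector hubs (planted topology only).
#' @param n_decoys Degree-matched decoy nodes (defaults to `n_connectors`).
#' @param p_edge Background/ER edge probability.
#' @param pa_m Edges per step for the Barabasi-Albert topology.
#' @param score_background,score_planted Integer score bands (inclusive).
#'   Non-planted topologies draw scores from
#'   `score_background[1]..score_planted[2]`.
#' @param rng_seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 300L,
                           topology = c("planted_connector", "erdos_renyi",
                                        "barabasi_albert"),
                           n_seeds = 12L, n_connectors = 3L,
                           n_decoys = n_connectors,
                           p_edge = 0.05, pa_m = 3L,
                           score_background = c(151L, 700L),
                           score_planted = c(900L, 1000L),
                           rng_seed = 1L) {
  topology <- match.arg(topology)
  n_nodes <- as.integer(n_nodes)
  n_seeds <- as.integer(n_seeds)
  n_connectors <- if (topology == "planted_connector")
    as.integer(n_connectors) else 0L
  n_decoys <- if (topology == "planted_connector") as.integer(n_decoys) else 0L
  stopifnot(n_seeds >= 2L, n_connectors >= 0L, n_decoys >= 0L,
            n_nodes > n_seeds + n_connectors + n_decoys,
            p_edge >= 0, p_edge <= 1,
            score_background[1L] > 150L,
            score_background[2L] < score_planted[1L],
            score_planted[2L] <= 1000L)
  if (topology == "planted_connector") {
    if (n_connectors < 1L) stop("planted_connector topology needs >= 1 connector")
    if (n_seeds < 2L * n_connectors) {
      stop("infeasible spec: need n_seeds >= 2 * n_connectors so every ",
           "connector serves at least one seed pair")
    }
  }
  structure(list(n_nodes = n_nodes, topology = topology, n_seeds = n_seeds,
                 n_connectors = n_connectors, n_decoys = n_decoys,
                 p_edge = p_edge, pa_m = as.integer(pa_m),
                 score_background = as.integer(score_background),
                 score_planted = as.integer(score_planted),
                 rng_seed = as.integer(rng_seed)),
            class = "synthetic_spec")
}

#' Draw STRING-like integer scores for a role
#'
#' Planted-role scores are drawn from `score_planted` and strictly exceed
#' every background score (`score_background`), which is what makes planted
#' routes strictly shortest.
#'
#' @param spec A [synthetic_spec()].
#' @param role `"planted"` or `"background"`.
#' @param n Number of draws.
#' @return Integer vector of scores in (0, 1000].
#' @export
score_sampler <- function(spec, role = c("planted", "background"), n = 1L) {
  role <- match.arg(role)
  band <- if (role == "planted") spec$score_planted else spec$score_background
  sample(seq.int(band[1L], band[2L]), n, replace = TRUE)
}

#' Generate a synthetic network, seed list and ground truth
#'
#' Emits exactly the artifacts the I/O layer consumes: an interaction table
#' (`protein_a`, `protein_b`, `score`), the built `ppi_network`, the seed
#' id list, and a `truth` list with `seeds`, `connectors` and `decoys`.
#' Generation is fully reproducible from `spec$rng_seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `edges` (data.frame), `network` (`ppi_network`),
#'   `seeds` (character) and `truth` (list of disjoint id sets).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$rng_seed, {
    nodes <- sprintf("N%05d", seq_len(spec$n_nodes))
    if (spec$topology == "planted_connector") {
      perm <- sample(nodes)
      seeds <- perm[seq_len(spec$n_seeds)]
      connectors <- perm[spec$n_seeds + seq_len(spec$n_connectors)]
      decoys <- if (spec$n_decoys > 0L) {
        perm[spec$n_seeds + spec$n_connectors + seq_len(spec$n_decoys)]
      } else character(0)

      # seeds -> own hub, round-robin so group sizes differ by at most 1
      hub_of <- rep(seq_len(spec$n_connectors), length.out = spec$n_seeds)
      ea <- connectors[hub_of]
      eb <- seeds
      es <- score_sampler(spec, "planted", spec$n_seeds)
      # hub chain, weight-0 edges
      if (spec$n_connectors > 1L) {
        ea <- c(ea, connectors[-spec$n_connectors])
        eb <- c(eb, connectors[-1L])
        es <- c(es, rep(1000L, spec$n_connectors - 1L))
      }
      # Erdos-Renyi background over nodes that are neither connectors nor
      # decoys (decoys get their edges below, so their degree is controlled)
      bg_nodes <- setdiff(nodes, c(connectors, decoys))
      g <- igraph::sample_gnp(length(bg_nodes), spec$p_edge)
      el <- igraph::as_edgelist(g, names = FALSE)
      if (nrow(el)) {
        ea <- c(ea, bg_nodes[el[, 1L]])
        eb <- c(eb, bg_nodes[el[, 2L]])
        es <- c(es, score_sampler(spec, "background", nrow(el)))
      }
      # each decoy gets exactly as many background edges as its paired
      # connector has planted ones, so the pair is degree-matched
      if (spec$n_decoys > 0L) {
        deg <- table(factor(c(ea, eb), levels = nodes))
        for (d in seq_len(spec$n_decoys)) {
          cdeg <- as.integer(deg[connectors[(d - 1L) %% spec$n_connectors + 1L]])
          pick <- sample(bg_nodes, min(cdeg, length(bg_nodes)))
          ea <- c(ea, rep(decoys[d], length(pick)))
          eb <- c(eb, pick)
          es <- c(es, score_sampler(spec, "background", length(pick)))
        }
      }
      truth <- list(seeds = seeds, connectors = connectors, decoys = decoys)
    } else {
      g <- if (spec$topology == "erdos_renyi") {
        igraph::sample_gnp(spec$n_nodes, spec$p_edge)
      } else {
        igraph::sample_pa(spec$n_nodes, m = spec$pa_m, directed = FALSE)
      }
      g <- igraph::simplify(g)
      el <- igraph::as_edgelist(g, names = FALSE)
      ea <- nodes[el[, 1L]]
      eb <- nodes[el[, 2L]]
      es <- sample(seq.int(spec$score_background[1L], spec$score_planted[2L]),
                   nrow(el), replace = TRUE)
      seeds <- sample(nodes, spec$n_seeds)
      truth <- list(seeds = seeds, connectors = character(0),
                    decoys = character(0))
    }
    edges <- data.frame(protein_a = ea, protein_b = eb,
                        score = as.integer(es), stringsAsFactors = FALSE)
    list(edges = edges,
         network = build_network(edges),
         seeds = seeds,
         truth = truth)
  })
}

#' Write a seed gene list file
#'
#' @param seeds Character vector of seed ids.
#' @param file Output path.
#' @export
write_seed_list <- function(seeds, file) {
  writeLines(seeds, file)
  invisible(file)
}

#' Small in-memory fixture networks
#'
#' A standard set of tiny networks used in the test suite and documentation:
#' a 3-node path graph, a triangle with one costly direct edge, a
#' disconnected pair, and a planted-hub star whose hub lies on all C(4,2)=6
#' seed-pair paths.
#'
#' @return Named list; each element has `edges`, `network`, `seeds` and
#'   (for the hub) `hub`.
#' @export
fixture_networks <- function() {
  path_edges <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "C"),
                           score = c(990L, 990L), stringsAsFactors = FALSE)
  tri_edges <- data.frame(protein_a = c("A", "B", "A"),
                          protein_b = c("B", "C", "C"),
                          score = c(995L, 995L, 980L),
                          stringsAsFactors = FALSE)
  disc_edges <- data.frame(protein_a = c("A", "C"), protein_b = c("B", "D"),
                           score = c(900L, 900L), stringsAsFactors = FALSE)
  hub_edges <- data.frame(
    protein_a = c("H", "H", "H", "H", "S1", "B1"),
    protein_b = c("S1", "S2", "S3", "S4", "B1", "S2"),
    score = c(950L, 960L, 970L, 980L, 300L, 300L),
    stringsAsFactors = FALSE)
  list(
    path = list(edges = path_edges, network = build_network(path_edges),
                seeds = c("A", "C")),
    triangle = list(edges = tri_edges, network = build_network(tri_edges),
                    seeds = c("A", "B", "C")),
    disconnected = list(edges = disc_edges,
                        network = build_network(disc_edges),
                        seeds = c("A", "C")),
    planted_hub = list(edges = hub_edges, network = build_network(hub_edges),
                       seeds = c("S1", "S2", "S3", "S4"), hub = "H")
  )
}

#' Write the fixture suite to disk
#'
#' Writes each fixture's edge list (`<name>_edges.tsv`) and seed list
#' (`<name>_seeds.txt`) into `dir`, in the formats the I/O layer consumes.
#'
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_fixture_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fx <- fixture_networks()
  for (nm in names(fx)) {
    write_edge_list(fx[[nm]]$network, file.path(dir, paste0(nm, "_edges.tsv")))
    write_seed_list(fx[[nm]]$seeds, file.path(dir, paste0(nm, "_seeds.txt")))
  }
  invisible(dir)
}
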