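---
title: "Shortest-path prioritization of disease genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shortest-path prioritization of disease genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedpath)
```

# The problem and the model

Known disease genes ("seed genes") tend to interact with, and sit close to,
other genes involved in the same disease. `seedpath` operationalizes that
intuition on a scored protein--protein interaction (PPI) network of the
STRING kind, where each interaction between proteins $p_1$ and $p_2$
carries an integer confidence score $I(p_1, p_2) \in (0, 1000]$. The
network is weighted so that confident interactions are *short*:

$$ w(v_1, v_2) \;=\; 1000 - I(p_1, p_2). $$

An interaction with score 0 is a non-edge; a score of 1000 yields a
weight-0 edge, which the path machinery handles exactly. For every
unordered pair of mapped seed genes, one minimum-weight path is computed
with Dijkstra's algorithm ($\binom{k}{2}$ queries for $k$ seeds). The
**path betweenness** of a non-seed gene is the number of those seed-pair
paths on which it appears as an *inner* node (any node other than the two
endpoints). Genes with betweenness above zero are the *shortest-path
genes* -- the candidate set. Seed genes themselves are never counted,
even when they sit inside another pair's path: the goal is novel genes.

Note this statistic is deliberately not classic betweenness centrality:
it counts one path per seed pair rather than summing fractions over all
shortest paths between all node pairs.

## Permutation false discovery rate

High betweenness can be a property of network topology (hubs and
cut vertices collect paths from *any* gene set) rather than of disease
relatedness. To control this, the observed betweenness of each candidate
is compared with its betweenness under $N$ random seed sets
$G_1, \dots, G_N$ of the same size as the mapped seed set, drawn
uniformly without replacement from the network:

$$ \mathrm{FDR}(p) \;=\; \frac{1}{N} \sum_{i=1}^{N} \delta_i,
   \qquad
   \delta_i = \begin{cases}
     1 & \text{betweenness of } p \text{ on } G_i \text{ strictly exceeds
         its observed value} \\
     0 & \text{otherwise.}
   \end{cases} $$

Two conventions are taken verbatim from the procedure this package
implements and are enforced in tests: the inequality is **strict** (a tie
contributes 0), and the candidate filter keeps genes with FDR **no more
than** the threshold (inclusive, default 0.1). No pseudo-count smoothing
is applied, so an FDR of exactly 0 is possible and meaningful. The
default number of permutations is 1000; the test suite and the acceptance
benchmarks use 200 to keep runtimes short without changing the estimator.

Null-set members are excluded as countable inner nodes, exactly as real
seeds are, so null and observed statistics are computed by the same rule.

## Enrichment stage

Candidate lists can be tested for over-representation against a
user-supplied GMT catalog. The p-value is the one-sided Fisher exact test
(hypergeometric upper tail) on the 2x2 table of query/term membership; an
EASE-style variant (overlap decremented by one, more conservative) is
available behind the `test = "ease"` switch. Multiple-testing families are
per annotation category (e.g. one family per GO namespace), matching the
`List Total` / `Pop Total` semantics of the familiar functional-annotation
tools: those totals count genes annotated to *at least one* term of the
category. Bonferroni and Benjamini--Hochberg columns are standard
`p.adjust` calls; the additional column labelled `FDR` is
Benjamini--Yekutieli, chosen as a dependence-robust complement because the
upstream web tools never document their exact recipe for that column.
Annotation backgrounds are caller-supplied and versionable; no live
GO/KEGG service is queried.

# Determinism and numerical choices

* **Integer arithmetic throughout.** Scores are integers (fractional
  scores in exports are rounded half up, so `score + weight == 1000`
  exactly); path weights are exact integer sums; no floating-point
  tolerance is needed anywhere in the path engine.
* **Tie-breaking.** Equal-weight shortest paths are common in
  integer-scored networks. The Dijkstra kernel optimizes the pair
  (total weight, hop count) and, among predecessors achieving the optimal
  pair, keeps the smallest node id (C-locale order). Hop counts strictly
  decrease along predecessor chains, so the predecessor tree stays acyclic
  even across weight-0 edges, where a pure smallest-id rule could cycle.
  The result: one well-defined path per pair, invariant to edge input
  order, heap internals and platform locale. Any other implementation
  with a different (undocumented) tie rule can legitimately report
  different per-gene counts on tie-rich networks -- this is the main
  reason exact count-level agreement with other software is not expected.
* **Single path per pair** is the default, matching the procedure's
  singular phrasing and its small per-gene counts; `path_mode =
  "all-shortest"` instead credits a node once per pair when it is interior
  to *any* minimum-weight route (membership test
  $d_s(v) + d_t(v) = d(s,t)$), for sensitivity analysis of the tie rule.
* **Duplicate edges** collapse to the maximum score (strongest evidence,
  most conservative for connectivity), with a warning on conflicts.
* **Unreachable seed pairs** are skipped and tallied (`pairs_skipped`),
  identically in observed and null runs.
* **Reproducibility.** One root seed drives the permutation stage;
  per-permutation seeds are pre-derived from it, so results do not depend
  on evaluation order. Repeated runs with the same configuration produce
  byte-identical output tables.

## Open design points and how they were resolved

* The procedure never states whether random gene sets exclude the real
  seeds. The default universe is *all* network nodes (the plain reading);
  `null_universe = "non-seed"` implements the other reading.
* "Same size" of the random sets is interpreted as the number of *mapped*
  seeds, since only mapped seeds generate paths.
* Seeds absent from the network are dropped by name with a log message;
  an empty mapped set is a fatal configuration error rather than a silent
  no-op.
* Degree-matched null sets would change the method and are deliberately
  not implemented; uniform sampling is what the FDR definition above
  prescribes.

# The synthetic benchmark generator

Real PPI networks with curated seed lists are large, versioned downloads;
the generator instead produces desk-scale networks where ground truth is
known *by construction*, so every stage of the pipeline can be validated
end to end.

In the `planted_connector` topology, seeds are partitioned among
connector hubs and attached by high-score edges (900--1000, weights
0--100); consecutive hubs are chained with score-1000 edges; everything
else is an Erdos--Renyi background over non-connector, non-decoy nodes
with scores 151--700 (weights at least 300). Any seed-to-seed route
through the hubs therefore weighs at most 200, while any alternative
contains a background edge of weight at least 300 -- the planted route is
strictly shortest and **unique**, so recovery results do not depend on
the tie-breaking rule. Decoy nodes receive exactly as many background
edges as their paired connector has planted ones, giving degree-matched
negative controls. Plain `erdos_renyi` and `barabasi_albert` topologies
with uniform scores are available for null-model experiments.

What the generator does *not* emulate: the heavy-tailed degree
distribution, evidence-channel structure and identifier ecosystem of real
STRING networks. Passing the synthetic benchmarks therefore demonstrates
algorithmic correctness and statistical calibration, not biological
validity of any particular candidate list.

## Benchmark problem sizes

The shipped tests and the acceptance script use: 100 random oracle graphs
of up to 30 nodes (checked against Floyd--Warshall and, at up to 10
nodes, exhaustive path enumeration); 20 planted-connector replicates of
100--500 nodes, 12 seeds, 3 connectors, 200 permutations for recovery and
decoy separation; and a 50-replicate calibration experiment on a 100-node
sparse graph with 200 permutations each. These sizes were chosen so the
whole suite completes in about a minute while keeping the Monte Carlo
error of each property far below its assertion margin.

## A note on the calibration experiment

When the "real" seed set is itself drawn from the null universe,
exchangeability makes the FDR of a fixed gene approximately uniform on
$\{0, 1/N, \dots, 1\}$ -- *approximately*, because betweenness is an
integer count and the strict inequality discards ties. If the tracked
gene's null betweenness piles up on a few values (in sparse graphs the
atom at zero can exceed half the mass), the FDR concentrates near a
constant and a Kolmogorov--Smirnov test against the uniform rejects even
though the permutation logic is flawless. The calibration experiment
therefore fixes its network by design -- a 100-node Erdos--Renyi graph
(edge probability 0.04) whose highest-degree node spreads its null
betweenness over ~30 values with only ~5% zero mass -- and randomizes the
50 replicate seed-set draws and their 200 nulls. This is a premise of the
KS check, not a tuning of its outcome.

# Worked example

```{r example}
spec <- synthetic_spec(n_nodes = 150, n_seeds = 8, n_connectors = 2,
                       rng_seed = 7)
sim <- generate_synthetic(spec)
sim$network

pt <- permutation_test(sim$network, sim$seeds,
                       permutation_config(n_permutations = 200,
                                          fdr_threshold = 0.1,
                                          rng_seed = 42),
                       quiet = TRUE)
pt$candidates
sort(sim$truth$connectors)
```

The candidate table recovers the planted connectors at the top with FDRs
at or near zero, while decoys and background genes are absent.

# Scaling to a real STRING network

The same pipeline runs unchanged on a full STRING `protein.links`
export plus a curated seed list:

```sh
Rscript inst/cli/seedpath.R discover \
  --edges protein.links.v9.0.txt --seeds seed_genes.txt \
  --id-map symbols_to_ensp.tsv \
  --permutations 1000 --fdr 0.1 --rng-seed 1 --out-dir results/
```

Historical analyses of this design on STRING v9.0 with 150 curated
gastric-cancer seed genes report on the order of 4-5 hundred
shortest-path genes and ~150 candidates at FDR $\le$ 0.1, with per-gene
counts in the hundreds for hubs like PCNA or MYC. Exact per-gene
agreement with any such run depends on the STRING version, the seed-to-
identifier mapping, and the (usually undocumented) shortest-path
tie-breaking rule of the original implementation; the run manifest
records the mapping and pair bookkeeping needed to audit those
divergences. Memory and time scale with $k$ single-source Dijkstra runs
per permutation; the full-scale run is minutes-to-hours depending on
permutation count, and is not part of the shipped test suite.

# Known limitations

* One path per pair means counts on tie-rich networks depend on the
  documented tie rule; use `path_mode = "all-shortest"` to bound that
  sensitivity.
* The FDR is a per-gene exceedance fraction, not a familywise or
  Benjamini--Hochberg-adjusted quantity; with $N$ permutations its
  resolution is $1/N$.
* The enrichment stage tests annotation overlap only; it knows nothing of
  GO graph structure or pathway topology.
* Identifiers are opaque strings; cross-namespace mapping is the caller's
  responsibility via the two-column id map.
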