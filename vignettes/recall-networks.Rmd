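---
title: "Scoring encoding strategies in free recall: clustering indices and association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring encoding strategies in free recall}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recallnet)
```

## The problem

In a free-recall task a participant studies a list of N objects (here, the
default study configuration is N = 46, each object at a unique presentation
position) and later reproduces as many as possible, in any order. The order
of reproduction is not noise: participants who encode by rote tend to walk
the presentation order (serial clustering), while participants who encode by
meaning tend to chain semantically related objects (semantic clustering).
`recallnet` quantifies both tendencies per protocol and aggregates them into
group-level association networks whose structure can be compared between
groups.

## List-based clustering indices

The observed cluster count `LBC_obs` is the number of consecutive recall
pairs that are adjacent — in either direction — in a reference ordering. For
the serial index the reference is the presentation order; for the semantic
index it is a similarity-optimized reference list (below). Under a uniformly
random ordering of r correct recalls the expected count is

    LBC_exp = 2 (r - 1) / N,

clamped to 0 for r ≤ 1 (no transition exists). The index is
`LBC_obs - LBC_exp`: positive values mean clustering above chance. At full
recall of a 46-object list `LBC_exp = 2·45/46 = 1.96` and the maximal index
is `45 - 1.96 = 43.04`. The factor 2 is the chance expectation for
*bidirectional* adjacency, which is why the observed count must also score
both directions; `recallnet` verifies this calibration by simulation
(`mean serial count → 2(r-1)/N` under random orderings at r ∈ {5, 15, 30}).

Two scoring details are deliberate:

* **Chaining counts per transition.** A run of k serially adjacent recalls
  scores k − 1, because the increment rule applies to each consecutive pair.
* **Cleaning.** Perseverations are dropped keeping the first occurrence;
  intrusions (ids outside the inventory) are dropped with a warning in the
  default lenient mode and are an error in strict mode. The indices are
  defined on correct unique recalls only; since the original scoring
  procedure for intrusions is not documented anywhere we expose both modes
  rather than guessing a single intent.

## Semantic similarity and the reference list

Semantic adjacency needs a reference ordering of all N objects. Each object
maps to one leaf of a rooted concept taxonomy with corpus frequencies; the
information content of a concept is `IC(c) = -log(cumFreq(c)/cumFreq(root))`
(natural log — the base cancels in the ratio below) and Lin's similarity is

    sim(a, b) = 2 IC(lcs(a, b)) / (IC(a) + IC(b)),

with `lcs` the lowest common subsumer. The taxonomy interface is generic: a
single-parent tree, one leaf per object, no word-sense disambiguation. The
licensed lexical database used in the original analysis is not bundled; any
taxonomy in the documented JSON format can be supplied, and
`generate_taxonomy()` builds synthetic ones.

The semantic reference list is the ordering of all objects that maximizes
the summed similarity over consecutive pairs — an *open-path* (no return
edge) travelling-salesman problem on the complete similarity graph. Because
empirical recall starting points concentrate on the first and the last
presented object, `build_reference_lists()` runs the solver twice,
constrained to start at the position-1 and the position-N object; semantic
counts are scored against both and averaged. The averaging happens on the
observed count before subtracting the (identical) expectation, which is
mathematically the same as averaging two full indices.

The solver has two modes. Exact mode is a Held–Karp style dynamic program
over vertex subsets, used automatically up to 13 objects and certified in
tests against exhaustive enumeration up to N = 8; among co-optimal orderings
it returns the lexicographically smallest, so results are reproducible.
Heuristic mode (the N = 46 default) seeds with greedy nearest-neighbour from
the constrained start and improves with best-improvement 2-opt reversals; by
construction it never falls below the greedy baseline. Which solver produced
an ordering is recorded in the result.

## Association networks

For each group, every consecutive recall pair across all participants and
all five trials increments an undirected co-occurrence count; pooling across
trials follows the view that the network reflects consolidated organization
rather than any single trial. Expected counts come from a chi-square style
independence model on the symmetric co-occurrence table:
`expected(i,j) = m_i m_j / M`, with `m_i` object i's total transition
involvement and `M` the full-table sum. The edge weight is
`expected/observed` — the *association likelihood* — so small weights mark
pairs recalled together far more often than chance. The margin recipe is
isolated behind `expected_counts()` so alternatives can be swapped.

**Pruning.** Edges are visited from the least important (largest weight)
down; an edge is removed iff its weight is ≥ 1 (configurable) and removal
does not disconnect any vertex of the edge-bearing set from the rest.
Removing an edge with weight ≥ 1 removes a non-positive `-log(weight)`
contribution, so this weakest-first reverse-delete maximizes the retained
backbone's `Σ -log(weight)` among connectivity-preserving prunings — the
test suite certifies this against brute-force subset search on small graphs.
Connectivity is interpreted strictly: a pendant vertex may not be cut loose
even if its only edge is weak. Under the alternative reading (a vertex may
silently drop out of the graph), the optimization target becomes a
Steiner-tree problem for which weakest-first removal is *not* optimal — we
found concrete counterexamples during testing — so the strict reading is
both the faithful one ("removed as long as the graph remains connected") and
the one under which the stated optimality holds. The threshold-1 stopping
rule also explains why more than N − 1 edges survive: below-chance edges are
never candidates, so the backbone is not forced down to a tree. Retention is
reported against both the N(N−1)/2 pair universe and the observed edge set,
since either denominator is defensible.

Serial edges (presentation positions differing by exactly 1, no wraparound)
are flagged, and the serial fraction of the backbone distinguishes
rote-leaning from meaning-leaning groups.

## Small-world index

Graph metrics use unweighted degree, triangle-based local clustering
(defined 0 for degree < 2), and shortest paths; the descriptive table
reports likelihood-weighted path lengths, while the small-world index uses
the unweighted C and L of the standard formulation. `sample_sigma()` draws
G(n, m) Erdős–Rényi nulls with the observed vertex and edge counts,
redrawing until a null is connected and contains at least one triangle
(σ is undefined on a triangle-free null), and records the per-draw ratios
`σ_k = (C/C_k)/(L/L_k)`.

The *point estimate* is the ratio-of-means form
`σ = (C/mean(C_k)) / (L/mean(L_k))`, not the mean of the per-draw ratios.
The distinction matters in exactly the sparse regime these networks occupy
(n ≈ 46, m ≈ 60–100): the null clustering C_k is small and variable, so
`E[1/C_k] > 1/E[C_k]` by Jensen's inequality, and the mean of per-draw
ratios is biased upward by 30–50% — an ER graph scored against ER nulls
would *not* average to 1. The ratio-of-means estimator is exactly centred at
1 for matched ensembles, which the test suite verifies empirically; the
per-draw ratios are kept for dispersion (`sd_sigma`) and for the rank-based
group comparison of the two σ samples. Note that a *single* sparse ER
graph's own clustering has a coefficient of variation near 0.7, so σ for one
graph is informative only relative to its sampling spread.

Because small-worldness scales with network size, an observed σ can also be
judged against a calibration value for networks of that vertex count
(`sigma_fold_change()`); the calibration is user-supplied — for example from
a log-linear fit of σ on vertex count over reference graphs — and is
recorded alongside the result rather than assumed.

## Comparing two groups

Per-vertex metrics (degree, local clustering, weighted path length) are
paired on object id across the two group graphs and compared by Wilcoxon
signed rank; clustering indices per trial and the σ samples by Wilcoxon
rank-sum. Both use the normal approximation with tie correction, and effect
sizes are `z/√n`. Edge weights are compared unpaired by default because the
two backbones need not share edges (a paired-on-common-edges option exists).
Serial-edge proportions use Fisher's exact test with the φ coefficient
(computed without continuity correction).

The *intersection graph* keeps the unordered pairs present in both pruned
backbones. Its connected components with ≥ 2 vertices are the "cliques" —
shared association subgraphs, not complete subgraphs; visual inspection of
such structures shows chains, so completeness would be the wrong notion.
Cliques are numbered by decreasing size with lexicographic tie-break.
Coherence is tested by contrasting within-clique against between-clique edge
weights (one-way F); edges touching unassigned vertices are excluded by
default since their class is genuinely ambiguous (an option counts them as
between). Clique association with object attributes (context typicality,
spatial zone) uses Pearson chi-square without continuity correction, warning
on low expected cell counts, with an exact alternative.

The validity regression pools both backbones' edges and fits OLS of the
likelihood weight on the standardized Lin similarity of the endpoints, the
serial flag, and the source group, after excluding edges that touch the
primacy (first 7) or recency (last 3) positions — serial-position effects
produce strong associations for reasons unrelated to meaning. On study-like
data the similarity coefficient is negative: semantically closer pairs carry
smaller (stronger) likelihoods.

## The synthetic-study generator

`simulate_recall()` factorizes protocol generation into two stages so the
planted ground truth stays interpretable:

1. **Subset sampling.** Each object enters the recalled set with odds
   proportional to the trial's learning-curve value times a primacy/recency
   boost (first 7 / last 3 positions).
2. **Ordering.** A Markov walk over the recalled set: with probability
   `p_serial` move to an unrecalled object at presentation distance 1, else
   with probability `p_semantic` to the most similar unrecalled object, else
   uniformly at random; unavailable strategies fall through to random, which
   avoids dead ends without rejection sampling. With probability `p_serial`
   the walk starts at the earliest presented recalled object — a rote
   strategist walks the list from its beginning, and a pure serial profile
   at full recall then reproduces the presentation order exactly, hitting
   the maximal index of 43.04 — otherwise the start is boost-weighted
   random.

Semantic transitions use the *nearest* unrecalled neighbour so the semantic
signal is strong at moderate `p_semantic` (a similarity-proportional mode is
available). `make_paper_like_study()` bundles the study shape: 46 objects,
two groups of 18 (HOA, semantic-leaning: `p_semantic = 0.35`,
`p_serial = 0.08`) and 30 (YA, serial-leaning: `p_serial = 0.22`,
`p_semantic = 0.18`, stronger primacy boost 3.0), five trials with learning
curve `(0.33, 0.48, 0.60, 0.57, 0.55)` — rising over learning, dipping
slightly after the delay. These values are fixed design choices that encode
the qualitative group contrast and a plausible learning trajectory for a
46-item everyday-object list; they are not fitted to any dataset.

What passing tests on synthetic data do and do not show: the generator
reproduces the *structural* contrasts (group ordering of semantic and serial
indices, serial-edge enrichment under rote strategies, primacy effects) but
not the numerical scale of real recall data. Its random transition mass is
spread more evenly than human recall, so simulated co-occurrence tables are
denser and pruned backbones retain more edges than real group networks of
comparable size; intersection cliques are correspondingly coarser. Tests
that pass on this generator certify the pipeline's arithmetic and its
ability to recover planted effects, not distributional fidelity to human
protocols.

## Numerical choices and degenerate inputs

* Ties break lexicographically by object id everywhere (path solver, edge
  ordering in pruning, clique numbering), so identical inputs give identical
  outputs across platforms.
* `LBC_exp` clamps to 0 at r ≤ 1; r = 0 protocols are legal and score 0.
* A rank-sum/signed-rank variance of 0 (all values tied) returns z = 0,
  p = 1 rather than NaN.
* Concepts with zero cumulative frequency get infinite IC with a warning;
  similarity requires finite IC at both endpoints.
* Disconnected inputs error by default; pruning and metrics accept
  `per_component = TRUE` where a per-component analysis is meaningful.
* All stochastic steps take explicit integer seeds, which are recorded in
  the outputs (σ samples, ground truth, run manifest).

## Problem sizes in the test suite

The suite certifies exact components at full strength (enumeration up to
N = 8 for the path solver over 200 random instances; brute-force subset
search for pruning on graphs with up to 7 edges) and stochastic components
at sizes chosen for tight Monte-Carlo error at interactive runtimes: 10,000
random orderings per r for the chance calibration, 150 independent ER
observed graphs with 60-draw null ensembles for the σ centring check, 200
protocols per group for strategy recovery, and 500 constructed edges for the
regression recovery. These sizes give standard errors several times smaller
than the effects being verified.

## Known limitations

* Mixed-effects modelling of the index trajectories is out of scope; the
  tidy per-trial export (`export_tidy_tables()`) feeds any standard tool.
  Note that downstream transformation of the indices (log / square-root)
  requires an offset choice for non-positive values that is left to the
  modeller.
* The taxonomy is a tree; a DAG would need a max-IC-subsumer rule that is
  not implemented.
* The heuristic path solver guarantees only greedy-or-better, not global
  optimality, above the exact-mode limit.
* Directed or per-trial network variants are not provided; the group
  networks pool recall direction and trials by design.
* σ is estimated against connected ER nulls; lattice-referenced variants
  (ω, SWP) are not implemented.
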