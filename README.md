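# recallnet

Scoring of encoding strategies in free-recall protocols from list-learning
memory examinations, for researchers in memory and cognitive aging who
record *what order* participants reproduce studied objects in — not just how
many.

When a participant recalls a studied list of N objects, consecutive recalls
of objects that were *presented* consecutively indicate rote, order-based
encoding; consecutive recalls of objects that are *semantically close*
indicate meaning-based encoding. `recallnet` quantifies both per protocol,
and aggregates recall transitions into group-level association networks
whose shared and divergent structure can be tested.

## What it computes

**List-based clustering indices.** The observed count `LBC_obs` is the
number of consecutive recall pairs adjacent (either direction) in a
reference ordering — the presentation order for the *serial* index, a
similarity-optimized reference list for the *semantic* index. With r correct
recalls from N objects the chance expectation is

```
LBC_exp = 2 (r − 1) / N          (0 for r ≤ 1)
index   = LBC_obs − LBC_exp
```

At full recall of the default 46-object list, `LBC_exp = 2·45/46 = 1.96` and
the maximal index is `45 − 1.96 = 43.04`.

**Semantic reference list.** Objects map to leaves of a concept taxonomy;
pairwise similarity is Lin's information-content measure
`sim(a,b) = 2·IC(lcs(a,b)) / (IC(a)+IC(b))`. The reference list is the
ordering maximizing summed similarity along an open path — a
travelling-salesman problem solved exactly (subset dynamic programming) up
to 13 objects and by greedy + 2-opt above that, run twice with the start
constrained to the first- and last-presented object.

**Association networks.** Consecutive-recall co-occurrences pooled over a
group's participants and trials become an undirected graph; edge weights are
expected/observed frequency ratios under a chi-square style independence
model (small weight = association far above chance). Weakest-first pruning
under a connectivity constraint retains the most important backbone and
maximizes its summed −log(weight). Graph metrics, a small-world index σ
against connected Erdős–Rényi nulls, intersection "cliques" (connected
components shared by two group graphs), attribute chi-squares, a
primacy/recency probe, and a validity regression of edge likelihood on
semantic similarity complete the analysis.

**Synthetic studies.** A fully seeded generator produces inventories,
taxonomies and recall protocols from controllable mixtures of serial,
semantic and random transitions with primacy/recency biases and a per-trial
learning curve — ground truth for every pipeline stage.

## Worked example

```r
library(recallnet)

study <- make_paper_like_study(seed = 42)   # 18 HOA + 30 YA, 5 trials each
study$dataset
#> <study_dataset> 240 protocols, 46 objects, groups: HOA, YA

refs <- build_reference_lists(study$sim, study$inventory)
refs$first
#> <reference_list> 46 objects, total similarity 25.1511, start obj34 (heuristic)

records <- index_table(study$dataset, refs)
compare_groups(records, "semantic", trial = "sdfr")
#> <group_comparison> semantic index, trial 4
#>   HOA (n=18): median 3.58 IQR [2.66; 4.73]
#>   YA (n=30): median 1.04 IQR [0.087; 2.18]
#>   z = 3.59, effect size z/sqrt(n) = 0.518, p = 0.000332
```

The semantic-leaning HOA profile planted by the generator is recovered: its
semantic clustering index at short-delay free recall is about 2.5 units
above the YA group's, a rank-sum effect size of 0.52. The network side:

```r
gH <- association_graph(study$dataset, "HOA")
compute_metrics(gH)
#> <graph_metrics> 46 vertices, 380 edges
#>   mean degree 16.5, C 0.393, weighted L 0.744, median weight 0.653
#>   serial edges 35 (9.21%)

sample_sigma(gH, n_samples = 200, seed = 43)
#> <sigma_sample> n = 46, m = 380, 200 null graphs (seed 43)
#>   sigma 1.071 (per-draw sd 0.0277)
```

Each line is interpretable: 380 of the 1035 possible pairs survive pruning
(synthetic protocols are more weakly structured than human ones, so their
backbones are denser), 9.2% of retained edges connect consecutively
presented objects, and σ slightly above 1 says this dense simulated network
is only marginally more clustered-yet-short-pathed than a random graph of
the same size.

The full pipeline (simulate → indices → networks, all outputs as CSV /
GraphML / JSON with a run manifest) is available as three functions:

```r
cfg <- pipeline_config(outdir = "out", seed = 1)
run_simulate(cfg); run_indices(cfg); run_networks(cfg)
```

## Documentation

The methods vignette (`vignettes/recall-networks.Rmd`) explains the model
and its assumptions, every tunable parameter with its default and rationale,
what the synthetic generator does and does not emulate, the numerical
choices (tie-breaks, degenerate inputs, the small-world estimator), and
known limitations.
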