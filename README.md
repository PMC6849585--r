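# morphparsimony

Maximum-parsimony phylogenetics for morphological matrices that mix
unordered, ordered and **continuous** characters, built for the
fossil-heavy, homoplasy-ridden datasets typical of early placental mammal
(“condylarth”-grade) systematics — but applicable to any genus-level
morphological matrix.

## What it does

* **Range-normalisation weighting** — every character's full observed
  range costs one step: a continuous trait spanning `[x_min, x_max]` gets
  weight `1/(x_max − x_min)`, an ordered character spanning `r` unit steps
  gets `1/r` (a three-state morphocline is weighted 0.5), binary and
  unordered characters stay at 1. This makes continuous, ordered and
  binary evidence commensurable, and makes length differences between a
  continuous and a discretised analysis attributable to coding alone.
* **Exact mixed-kind scoring** — one generalised Sankoff dynamic
  programme (C++) scores all three kinds, including linear (Wagner)
  parsimony for continuous characters over their observed values (exact
  for L1 Steiner on trees), interval-coded polymorphic ordered terminals,
  and polytomies.
* **Scaffold-constrained search** — molecular-backbone constraints with
  “floater” taxa free to attach anywhere: seeded random-addition starts,
  SPR/TBR hill climbing, pooling of most-parsimonious and near-optimal
  trees, strict consensus, suboptimal-pool growth to a storage cap.
* **Support and tests** — relative Bremer support
  `100·(S − C)/max(S, C)` over suboptimal pools with rogue-taxon pruning;
  Templeton's (Wilcoxon signed-rank) test between topologies with exact
  small-sample p-values; ensemble CI/RI homoplasy indices; unambiguous
  synapomorphy lists from marginal MPR ancestral-state sets.
* **I/O** — TNT (`xread`, with continuous blocks and `ccode`) and NEXUS
  matrices, Newick trees; lossless round-trips.
* **Synthetic data** — a generator emulating the structure of such
  studies (mixed kinds, ~7% continuous characters, fossil-concentrated
  missing data, molecular scaffold with sequential outgroups) so the
  whole pipeline is testable end to end, plus a topology-recovery
  benchmark.
* **Pipeline driver** — `run_pipeline()` executes the full
  (data set × constraint level) grid — e.g. CU/CM/CF/CP × DU/DM/DF/DP —
  from one YAML config, writing ensembles, consensus trees, score,
  support and pairwise-Templeton tables plus a JSON manifest,
  byte-reproducibly.

## Worked example

Simulate an 8-taxon matrix of 55 mixed characters (30% missing cells) on
a known tree, weight it, and run a scaffold-constrained search that also
keeps trees within one step of the optimum:

```r
library(morphparsimony)

tt <- ape::read.tree(text =
  "(((A:0.5,B:0.5):1.5,(C:0.5,D:0.5):1.5):1.5,((E:0.5,F:0.5):1.5,(G:0.5,H:0.5):1.5):1.5);")
cfg <- sim_config(tt, n_unordered = 40, n_ordered = 10, n_continuous = 5,
                  n_states = 3, rate = 0.2, bm_sigma = 1,
                  missing_rate = 0.3, seed = 42)
sim <- simulate_matrix(cfg)
w   <- assign_range_weights(sim$matrix)
sim$matrix
#> morph_matrix: 8 taxa x 55 characters (40 unordered, 10 ordered, 5 continuous; 55 active)

scaffold <- make_scaffold(tt, c("A", "C", "E", "G"),
                          collapse_fraction = 0.25, seed = 42)
ens <- tbr_search(w$matrix, scaffold, n_starts = 3, seed = 42, epsilon = 1)
ens
#> tree_ensemble: 3 trees (1 MPTs at length 67.7462), epsilon 1
homoplasy_indices(mpt_trees(ens)[[1]], w$matrix)
#> score_report: length 67.7462, CI 0.7720, RI 0.7341
```

The fractional length (67.7462) is the signature of weighted continuous
characters; CI 0.77 says roughly a quarter of the weighted changes are
homoplastic. With only 55 characters the single MPT gets one clade wrong
— and the support measure knows it:

```r
sup <- relative_bremer(ens, strict_consensus(mpt_trees(ens)))
sup$table[order(-sup$table$support), ]
#>         clade S C support
#> 1         C|D 3 0     100
#> 2         G|H 3 0     100
#> 4     E|F|G|H 3 0     100
#> 5 C|D|E|F|G|H 3 0     100
#> 3       F|G|H 1 2     -50
```

Every true clade is displayed by all 3 pooled trees (support 100); the
erroneous grouping `(F,(G,H))` is contradicted by two of the three
near-optimal trees (support −50) and is collapsed in the annotated
consensus `sup$consensus`. At the benchmark's full 200 characters,
`recovery_benchmark()` recovers the true topology outright in ≥95% of
replicates.

A thin command-line front end over the same functions lives in
`inst/cli/morphparsimony.R` (subcommands `run`, `simulate`, `score`,
`search`, `templeton`), and `run_pipeline("run.yaml")` drives the whole
analysis grid.

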