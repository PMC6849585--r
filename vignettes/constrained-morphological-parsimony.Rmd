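---
title: "Constrained parsimony on mixed morphological characters: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constrained parsimony on mixed morphological characters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphparsimony)
```

## The problem this package addresses

Genus-level phylogenies of fossil-rich clades — the motivating case is the
archaic placental mammals of the Paleocene, the classic "condylarth"
problem — must be built almost entirely from morphology: teeth, crania and
postcrania scored across hundreds of taxa, most of them extinct and
incomplete. Three well-known difficulties dominate such analyses, and this
package implements one coherent workflow for all three:

1. **Mixed character kinds.** Some characters are qualitative and
   unordered, some form ordered morphoclines, and some are inherently
   continuous (ratios, angles, relative sizes). Treating continuous traits
   as such avoids arbitrary state boundaries, but raises the question of
   how much a continuous change should cost relative to a discrete one.
2. **Rampant homoplasy.** Adaptive convergence among ecologically similar
   lineages routinely overwhelms the phylogenetic signal at the deepest
   nodes; unconstrained morphological parsimony then contradicts
   relationships that molecular data establish beyond reasonable doubt.
3. **Fossils cannot be constrained, but living clades can.** The standard
   remedy is a molecular *scaffold*: the extant taxa are fixed to their
   molecularly supported relationships while every fossil "floater" is
   free to attach anywhere.

## Range-normalisation weighting

The weighting model makes all character kinds commensurable by declaring
one unit: *a character's full observed range costs one step.*

* A continuous character with observed minimum $x_{\min}$ and maximum
  $x_{\max}$ receives weight $w = 1/(x_{\max}-x_{\min})$, so the span of the
  trait across the whole sample costs exactly one weighted step, and a
  change along a branch costs the fraction of the range it traverses.
* An ordered discrete character whose observed states span $r$ unit steps
  receives $w = 1/r$: a three-state morphocline (states 0–2) is weighted
  0.5, because two changes are needed to travel between its endpoints.
* Binary and unordered characters need no adjustment ($w = 1$).

Cell values are taken to be per-taxon means computed upstream of the
matrix; `assign_range_weights()` performs no within-file aggregation.
Polymorphic cells contribute both their extreme states to the observed
range — they are real observations of those states. A consequence worth
knowing: when a range endpoint is observed *only* inside a polymorphic
cell, scoring (which satisfies such a cell anywhere inside its interval)
can realise the character for less than one weighted step; with
monomorphic endpoints the minimum is exactly 1. Characters with zero
observed range are deactivated (reason `"invariant"`) rather than given
infinite weight.

`discretize_continuous()` produces the "traditionally discrete" variant of
a mixed matrix by equal-width binning over each character's observed
range, with half-open bins and the maximum value assigned to the last bin.
Equal-width binning is a reproducible default, not a claim about how any
particular published matrix was discretised; gap coding and other schemes
are deliberately out of scope. After re-weighting, a binned character
costs $1/(k-1)$ per bin boundary crossed, so its full range again costs
one step — which is the point of the exercise: length differences between
the continuous and discretised analyses then reflect the coding decision
alone.

## Scoring: one dynamic programme, three character kinds

All scoring runs through a single generalised Sankoff recursion (in C++),
parameterised by a terminal-cost matrix and a state-change cost matrix:

* **unordered** — uniform cost 1 between distinct states;
* **ordered** — linear cost $|i-j|$; polymorphic terminals are treated as
  intervals $[\min, \max]$ satisfiable at zero cost anywhere inside;
* **continuous** — linear (Wagner) parsimony, with the dynamic programme
  run over the set of observed leaf values of that character. This is
  exact: an L1 Steiner solution on a tree always exists with ancestral
  values drawn from the input values, so restricting the state space loses
  nothing.

Missing (`?`) and inapplicable (`-`) cells are stored distinctly but both
score as "any state at no cost". Nothing in the source material for this
workflow describes inapplicable-aware scoring, so conflating them in the
optimisation (while preserving the distinction in files and round-trips)
is the least surprising choice. Polytomies are scored exactly — the
recursion simply sums over all children — so strict-consensus trees can be
scored without arbitrary resolution.

Per-character bounds use the classical closed forms: the minimum $m_c$ is
the steps on the best conceivable tree (observed states minus one for
unordered; observed span for ordered/continuous), the maximum $g_c$ is the
steps on the star tree (computed by a one-node version of the same
recursion; for ordered/continuous this is the L1 distance to the median).
The ensemble indices are $CI = \sum m_c / \sum s_c$ and
$RI = (\sum g_c - \sum s_c)/(\sum g_c - \sum m_c)$, with both sums taken
over active, parsimony-informative characters ($g_c > m_c$); using one
character set for both keeps the indices comparable and bounds $CI \le 1$.
Equality of weighted lengths is always judged at a tolerance of $10^{-9}$.

## Constrained search

A scaffold is a (possibly polytomous) backbone tree over the non-floater
taxa plus a floater set and an ordered list of sequential outgroups. A
candidate tree is *admissible* when its restriction to the non-floaters
(suppressing degree-2 nodes) displays every non-trivial backbone
bipartition — backbone polytomies may be resolved freely, floaters land
anywhere.

The search itself is deliberately plain: seeded random-addition starting
trees (each taxon inserted at the admissible position of minimum length
increase, ties broken by lowest edge index) followed by steepest-descent
hill climbing over the tree-bisection-reconnection (TBR) neighbourhood,
which contains all subtree-prune-regraft (SPR) moves as the subset with an
unchanged reconnection point on the pruned side. Equal-best and
near-optimal trees are then pooled by breadth-first closure over the same
neighbourhood within a suboptimality window `epsilon` (default 1.0 step
for "near-optimal" reporting, matching the convention of collecting trees
less than a step longer than the optimum — the natural window once
continuous weighting makes lengths fractional). `collect_suboptimal()`
raises the window through a schedule, with a storage cap of 99 999 trees
by default. The elaborate driven-search machinery of dedicated parsimony
programs (sectorial searches, drift, tree fusing) is intentionally not
emulated; at the problem sizes this package targets in tests (≤ ~20
taxa), multi-start TBR reaches the global optimum — verified exhaustively
up to 8 taxa — and the scientific content lies in the constraints,
weights and support measures, not the search heuristics.

Everything is reproducible: identical matrix, scaffold, seed and settings
give an identical ensemble, and the pipeline's tables are byte-identical
across re-runs.

## Relative Bremer support and rogue taxa

Within a pool of optimal and suboptimal trees, a clade $K$ of a reference
tree is scored from $S$ = the number of pool trees displaying $K$ and
$C$ = the number containing a bipartition incompatible with $K$:

$$\mathrm{support}(K) = 100\,\frac{S - C}{\max(S, C)} \in [-100, 100].$$

This form is fixed by three anchor conditions: clades present in every
tree score 100, clades contradicted by every tree score −100, and a clade
whose contradictors are half as numerous as its supporters scores 50. (A
denominator of $S$ alone would violate the −100 anchor.) Pool members that
neither display nor contradict a clade — possible when the pool contains
polytomous trees — count in neither $S$ nor $C$. Clades scoring ≤ 0 are
collapsed in the reported consensus. Readers should note that the original
relative Bremer measure of Goloboff & Farris is defined through step
differences of constrained searches, not tree counts; the tree-count
formulation implemented here is the one this workflow describes, and the
two need not agree numerically.

`find_unstable_taxa()` addresses the familiar rogue-taxon pathology:
greedily remove the taxon whose deletion most increases the number of
strict-consensus splits (ties broken alphabetically), until no removal
helps or a budget is reached. Support is then recomputed on the pruned
pool, where it can only rise for surviving clades.

## Templeton's test

Two topologies are compared through their per-character weighted step
differences: zeros dropped, absolute differences mid-ranked, and
$W = \min(\text{positive rank sum}, \text{negative rank sum})$. For
$n \le 20$ informative characters the two-tailed p-value is exact,
computed from the full sign-pattern distribution (via the generating
function of the positive rank sum, identical to enumerating all $2^n$
patterns); beyond that the normal approximation with tie-corrected
variance is used, without continuity correction — the simplest standard
convention, stated here because the choice of tie handling and rank-sum
convention is exactly what makes published $W$ values hard to reproduce
without the underlying per-character data. Continuous characters
participate with real-valued differences. No multiple-testing correction
is applied across a pairwise table; the table reports raw pairwise
p-values.

## Ancestral states and synapomorphies

`mpr_sets()` computes, for every node of a rooted binary tree, the exact
set of states (or candidate values) attained in at least one
most-parsimonious reconstruction: a down-pass of subtree costs and an
up-pass marginalising the rest of the tree, both reusing the Sankoff
kernel. A character is an *unambiguous synapomorphy* of a clade when the
MPR set at the clade's ancestor is disjoint from the MPR set at that
node's parent — every optimal reconstruction then places a change on the
subtending branch. Overlapping-but-unequal sets are reported but flagged
ambiguous. With an ensemble, `consistent_synapomorphies()` keeps only
characters unambiguous on every tree displaying the clade. Marginal (not
joint) ambiguity is used throughout, matching how synapomorphy lists are
conventionally read; polytomous trees are refused with a pointer to use a
binary MPT.

## What the synthetic generator does and does not emulate

`simulate_matrix()` evolves unordered characters by a symmetric k-state
jump process (Poisson change events along each branch), ordered characters
by a ±1 reflected walk, and continuous characters by Brownian motion, then
masks cells missing — independently, or with per-taxon multipliers that
concentrate missingness in designated "fossil" rows. `make_scaffold()`
derives a backbone from the true tree and collapses a chosen fraction of
its internal edges into polytomies, so admissibility of the truth is
guaranteed by construction. `paper_shaped_config()` bundles a
study-shaped configuration — 177 taxa, 680 characters of which 48
continuous and 112 ordered, three sequential outgroups branching basally,
a scaffold over 18 extant-like backbone taxa with a quarter of its edges
collapsed, and fossil-style doubled missingness in half the ingroup —
with a `scale` argument for smaller, structurally identical variants.

The generator reproduces the *shape* of such data (character-kind mix,
taxon-concentrated missingness, tunable homoplasy: ensemble CI falls
monotonically as the rate rises), not its biology: characters evolve
independently (no morphological integration or correlated evolution), all
characters share one rate, there is no ascertainment bias toward variable
characters, and missingness is unrelated to character state. Passing
recovery tests on these data therefore demonstrates the machinery, i.e.
that the estimator and search find the truth when the model holds — not
that any empirical matrix meets these assumptions.

## The recovery benchmark, and how its conditions were fixed

`recovery_benchmark()` is the package's parameter-recovery experiment: an
8-taxon balanced tree of four cherries, 200 characters (140 unordered, 40
ordered, 20 continuous), 30% missing cells, searches with and without a
correct scaffold, success measured as Robinson–Foulds distance 0 between
the strict consensus of the MPTs and the true topology.

The free design parameters — branch lengths and rate — were fixed once by
a power analysis, because a recovery benchmark is only meaningful in a
regime where the estimator is expected to succeed. Two failure modes
bracket the useful range. At high change density (≈0.5 expected changes
per branch per character) the data saturate: the *exhaustive-search*
optimum itself differs from the truth, so no search could score better.
At very low density, short internal branches go unmarked and ties
proliferate. The diagnosis that mattered: in every failing replicate
examined, `tbr_search` had found the exact global optimum over all 10 395
topologies — the misses were properties of the data, not the search. The
frozen conditions (internal branches 1.5, terminals 0.5, rate 0.2 — about
2.6 expected changes per character across the tree, CI ≈ 0.8) gave 79/80
recovery on seed bases disjoint from any used while exploring, and the
scaffold arm never recovered worse than the unconstrained arm.

## Numerical and interface choices

* Character indices are 1-based everywhere in the API and reports;
  TNT-format `ccode`/`cnames` commands keep TNT's 0-based convention on
  disk.
* The TNT dialect is the `xread` family: `&[continuous]`/`&[num]`
  sub-blocks (emitted per run of same-kind columns so column order
  round-trips), bracketed polymorphisms, `?` missing, `-` inapplicable,
  `ccode` for ordering/activity/weights, plus three small extension
  commands (`cnames`-style groups for labels, `ctags` for anatomical
  region, `cstates` for declared state counts that exceed the observed
  ones). The NEXUS dialect mirrors all of this with standard
  `ASSUMPTIONS` sets plus `ANATOMYSET`/`STATESET` extensions. Labels
  round-trip with spaces encoded as underscores.
* Duplicate trees are detected by canonical sorted-bipartition keys;
  reported trees are rooted at the first sequential outgroup.
* Scoring problem sizes in the test-suite are chosen so every optimum can
  be cross-checked by brute force: ≤ 6 taxa against enumeration of all
  internal assignments, ≤ 8 taxa against enumeration of all topologies.
  The pipeline smoke grid runs eight cells on 8-taxon data.

## Known limitations

* Inapplicable characters are scored as missing; no coding-hierarchy
  logic.
* Relative Bremer uses the tree-count reading (see above), and its value
  depends on how deeply the suboptimal pool was collected — as it does in
  any implementation of the measure.
* The search offers no ratchet or branch-and-bound; very large matrices
  (hundreds of taxa) are out of its intended range, although scoring,
  weighting, I/O and support computations all remain exact at that scale.
* Step-matrix (general cost-matrix) characters and implied weighting are
  not implemented.
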