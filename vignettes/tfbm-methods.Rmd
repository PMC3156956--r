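---
title: "Breakpoint reuse and the turnover of fragile regions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint reuse and the turnover of fragile regions: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbm)
```

## The scientific question

Where do chromosomal rearrangements break genomes?  The random breakage
model (RBM) says anywhere; the fragile breakage model (FBM) says in a
fixed minority of fragile regions, which predicts heavy *reuse* of the
same breakpoints.  Comparative studies found heavy reuse *within*
lineages but surprisingly little *between* distant lineages.  The
turnover fragile breakage model (TFBM) reconciles the two observations:
regions are fragile only for a limited evolutionary time, dying and being
born at a steady rate, so nearby rearrangements share breakpoints while
distant ones do not.  This package implements the machinery needed to
state and test that hypothesis on circular genomes: breakpoint graphs,
model simulators, reuse statistics with their breakpoint-graph bounds,
shortest-scenario sampling, and the multispecies reuse curve `R(l)` with
its closed-form TFBM prediction.

## Genomes, 2-breaks and the breakpoint graph

A genome over `m` signed synteny blocks is a perfect matching on the
`2m` block extremities (tails and heads); each matched pair is an
adjacency and every matching is a valid set of circular chromosomes.  A
*2-break* (the DCJ operation restricted to circular genomes) cuts two
adjacencies and rejoins the four extremities the other way; it *uses*
those four vertices.  Superimposing the matchings of two genomes gives
the breakpoint graph, a disjoint union of alternating black–red cycles.
With `b` the number of synteny blocks delimited by breakpoints
(vertices on non-trivial cycles, divided by two) and `c` the number of
non-trivial cycles, the rearrangement distance is `d = b - c`, because a
2-break can raise the cycle count by at most one and a splitting 2-break
always does.

```{r worked-example}
P <- make_genome(list(c("+a", "+b"), c("+c", "+e", "-d")))
Q <- make_genome(list(c("+a", "+b", "-e", "+c", "+d")))
bg <- breakpoint_graph(P, Q)
c(b = bg$b, c = bg$c, d = two_break_distance(P, Q))
```

The package validates `d = b - c` against a breadth-first-search oracle
over the full 2-break move graph on all genomes with up to four blocks
(105 perfect matchings), and the cycle decomposition against an
independent connected-component count.

## The simulator

`simulate_tree()` evolves a random multi-chromosomal genome along a
phylogenetic tree whose integer branch lengths count 2-breaks.  The
fragility state partitions the current adjacencies into `n` fragile and
`m - n` solid sites.  Each step draws two distinct fragile adjacencies
uniformly, applies one of the two reconnections with equal probability,
marks the two new adjacencies fragile, and then turns over exactly `x`
sites each way (uniformly chosen deaths among the `n` fragile, births
among the `m - n` solid).  FBM is `x = 0`; RBM is `x = 0, n = m`.

Modelling choices worth stating explicitly:

* **Fragility lives on adjacencies and is inherited through breakage.**
  The two adjacencies created by a 2-break take over the fragile status
  of the two they replace, before turnover applies.  Under `x = 0` this
  makes the fragile vertex set closed for the whole simulation, which is
  what gives the FBM closed forms below their exact per-step usage
  probability `2/n`.
* **State is a property of the evolutionary point.**  At each tree node
  the genome and fragility state are snapshotted; every branch leaving
  the node inherits that snapshot, so fragility evolves continuously
  along every root-to-leaf path rather than along an arbitrary traversal
  order.
* **The reconnection choice is uniform.**  Of the two ways to rejoin
  four extremities, each is taken with probability 1/2.  This is a
  modelling assumption; nothing in the theory depends on it.
* **The start node is a leaf by default.**  2-breaks are invertible, so
  placing the random start genome at any node yields the same process up
  to branch orientation; the orientation fixes how scenario positions
  are indexed.
* **`m` defaults to the block count.**  With `x = 0` the solid sites are
  inert, so FBM statistics do not depend on `m`.

The default study conditions are those of the simulation protocol the
statistics are calibrated against: the five-species tree
((M,R)MR,D)MRD,(Q,H)QH with 100 2-breaks per branch, a start genome of
`m = 2000` blocks in 20 random circular chromosomes, and 100 replicates
per experiment.

## Reuse statistics and their bounds

A vertex is *intra-reused* on a branch when two distinct 2-breaks of its
scenario use it (`br(e)`; the weighted variant `BR(e)` counts extra uses)
and *inter-reused* on a branch pair when 2-breaks on both branches use it
(`br(e1, e2)`).  For real genomes the scenarios are unknown, so
`reuse_table()` also reports the breakpoint-graph bounds: `4d - 2b` for a
branch and the number of vertices shared between the non-trivial cycles
of two branches' breakpoint graphs for a pair.  The latter equals the
actual inter-reuse whenever both simulated scenarios happen to be
shortest, a property the test suite asserts on flagged replicates.

Under FBM, each 2-break uses a given fragile vertex with probability
`2/n`, giving the expected inter-reuse
`2n (1 - e^{-2 t1/n})(1 - e^{-2 t2/n})` for branches of `t1` and `t2`
2-breaks and the analogous intra-reuse expectation implemented in
`expected_intra()`.  The exponential form replaces the exact
`(1 - 2/n)^t`; at `t = 100, n = 500` the two differ by about 0.3%, so
the Monte-Carlo tests compare simulated means against the exact binomial
form and separately assert that the exponential form agrees with it.
Scaled reuse (observed over expected) is close to one across all 21
branch pairs under FBM, while turnover (`x > 0`) orders the class means
red > green > yellow (branch pairs sharing a node, separated by one
branch, separated by two).

Statistical bands in the tests are three standard errors of the
replicate mean, the natural scale for quantities reported as averages
over 100 simulations.

## The multispecies reuse curve

For two 2-breaks separated by `l - 1` others along the tree path,
`R(l)` is the mean number of shared vertices.  With known scenarios the
curve is exact (`actual_R_curve()`).  With only node genomes,
`empirical_R_curve()` samples shortest scenarios per branch: repeatedly
choose a non-trivial cycle `C` with probability proportional to
`|C|/2 - 1` and apply one of the `|C|(|C|-2)/8` splitting 2-breaks of
`C` uniformly.  Every sampled scenario has length `b - c` and each step
drops the distance by exactly one.  This is a particular proposal
distribution over shortest scenarios, not the uniform one.

Averaging accumulates shared-vertex totals and pair counts across
samplings before dividing, so all distance bins are weighted
consistently; bins with no pairs are omitted rather than reported as
0/0.  Same-branch pairs are included: they dominate the small-`l` bins
and produce the characteristic horizontal trend there, which is also why
sampling on a *single* branch loses the turnover signal entirely — a
two-genome comparison cannot see fragile sites die.

## The TFBM closed form and parameter estimation

A vertex fragile now is still fragile after `l` 2-breaks with
probability

`P(l) = ((m-n)/m) (1 - x m / (n(m-n)))^l + n/m`,

the solution of the two-state Markov recurrence with `P(0) = 1`.  The
predicted curve is `R(l) = (8/n) P(l)`: flat at `8/n` for FBM/RBM,
decaying towards `8/m` under turnover.  For small `x m l / (n(m-n))` it
is close to the line `8/n - (8x/n^2) l`, which is independent of `m` —
so `m` is identified only by curvature, and fits on short or shallow
curves flag it as weakly constrained.

`fit_tfbm()` estimates `(n, x, m)` by weighted nonlinear least squares
(weights are the per-bin pair counts) in the transformed space
`(log n, log x, log(m - n))`, which enforces positivity and `n < m`.
Starting values come from the model's own moments: `n0 = 8/R` at the
smallest bin, `x0` from the initial slope via the linear approximation,
`m0 = 2 n0`.  A curve that is flat within noise is reported as `x = 0`
("no turnover signal") with `m` undefined.  The fitting objective is this
package's choice; the theory fixes the curve but not the estimator.

On noiseless theoretical curves the fit recovers the parameters to
better than 1%.  On full simulated experiments (five-species tree,
`m = 2000, n = 900, x = 1`, 30 scenario samplings per curve) the tree
diameter of roughly 390 sub-branches sees the curve decay by only ~25%,
so single-replicate estimates of `x` are noisy; across 10 replicates
`n` is recovered within ±25% in every fit and the median of `x` lands
within ±25% of truth.  This is the regime the test suite asserts.

## Numerical and degenerate-input choices

* Midpoint distances between branches can be half-integers; they are
  exact in double precision.
* `expected_intra()` clamps its small-`t` negative dip to zero
  (the formula is an approximation); it requires `t >= 1`.
* `persistence_probability()` rejects `n = m` with `x > 0` (division by
  `m - n`) and `fit_tfbm()` requires at least four distinct bins.
* A branch of length zero leaves its end genomes identical; a trivial
  cycle yields no splitting 2-breaks; `P = Q` yields an empty scenario.
* All stochastic entry points take a seed and are exactly reproducible;
  replicate `r` of an experiment uses `seed + r`.

## What the simulations do and do not show

The generator emulates the study conditions: uniform breakage within the
currently fragile set, a constant genome-wide turnover rate, 2-breaks
only, and circular chromosomes.  Real mammalian genomes violate all four
in various ways — linear chromosomes with telomeres, non-uniform
fragility propensities (segmental duplications), transpositions, and
resolution-dependent synteny blocks.  Passing tests therefore show that
the statistics and estimators behave as the models predict under the
models' own assumptions, not that any particular genome evolved that
way.  Reconstructed ancestral genomes, which real analyses require, are
out of scope: `reuse_table()` and `empirical_R_curve()` accept ancestral
genomes as input but do not infer them.
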