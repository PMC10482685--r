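---
title: "Trait-dependent models of historical biogeography with traitDEC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-dependent models of historical biogeography with traitDEC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

traitDEC fits dispersal–extinction–cladogenesis (DEC) family models of
geographic range evolution on a dated phylogeny. A lineage's range is a
non-empty subset of `A` discrete areas. Along branches the range evolves as
a continuous-time Markov chain: expansion into area `k` at rate

    d * m_trait * sum_{j in range} MDMM[j,k] * (D[j,k] / Dbar)^x

and contraction out of area `j` at rate `e` per occupied area (losing the
last area leads to the absorbing null range, which surviving tips never
occupy). `MDMM` is a manual dispersal multiplier matrix encoding barrier
permeability — the three standard scenarios set continental/oceanic pairs to
1/1 (`equal`), 0.5/0.125 (`half`) and 0.5/0.05 (`tenth`) — and `x` is a free
distance exponent (the `+x` models; distances are normalized by their
off-diagonal mean `Dbar` so that `d` stays on a comparable scale for any
`x`). At nodes, the range is partitioned between daughters by a
cladogenesis table: DEC allows subset sympatry and single-area vicariance,
DIVALIKE any ordered bipartition, BAYAREALIKE only identical inheritance;
all scenarios of a model are equally likely. Analyses can be
time-stratified: each epoch slice carries its own MDMM and allowed-area
mask, and states containing a disallowed area receive zero likelihood at
the older edge of an epoch boundary.

Trait dependence (`+m2` models) doubles the state space with a binary trait
axis. The state-1 dispersal multiplier is fixed at 1 and the state-2
multiplier `m2` is estimated, together with a symmetric trait switch rate
`t`; the trait state is inherited unchanged by both daughters at nodes. Tip
trait states come from binarizing a continuous factor score (for example,
the body-size or life-history axis of a phylogenetic factor analysis) at
four splits: `median` (lower half focal), `first25`, `last25` and
`extreme50`. Species ranked by (score, name) — the name is the
deterministic tie-break — are cut at ranks ⌈n/4⌉, ⌈n/2⌉, ⌈3n/4⌉; the focal
set is trait state 2. Species without a score keep an ambiguous state
(likelihood 1 for both states) and are never dropped.

### Likelihood and the trait-conditioning choice

The likelihood is computed by Felsenstein pruning with per-segment matrix
exponentials of the epoch generator, daughter combination through the
cladogenesis table, per-node rescaling against underflow, and a uniform
root prior over allowed non-null states. For trait-dependent models the
reported quantity is the likelihood of the ranges *conditional on the
observed trait states*: the joint trait-augmented pruning likelihood minus
the likelihood of the trait data alone under the same two-state chain.
Without this conditioning, trait-dependent models would carry the trait
data's entropy (roughly `-n log 2`) that trait-independent models never
pay, and the ten-model AICc comparison would not compare like with like.
With `m2 = 1` the joint likelihood factorizes exactly into (range process)
× (trait chain), so the conditional likelihood collapses to the base model
— the package's nested-identity tests check this to machine precision. The
parameter counts used for AICc (with n = number of tips) are 2 (base,
d and e), 3 (`+x`), 4 (`+m2`: d, e, m2, t) and 5 (`+m2x`).

### Model set, averaging, and the trait–dispersal curve

Following standard practice the base model and MDMM scenario are chosen
first among the nine trait- and distance-independent combinations by AICc
(ties break toward the equal-weight MDMM, then DEC). On the winning
combination the candidate set is {base, +x} ∪ {+m2, +m2x} × 4 splits — ten
models whose AICc weights are normalized jointly. Trait support, however,
is summarized per split: within each split's four-model subset
{base, +x, +m2, +m2x} the renormalized weights of +m2 and +m2x are summed,
and the four values averaged. This two-vs-two construction gives the
trait-dependent and trait-independent alternatives equal prior mass; the
naive sum over all ten models (available as `method = "joint"`) compares
eight trait models against two and exceeds 0.5 under the null through
multiplicity alone. The trait–dispersal
curve assigns each factor quartile the weighted average of the multipliers
that apply to it (`m2` where the quartile is in a model's focal set, 1
elsewhere). Because published applications are ambiguous about the
averaging base, a `per_split` alternative (renormalize within each split's
four-model subset, then average the four curves) is available as a config
switch; `joint` is the default. The curve's magnitude is
`100 * (max - min) / max`, so reported percentages are bounded by 100. A
relationship is classified only when the magnitude exceeds 10%: comparing
the linear score `Q4 - Q1` against the quadratic score
`(Q1+Q4)/2 - (Q2+Q3)/2`, with the strictly larger absolute score deciding
between positive/negative and U/bell (exact ties go to the linear class).

### Reconstruction comparison metrics

Marginal ancestral ranges are computed by the standard two-pass algorithm
and model-averaged within groups (trait-dependent {+m2, +m2x} vs
trait-independent {base, +x}; distance-dependent {+x, +m2x} vs
distance-independent {base, +m2}) with weights renormalized within the
group, per split, then averaged across the four splits. Resolution is the
mean per-node maximum range probability. Node disagreement is the
proportion of internal nodes whose most likely range differs between the
two groups (strict argmax; ties break to the first state in the canonical
order: null, then by range size, then lexicographic). Dispersal events are
counted on biogeographic stochastic maps: node states are sampled jointly
root-down from the cached pruning partials, branch paths are sampled
conditioned on their endpoints by rejection (forward simulation, 10,000
retries) with an exact uniformization fallback; the two samplers are
checked against each other in distribution. Each expansion event is
classified oceanic or continental by the barrier class of its dominant
(highest dispersal weight) source route, a per-event attribution the
original analyses leave unspecified.

## The synthetic generator

`simulateClade()` is the generative twin of the fitted models: a
birth–death tree conditioned on the number of surviving tips (forward
Gillespie, stopped when the (n+1)-th birth would occur; for a Yule process
the expected root age is `sum_{k=2..n} 1/(k lambda)`), a Brownian trait
factor, and a Gillespie range history with cladogenetic draws from the
model's event table. Trait states are produced by thresholding the factor
at its simulated tip median — branches whose child-node value falls below
the median carry the multiplier `m2` — so that the generated effect aligns
with the pipeline's median split and the fitted `m2` is directly
comparable to the generating value. (A consequence of this convention: a
strong positive `m2` produces a "negative"-shaped curve, since the focal
state comprises the *low*-scoring quartiles. Shape generation instead uses
an explicit quartile curve: each branch carries the multiplier of its
child-node quartile.) An independent-chain trait mode is available via the
`t` parameter for simulations without the Brownian coupling.

Replicates in which any lineage is absorbed into the null range are
rejected whole and redrawn. This is clean conditioning on the
observed-data regime, but at the default study conditions (d = 0.02,
e = 0.01) acceptance can be rare for large clades — rejection counts in
the thousands — and the accepted histories systematically under-represent
single-area contraction. Because the fitted likelihood does *not*
condition on survival (uniform root prior, as in the standard software
defaults), this survivorship gap, combined with the well-known confounding
between anagenetic contraction and cladogenetic subset sympatry in DEC,
makes the contraction rate `e` essentially unidentifiable at these
conditions: fitted values collapse to the lower bound while `d`, `m2` and
the trait-support weights are recovered well. The acceptance suite reports
this honestly rather than tuning around it.

What the generator does not emulate: fossils and sampled ancestors,
diversity-dependent or trait-dependent diversification (no SSE component —
the trait affects dispersal only), phylogenetic and taxonomic error,
spatially autocorrelated sampling artefacts, or paleogeographic area
movement. Passing tests therefore demonstrate internal statistical
consistency of the machinery, not robustness to the many ways real data
violate DEC-family assumptions.

## Numerical choices

* Matrix exponentials on the hot path use a spectral decomposition of the
  epoch generator (one `eig` per likelihood evaluation, two complex
  mat-vecs per branch segment). Decompositions whose reconstruction
  residual exceeds 1e-10 — typical when `e` sits near zero and the
  generator is near-defective — are rejected, and propagation falls back
  to uniformization, which is stable because every term is non-negative.
  The R-side propagators used for marginals and stochastic maps apply the
  same residual test with a `Matrix::expm` fallback.
* Optimization is Nelder–Mead on log-transformed rates with a penalty
  outside the bounds d, e, t ∈ [1e-9, 5], m2 ∈ [1e-4, 100], x ∈ [-5, 5],
  three deterministic starts (default; the default start, and d, e scaled
  by 10 and 1/10), relative function tolerance 1e-8 (≈ 1e-6 in
  log-likelihood units at typical magnitudes). Within a model set the
  base fit seeds the other starts and each `+m2x` fit starts from its
  `+m2` optimum.
* The state-space guard rejects more than 10 areas (the dense state space
  grows as `2^A`, doubled for trait models); `maxRangeSize` defaults to
  `A` because the original analyses report no cap.
* Seeds: every stochastic routine takes an explicit seed; one master seed
  deterministically derives per-component streams, and identical
  configuration plus seed reproduces clade reports byte for byte.

## Problem sizes used by the test and acceptance suites

Parameter recovery runs 20 replicates at 150 tips and 4 areas under the
strong effect (m2 = 4) and 9 replicates at 100 tips under the null
(m2 = 1; the smaller size keeps null-history rejection sampling
practical). Shape recovery runs 20 replicates per shape at 100 tips on a
3-area geography with ratio-3 curves and single-start warm-chained fits —
at strong effect the classification is insensitive to the extra starts.
Oracle comparisons enumerate all joint histories on trees of up to 4 tips
and 3 areas. These sizes are the package's validation design; the
machinery itself handles the guard-limited state space.

## Known limitations

* `e` is weakly identified in DEC-family models generally, and the
  generator's survivorship conditioning widens the gap at the default
  conditions (see above).
* The ten-model set treats the four binarizations of one factor as
  competing models; the curve is therefore a model-averaged summary, not a
  continuous-trait estimate.
* Founder-event (+J) cladogenesis is deliberately absent, and only a
  single symmetric trait-switch rate is offered.
* Bioregionalization (`phyloBeta`, `weightByDistance`, `upgmaCluster`,
  `cutRegions`) expects already-gridded presence matrices; projections and
  shapefile handling are out of scope, and the distance-weighting form
  (elementwise product with a 1% floor) is one monotone choice among
  several, isolated behind a single function for replacement.
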