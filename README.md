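# traitDEC

Trait-dependent dispersal–extinction–cladogenesis (DEC) models for
historical biogeography, in R.

## The problem

Lineages cross biogeographic barriers — oceans, deserts, mountain chains —
rarely, and whether a crossing succeeds may depend on the lineage's
biology: its body size, its life-history speed, its physiology. Standard
ancestral-range models (DEC, DIVALIKE, BAYAREALIKE) assume every lineage
disperses at the same rate *d*. traitDEC implements the trait-dependent
extension in which a binary trait state multiplies the dispersal rate:
state 1 keeps multiplier 1 and state 2 carries a free multiplier *m₂*,
estimated jointly with *d*, the range-contraction rate *e*, a trait switch
rate *t*, and optionally a distance exponent *x* under which the expansion
rate into area *k* from range *r* is

```
d · m_trait · Σ_{j∈r} MDMM[j,k] · (D[j,k]/D̄)^x
```

with `MDMM` a manual dispersal multiplier matrix encoding barrier
permeability (equal / 0.5–0.125 / 0.5–0.05 scenarios for
continental/oceanic pairs) and `D` the inter-area distances.

Because a binary trait is a coarse probe of a continuous axis, the
pipeline fits four binarizations of a continuous factor score (median
split, first 25%, last 25%, extreme 50%) and model-averages the estimated
multipliers by AICc weight into a **trait–dispersal curve** over factor
quartiles. The curve's **magnitude** (`100·(max−min)/max`) quantifies the
effect; when it exceeds 10% the relationship is classified **positive**,
**negative**, **U** or **bell**. Trait-dependent and trait-independent
reconstructions are compared through ancestral-range resolution,
stochastic-map dispersal counts (with oceanic/continental attribution) and
the proportion of nodes whose most likely range changes.

The package also ships the generative twin of the model (birth–death
trees, Brownian factors, Gillespie range histories with known parameters),
so every stage is testable against known truth, plus phylogenetic
beta-diversity bioregionalization utilities (PhyloSor, great-circle
distance weighting, UPGMA, silhouette-guided region cutting) for building
the discrete areas in the first place.

## Worked example

```r
library(traitDEC)

# a synthetic clade at the package's standard strong-effect conditions:
# 60 tips, 4 areas, d = 0.02, e = 0.01, m2 = 4 on the below-median state
sim <- simulateClade(simConfig(n = 60, seed = 42))

reports <- runCladePipeline(sim$dataset,
                            list(seed = 1, nStarts = 2, nMaps = 25))
reports[["factor1"]]
#> CladeReport: trait factor1
#>   curve (Q1..Q4): 1.3517, 1.2955, 1.0000, 0.6942
#>   magnitude: 48.64%  shape: negative  trait-dependent weight: 0.378
```

Reading the output: the selected base model was DEC with the equal-weight
MDMM; the model-averaged dispersal multiplier falls from 1.35 in the
lowest factor quartile to 0.69 in the highest — a 48.6% maximal rate
difference, classified "negative" (low-scoring lineages disperse more,
exactly the side the generator boosted with m₂ = 4). The trait-dependent
weight (per-split AICc support of {+m2, +m2x} against {base, +x},
averaged over the four binarizations) is 0.38 at this modest clade size;
at 150 tips the same conditions give 0.8–1.0. The comparison metrics on
the same run:

```r
r <- reports[["factor1"]]
r@comparison$trait$disagreement      # 0.042  -> 4.2% of nodes change
r@comparison$trait$resolutionDep     # 0.585  (trait-independent: 0.584)
r@comparison$trait$perLineageDep     # 1.33 dispersal events per lineage
r@comparison$trait$oceanicPctDep     # 54.5% of expansions oceanic
```

Lower-level entry points: `readNewick()` / `readGeography()` /
`readAreaMatrix()` / `buildDataset()` for real data, `computeLogLik()` and
`fitModel()` for single models, `selectBaseModel()` and `fitModelSet()`
for the candidate set, `ancestralMarginals()`, `stochasticMaps()` and
`compareModelGroups()` for reconstructions, `makeFixture()` to write a
complete synthetic dataset to disk, and `phyloBeta()` → `weightByDistance()`
→ `upgmaCluster()` → `cutRegions()` for bioregionalization.

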