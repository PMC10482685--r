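Package: traitDEC
Title: Trait-Dependent Dispersal-Extinction-Cladogenesis Models for
    Historical Biogeography
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Fits dispersal-extinction-cladogenesis (DEC) family models of
    ancestral geographic range evolution in which lineage dispersal rates may
    depend on a binary trait and/or on inter-region distance. Provides
    time-stratified maximum-likelihood inference over DEC, DIVALIKE and
    BAYAREALIKE cladogenesis schemes with manual dispersal multiplier
    matrices, AICc model averaging of trait-dispersal multipliers across four
    trait binarizations into a trait-dispersal curve, effect-magnitude and
    shape classification, marginal ancestral-range estimation, biogeographic
    stochastic mapping with oceanic/continental event attribution, and
    comparison of trait-dependent against trait-independent reconstructions.
    Includes a generative twin (birth-death trees, Brownian trait factors,
    trait-dependent range histories) and phylogenetic beta-diversity
    bioregionalization utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    ape,
    phytools,
    Matrix,
    Rcpp,
    jsonlite,
    geosphere,
    cluster
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
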