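#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib traitDEC, .registration = TRUE
NULL

setOldClass("phylo")

#' BiogeoDataset: a validated, cross-linked biogeographic dataset
#'
#' Container tying together a dated phylogeny, a species-by-area presence
#' matrix, inter-area distances (km), an oceanic/continental barrier
#' classification, a time-stratified epoch specification (each slice carrying
#' a manual dispersal multiplier matrix, MDMM, and an allowed-area mask) and
#' continuous trait factor scores per species. Construct with
#' [buildDataset()]; do not fill slots by hand.
#'
#' @slot tree a rooted, strictly bifurcating `ape::phylo` with branch lengths
#'   in My.
#' @slot presence binary tips x areas matrix; every tip occupies >= 1 area.
#' @slot distances symmetric non-negative A x A matrix of great-circle
#'   distances between area centroids (km), zero diagonal.
#' @slot barriers symmetric A x A character matrix with entries
#'   `"continental"`/`"oceanic"` off-diagonal and `"self"` on the diagonal.
#' @slot epochs list of time slices, young to old; each a list with `start`
#'   and `end` (Ma before present), `mdmm` (A x A multipliers in \[0,1\]) and
#'   `allowed` (logical mask of areas reachable in that slice). Slices tile
#'   \[0, root age\].
#' @slot traits data.frame of continuous factor scores (one column per
#'   factor), rownames are species; `NA` allowed (trait state treated as
#'   ambiguous downstream, species are never dropped).
#' @slot metadata list: `clade` name, `nTips`, `ambiguousTrait` (species with
#'   a missing score in any factor).
#' @seealso [buildDataset()], [readNewick()], [readGeography()],
#'   [readAreaMatrix()]
#' @export
setClass("BiogeoDataset",
  representation(
    tree = "phylo",
    presence = "matrix",
    distances = "matrix",
    barriers = "matrix",
    epochs = "list",
    traits = "data.frame",
    metadata = "list"
  )
)

setValidity("BiogeoDataset", function(object) {
  msg <- character()
  tr <- object@tree
  tips <- tr$tip.label
  if (anyDuplicated(tips)) msg <- c(msg, "duplicate tip labels")
  if (!ape::is.binary(tr)) msg <- c(msg, "tree is not strictly bifurcating")
  if (any(tr$edge.length < 0)) msg <- c(msg, "negative branch lengths")
  A <- ncol(object@presence)
  if (!setequal(rownames(object@presence), tips))
    msg <- c(msg, "presence matrix rows do not match tree tips")
  if (any(rowSums(object@presence) < 1))
    msg <- c(msg, "some species occupy no area")
  if (!all(object@presence %in% c(0, 1)))
    msg <- c(msg, "presence matrix must be binary")
  if (!isTRUE(all.equal(object@distances, t(object@distances),
                        tolerance = 1e-9)))
    msg <- c(msg, "distance matrix not symmetric")
  if (any(object@distances < 0)) msg <- c(msg, "negative distances")
  if (any(diag(object@distances) != 0))
    msg <- c(msg, "distance diagonal must be zero")
  if (!identical(object@barriers, t(object@barriers)))
    msg <- c(msg, "barrier matrix not symmetric")
  if (!all(diag(object@barriers) == "self"))
    msg <- c(msg, "barrier diagonal must be 'self'")
  off <- object@barriers[row(object@barriers) != col(object@barriers)]
  if (!all(off %in% c("continental", "oceanic")))
    msg <- c(msg, "unknown barrier label")
  if (nrow(object@traits) > 0 &&
      !all(rownames(object@traits) %in% tips))
    msg <- c(msg, "trait table contains species absent from the tree")
  rootAge <- max(nodeAges(tr))
  ep <- object@epochs
  if (length(ep) == 0) {
    msg <- c(msg, "at least one epoch slice required")
  } else {
    starts <- vapply(ep, `[[`, numeric(1), "start")
    ends <- vapply(ep, `[[`, numeric(1), "end")
    tol <- 1e-8 * max(rootAge, 1)
    if (abs(starts[1]) > tol) msg <- c(msg, "first epoch must start at 0 Ma")
    if (ends[length(ep)] < rootAge - tol)
      msg <- c(msg, "epoch slices do not reach the root age")
    if (length(ep) > 1 &&
        any(abs(starts[-1] - ends[-length(ep)]) > tol))
      msg <- c(msg, "epoch slices have gaps or overlaps")
    for (sl in ep) {
      if (any(sl$mdmm < 0 | sl$mdmm > 1))
        msg <- c(msg, "MDMM entries must lie in [0,1]")
      if (length(sl$allowed) != A)
        msg <- c(msg, "allowed-area mask has wrong length")
    }
  }
  if (length(msg)) msg else TRUE
})

#' RangeStateSpace: ordered geographic-range states
#'
#' The discrete state space of a DEC-family model: all subsets of the A areas
#' up to `maxRangeSize`, ordered null range first, then by range size, then
#' lexicographically by area order; optionally crossed with a binary trait
#' axis (states `s1`, `s2`), in which case all ranges with trait `s1` precede
#' all ranges with trait `s2`.
#'
#' @slot areas ordered area names.
#' @slot masks integer bitmasks (bit i-1 set = area i occupied), canonical
#'   order; `masks[1] == 0L` is the null range.
#' @slot maxRangeSize largest allowed range size.
#' @slot traitAugmented logical; if `TRUE` the state count doubles.
#' @slot labels human-readable state labels, e.g. `"AB"` or `"AB|s2"`.
#' @seealso [enumerateRanges()]
#' @export
setClass("RangeStateSpace",
  representation(
    areas = "character",
    masks = "integer",
    maxRangeSize = "integer",
    traitAugmented = "logical",
    labels = "character"
  )
)

setValidity("RangeStateSpace", function(object) {
  A <- length(object@areas)
  k <- object@maxRangeSize
  expected <- 1L + sum(choose(A, seq_len(k)))
  if (length(object@masks) != expected)
    return("range count does not match 1 + sum_k C(A,k)")
  n <- expected * (1L + object@traitAugmented)
  if (length(object@labels) != n)
    return("label count inconsistent with trait augmentation")
  if (object@masks[1] != 0L) return("null range must come first")
  TRUE
})

#' BiogeoFit: one maximum-likelihood model fit
#'
#' Result of [fitModel()] (or of a fixed-parameter likelihood evaluation):
#' model specification, ML parameter estimates, log-likelihood, parameter
#' count, AICc, convergence diagnostics and the cached pruning context that
#' downstream operations ([ancestralMarginals()], [stochasticMaps()]) reuse.
#'
#' @slot modelSpec list: `base` ("DEC"/"DIVALIKE"/"BAYAREALIKE"), `hasX`,
#'   `hasM2`, `split` (binarization id when `hasM2`), `mdmm` scenario id,
#'   `trait` column name.
#' @slot params named numeric vector (d, e, and any of x, m2, t).
#' @slot lnL log-likelihood at `params`.
#' @slot k number of free parameters.
#' @slot AICc small-sample Akaike information criterion (n = number of tips).
#' @slot convergence list of optimizer diagnostics.
#' @slot cache internal pruning context (state space, rate matrices,
#'   per-node partials); treat as opaque.
#' @export
setClass("BiogeoFit",
  representation(
    modelSpec = "list",
    params = "numeric",
    lnL = "numeric",
    k = "integer",
    AICc = "numeric",
    convergence = "list",
    cache = "list"
  )
)

setValidity("BiogeoFit", function(object) {
  if (!is.finite(object@lnL)) return("non-finite log-likelihood")
  TRUE
})

#' BiogeoModelSet: the 10-model candidate set for one clade and trait
#'
#' All fits for one clade x one trait factor: the trait-independent pair
#' (base, +x) plus the trait-dependent pair (+m2, +m2x) under each of the
#' four binarization splits, with AICc weights normalized over all 10.
#'
#' @slot fits named list of [BiogeoFit-class] objects.
#' @slot weights AICc weights, same names, summing to 1.
#' @slot baseModel the selected base cladogenesis model.
#' @slot mdmm the selected MDMM scenario id.
#' @slot trait trait factor column the set was fitted for.
#' @slot dataset the [BiogeoDataset-class] the set was fitted on.
#' @seealso [fitModelSet()], [modelWeights()], [dispersalCurve()]
#' @export
setClass("BiogeoModelSet",
  representation(
    fits = "list",
    weights = "numeric",
    baseModel = "character",
    mdmm = "character",
    trait = "character",
    dataset = "BiogeoDataset"
  )
)

setValidity("BiogeoModelSet", function(object) {
  if (length(object@fits) != length(object@weights))
    return("fits and weights differ in length")
  if (length(object@weights) &&
      abs(sum(object@weights) - 1) > 1e-12)
    return("AICc weights must sum to 1")
  if (any(object@weights < 0)) return("negative AICc weight")
  TRUE
})

#' CladeReport: trait-dispersal summary for one clade and trait
#'
#' End product of [runCladePipeline()] for one trait factor: the
#' model-averaged trait-dispersal curve over factor quartiles, its magnitude
#' (percent difference between most- and least-dispersive quartiles), the
#' classified shape, the summed AICc weight of trait-dependent models and
#' the trait-dependent vs trait-independent comparison metrics.
#'
#' @slot trait trait factor column name.
#' @slot curve model-averaged dispersal multipliers for quartiles Q1..Q4.
#' @slot magnitudePct 100 * (max - min) / max of the curve.
#' @slot shape one of `"positive"`, `"negative"`, `"U"`, `"bell"`, `"none"`
#'   (`"none"` iff magnitude <= threshold).
#' @slot traitWeight AICc weight of the +m2/+m2x models relative to
#'   base/+x, computed within each split and averaged (see
#'   [traitDependentWeight()]).
#' @slot comparison list of group-comparison metrics (resolution, dispersal
#'   events per lineage, oceanic fraction, node disagreement), or empty.
#' @slot modelTable data.frame with one row per candidate model (parameters,
#'   lnL, AICc, weight).
#' @slot provenance list: seed, base model, MDMM, configuration echoes.
#' @export
setClass("CladeReport",
  representation(
    trait = "character",
    curve = "numeric",
    magnitudePct = "numeric",
    shape = "character",
    traitWeight = "numeric",
    comparison = "list",
    modelTable = "data.frame",
    provenance = "list"
  )
)

setValidity("CladeReport", function(object) {
  if (length(object@curve) != 4) return("curve must have four quartile values")
  if (any(object@curve <= 0)) return("curve multipliers must be positive")
  ok <- object@shape %in% c("positive", "negative", "U", "bell", "none")
  if (!ok) return("unknown shape class")
  TRUE
})
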