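splitFocalQuartiles <- list(median = c(1L, 2L), first25 = 1L,
                            last25 = 4L, extreme50 = c(1L, 4L))

#' Binarize continuous factor scores for a trait-dependent model
#'
#' Species with scores are ranked by (score, species name) — the name is
#' the deterministic tie-break — and assigned quartiles with boundaries at
#' ranks ceiling(n/4), ceiling(n/2) and ceiling(3n/4). The split's focal
#' quartile set receives trait state 2 (whose dispersal multiplier m2 the
#' model estimates), the complement state 1 (multiplier fixed at 1):
#' `median` = \{Q1,Q2\}, `first25` = \{Q1\}, `last25` = \{Q4\},
#' `extreme50` = \{Q1,Q4\}. Unscored species get state `NA` (ambiguous).
#'
#' @param scores named numeric vector of factor scores (`NA` = unscored).
#' @param split split id.
#' @return list: `split`, `states` (named 1/2/NA), `quartile` (named
#'   1..4), `focal` (integer quartiles in the focal set).
#' @export
binarizeFactor <- function(scores, split = c("median", "first25", "last25",
                                             "extreme50")) {
  split <- match.arg(split)
  scored <- scores[!is.na(scores)]
  n <- length(scored)
  if (n < 8) stopf("need >= 8 scored species for binarization (have %d)", n)
  ord <- names(scored)[order(scored, names(scored))]
  rk <- seq_len(n)
  q <- ifelse(rk <= ceiling(n / 4), 1L,
              ifelse(rk <= ceiling(n / 2), 2L,
                     ifelse(rk <= ceiling(3 * n / 4), 3L, 4L)))
  quart <- stats::setNames(q, ord)
  focal <- splitFocalQuartiles[[split]]
  states <- stats::setNames(rep(NA_integer_, length(scores)), names(scores))
  states[ord] <- ifelse(quart %in% focal, 2L, 1L)
  list(split = split, states = states, quartile = quart, focal = focal)
}

#' Model-averaged trait-dispersal curve over factor quartiles
#'
#' Averages the dispersal multipliers of the candidate models into one
#' multiplier per factor quartile: a model contributes its estimated m2 to
#' the quartiles in its split's focal set and 1 elsewhere; trait-independent
#' models contribute 1 everywhere. With `normalization = "joint"` (default)
#' the AICc weights of all 10 models are used directly; with `"per_split"`
#' weights are renormalized within each split's four-model subset
#' \{base, +x, +m2, +m2x\} and the four per-split curves averaged.
#'
#' @param modelSet a [BiogeoModelSet-class].
#' @param normalization `"joint"` or `"per_split"`.
#' @return numeric length-4 vector (Q1..Q4) of averaged multipliers.
#' @export
dispersalCurve <- function(modelSet, normalization = c("joint",
                                                       "per_split")) {
  normalization <- match.arg(normalization)
  fits <- modelSet@fits
  multOf <- function(f, q) {
    if (!isTRUE(f@modelSpec$hasM2)) return(1)
    if (q %in% splitFocalQuartiles[[f@modelSpec$split]])
      unname(f@params["m2"]) else 1
  }
  if (normalization == "joint") {
    w <- modelSet@weights
    curve <- vapply(1:4, function(q)
      sum(vapply(seq_along(fits), function(i)
        w[i] * multOf(fits[[i]], q), numeric(1))), numeric(1))
  } else {
    splits <- setSplits(modelSet)
    curves <- vapply(splits, function(sp) {
      mem <- vapply(names(fits), function(n) {
        f <- fits[[n]]
        is.null(f@modelSpec$split) || f@modelSpec$split == sp
      }, logical(1))
      w <- modelSet@weights[mem] / sum(modelSet@weights[mem])
      sub <- fits[mem]
      vapply(1:4, function(q)
        sum(vapply(seq_along(sub), function(i)
          w[i] * multOf(sub[[i]], q), numeric(1))), numeric(1))
    }, numeric(4))
    curve <- rowMeans(curves)
  }
  stats::setNames(curve, c("Q1", "Q2", "Q3", "Q4"))
}

#' Magnitude of a trait-dispersal curve
#'
#' The maximal relative difference in dispersal rate across the curve,
#' `100 * (max - min) / max`, i.e. the percent reduction from the
#' most-dispersive to the least-dispersive quartile; 0 for a flat curve,
#' always < 100.
#'
#' @param curve length-4 multiplier vector from [dispersalCurve()].
#' @return percent, in \[0, 100).
#' @examples
#' curveMagnitude(c(1.6, 1.6, 1.0, 1.0))  # 37.5
#' @export
curveMagnitude <- function(curve) {
  if (length(curve) != 4 || any(curve <= 0)) stopf("invalid curve")
  100 * (max(curve) - min(curve)) / max(curve)
}

#' Classify the shape of a trait-dispersal relationship
#'
#' If the curve's magnitude is at or below `threshold` percent the
#' relationship is `"none"`. Otherwise a linear score `Q4 - Q1` and a
#' quadratic score `(Q1 + Q4)/2 - (Q2 + Q3)/2` are compared: when the
#' quadratic dominates (strictly larger in absolute value), the shape is
#' `"U"` (positive quadratic: extremes disperse more) or `"bell"`
#' (negative: intermediates disperse more); otherwise (including an exact
#' tie) `"positive"` (Q4 > Q1) or `"negative"`.
#'
#' @param curve length-4 multiplier vector.
#' @param threshold magnitude threshold in percent for a notable effect.
#' @return one of `"positive"`, `"negative"`, `"U"`, `"bell"`, `"none"`.
#' @examples
#' classifyShape(c(1, 0.5, 0.5, 1))   # "U"
#' classifyShape(c(1, 1.2, 1.5, 2))   # "positive"
#' @export
classifyShape <- function(curve, threshold = 10) {
  if (curveMagnitude(curve) <= threshold) return("none")
  lin <- curve[4] - curve[1]
  quad <- (curve[1] + curve[4]) / 2 - (curve[2] + curve[3]) / 2
  if (abs(quad) > abs(lin)) {
    if (quad > 0) "U" else "bell"
  } else {
    if (lin > 0) "positive" else "negative"
  }
}

#' Run the full trait-dispersal pipeline for one clade
#'
#' Orchestrates, per trait factor: base model and MDMM selection over the
#' nine trait-independent combinations, the 10-model candidate set, the
#' model-averaged dispersal curve with magnitude and shape, and (optionally)
#' the trait-dependent vs trait-independent comparison metrics. Fully
#' deterministic given `config$seed`.
#'
#' @param dataset a [BiogeoDataset-class] with at least one trait column.
#' @param config list; recognized entries (with defaults): `seed` (1),
#'   `traits` (all columns), `splits` (the four standard splits), `nStarts`
#'   (3), `nMaps` (0 = skip stochastic-map comparison), `compare` (TRUE),
#'   `curveNormalization` ("joint"), `shapeThreshold` (10), `base`/`mdmm`
#'   (skip selection and use these).
#' @return named list of [CladeReport-class], one per trait.
#' @export
runCladePipeline <- function(dataset, config = list()) {
  cfg <- utils::modifyList(
    list(seed = 1L, traits = colnames(dataset@traits),
         splits = c("median", "first25", "last25", "extreme50"),
         nStarts = 3, nMaps = 0, compare = TRUE,
         curveNormalization = "joint", shapeThreshold = 10,
         base = NULL, mdmm = NULL), config)
  if (!length(cfg$traits)) stopf("dataset has no trait factors")
  if (is.null(cfg$base) || is.null(cfg$mdmm)) {
    sel <- tryCatch(selectBaseModel(dataset, nStarts = cfg$nStarts),
                    error = function(e)
                      stopf("base-model selection failed: %s",
                            conditionMessage(e)))
    cfg$base <- sel$base; cfg$mdmm <- sel$mdmm
  }
  reports <- list()
  for (tr in cfg$traits) {
    ms <- tryCatch(
      fitModelSet(dataset, tr, base = cfg$base, mdmm = cfg$mdmm,
                  splits = cfg$splits, nStarts = cfg$nStarts),
      error = function(e)
        stopf("model-set fitting failed for trait %s: %s", tr,
              conditionMessage(e)))
    curve <- dispersalCurve(ms, normalization = cfg$curveNormalization)
    mag <- curveMagnitude(curve)
    shape <- classifyShape(curve, threshold = cfg$shapeThreshold)
    cmp <- list()
    if (isTRUE(cfg$compare))
      cmp <- tryCatch(
        compareModelGroups(ms, nMaps = cfg$nMaps,
                           seed = deriveSeed(cfg$seed, tr)),
        error = function(e)
          stopf("group comparison failed for trait %s: %s", tr,
                conditionMessage(e)))
    # strip the bulky marginal matrices from the serialized comparison
    cmpSlim <- lapply(cmp, function(g)
      g[setdiff(names(g), c("margDep", "margIndep"))])
    mt <- do.call(rbind, lapply(names(ms@fits), function(n) {
      f <- ms@fits[[n]]
      data.frame(model = n,
                 d = unname(f@params["d"]), e = unname(f@params["e"]),
                 x = unname(f@params["x"]), m2 = unname(f@params["m2"]),
                 t = unname(f@params["t"]), lnL = f@lnL, k = f@k,
                 AICc = f@AICc, weight = unname(ms@weights[n]))
    }))
    reports[[tr]] <- methods::new(
      "CladeReport", trait = tr, curve = unname(curve),
      magnitudePct = mag, shape = shape,
      traitWeight = traitDependentWeight(ms),
      comparison = cmpSlim, modelTable = mt,
      provenance = list(seed = cfg$seed, base = cfg$base, mdmm = cfg$mdmm,
                        curveNormalization = cfg$curveNormalization,
                        shapeThreshold = cfg$shapeThreshold,
                        nMaps = cfg$nMaps, splits = as.list(cfg$splits),
                        clade = dataset@metadata$clade))
  }
  reports
}
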