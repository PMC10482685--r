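# group helpers: model names in a BiogeoModelSet for each grouping ---------

setSplits <- function(modelSet) {
  sp <- unique(stats::na.omit(vapply(modelSet@fits, function(f)
    f@modelSpec$split %||% NA_character_, character(1))))
  sp
}

groupMembers <- function(modelSet, group = c("traitDep", "traitIndep",
                                             "distDep", "distIndep"),
                         split) {
  group <- match.arg(group)
  nm <- names(modelSet@fits)
  pick <- vapply(nm, function(n) {
    f <- modelSet@fits[[n]]
    sOK <- is.null(f@modelSpec$split) || f@modelSpec$split == split
    switch(group,
           traitDep = isTRUE(f@modelSpec$hasM2) && sOK,
           traitIndep = !isTRUE(f@modelSpec$hasM2),
           distDep = isTRUE(f@modelSpec$hasX) && sOK,
           distIndep = !isTRUE(f@modelSpec$hasX) && sOK)
  }, logical(1))
  nm[pick]
}

# AICc-weighted (renormalized within the group) average of per-model range
# marginals; all marginals are collapsed to the shared range basis first.
groupMarginals <- function(modelSet, members, margCache) {
  w <- modelSet@weights[members]
  if (sum(w) == 0) w <- rep(1, length(w))   # degenerate: equal weights
  w <- w / sum(w)
  out <- NULL
  for (i in seq_along(members)) {
    m <- margCache[[members[i]]]
    out <- if (is.null(out)) w[i] * m else out + w[i] * m
  }
  out
}

groupScalar <- function(modelSet, members, values) {
  w <- modelSet@weights[members]
  if (sum(w) == 0) w <- rep(1, length(w))
  sum(values[members] * w / sum(w))
}

argmaxRange <- function(marg) {
  apply(marg, 1, which.max)   # ties: lowest state index (canonical order)
}

#' Compare trait-dependent vs trait-independent reconstructions
#'
#' For each grouping (trait-dependent `{+m2, +m2x}` vs trait-independent
#' `{base, +x}`, and distance-dependent `{+x, +m2x}` vs distance-independent
#' `{base, +m2}`), computes the AICc-weighted (within group, renormalized)
#' average of node range marginals and, optionally, of stochastic-map
#' dispersal summaries, per binarization split, then averages across the
#' four splits. Node disagreement is the proportion of internal nodes whose
#' most likely range differs between the two groups of a comparison
#' (strict argmax; ties break to the first state in canonical order).
#'
#' @param modelSet a [BiogeoModelSet-class] from [fitModelSet()].
#' @param nMaps stochastic maps per model for the dispersal comparison;
#'   `0` skips it (marginal-based metrics only).
#' @param seed RNG seed for the maps.
#' @return list with elements `trait` and `distance`, each containing
#'   `disagreement`, `resolutionDep`, `resolutionIndep`, and (when maps were
#'   drawn) `perLineageDep`, `perLineageIndep`, `oceanicPctDep`,
#'   `oceanicPctIndep`; plus `margTraitDep`/`margTraitIndep` averaged
#'   across splits.
#' @export
compareModelGroups <- function(modelSet, nMaps = 0, seed = 1) {
  fits <- modelSet@fits
  if (!length(fits)) stopf("empty model set")
  splits <- setSplits(modelSet)
  nT <- nTips(modelSet@dataset)
  margCache <- lapply(fits, function(f)
    rangeMarginals(ancestralMarginals(f), f@cache$ctx$stateSpace))
  resCache <- vapply(margCache, rangeResolution, numeric(1))
  dispCache <- NULL
  if (nMaps > 0) {
    dispCache <- lapply(seq_along(fits), function(i)
      countDispersal(stochasticMaps(fits[[i]], nMaps = nMaps,
                                    seed = deriveSeed(seed,
                                                      names(fits)[i])),
                     nT))
    names(dispCache) <- names(fits)
  }

  oneComparison <- function(depGroup, indepGroup) {
    dis <- resD <- resI <- plD <- plI <- ocD <- ocI <- numeric(0)
    margD <- margI <- NULL
    for (sp in splits) {
      dep <- groupMembers(modelSet, depGroup, sp)
      ind <- groupMembers(modelSet, indepGroup, sp)
      if (!length(dep) || !length(ind)) stopf("empty model group")
      mD <- groupMarginals(modelSet, dep, margCache)
      mI <- groupMarginals(modelSet, ind, margCache)
      dis <- c(dis, mean(argmaxRange(mD) != argmaxRange(mI)))
      resD <- c(resD, rangeResolution(mD))
      resI <- c(resI, rangeResolution(mI))
      margD <- if (is.null(margD)) mD / length(splits) else
        margD + mD / length(splits)
      margI <- if (is.null(margI)) mI / length(splits) else
        margI + mI / length(splits)
      if (!is.null(dispCache)) {
        pl <- vapply(dispCache, `[[`, numeric(1), "perLineage")
        oc <- vapply(dispCache, `[[`, numeric(1), "oceanicPct")
        plD <- c(plD, groupScalar(modelSet, dep, pl))
        plI <- c(plI, groupScalar(modelSet, ind, pl))
        ocD <- c(ocD, groupScalar(modelSet, dep, oc))
        ocI <- c(ocI, groupScalar(modelSet, ind, oc))
      }
    }
    out <- list(disagreement = mean(dis),
                resolutionDep = mean(resD), resolutionIndep = mean(resI),
                margDep = margD, margIndep = margI)
    if (!is.null(dispCache))
      out <- c(out, list(perLineageDep = mean(plD),
                         perLineageIndep = mean(plI),
                         oceanicPctDep = mean(ocD),
                         oceanicPctIndep = mean(ocI)))
    out
  }

  list(trait = oneComparison("traitDep", "traitIndep"),
       distance = oneComparison("distDep", "distIndep"))
}
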