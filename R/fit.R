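#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 lnL + 2k + 2k(k+1)/(n-k-1)`, with n the number of tips
#' (the convention of the biogeographic software this mirrors).
#'
#' @param lnL log-likelihood.
#' @param k number of free parameters.
#' @param n sample size (tips); must exceed `k + 1`.
#' @return scalar AICc.
#' @examples
#' aicc(-100, 2, 50)  # 204 + 12/47
#' @export
aicc <- function(lnL, k, n) {
  if (n <= k + 1) stopf("AICc undefined for n <= k + 1 (n=%g, k=%g)", n, k)
  -2 * lnL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' AICc weights for a set of candidate models
#'
#' `w_i = exp(-Delta_i / 2) / sum_j exp(-Delta_j / 2)` with
#' `Delta_i = AICc_i - min AICc`.
#'
#' @param aiccValues numeric vector of AICc values (names preserved).
#' @return weights summing to 1.
#' @examples
#' modelWeights(c(m1 = 100, m2 = 102))
#' @export
modelWeights <- function(aiccValues) {
  d <- aiccValues - min(aiccValues)
  w <- exp(-d / 2)
  w / sum(w)
}

# parameter bounds and optimizer transforms -------------------------------

paramBounds <- list(d = c(1e-9, 5), e = c(1e-9, 5), t = c(1e-9, 5),
                    m2 = c(1e-4, 100), x = c(-5, 5))
logScaleParams <- c("d", "e", "t", "m2")

freeParamsFor <- function(spec) {
  p <- c("d", "e")
  if (isTRUE(spec$hasX)) p <- c(p, "x")
  if (isTRUE(spec$hasM2)) p <- c(p, "m2", "t")
  setdiff(p, names(spec$fixed))
}

defaultStart <- c(d = 0.01, e = 0.01, x = 0, m2 = 1, t = 0.1)

toTheta <- function(params, free) {
  th <- params[free]
  ls <- intersect(free, logScaleParams)
  th[ls] <- log(th[ls])
  th
}

fromTheta <- function(theta, free) {
  p <- theta
  names(p) <- free
  ls <- intersect(free, logScaleParams)
  p[ls] <- exp(p[ls])
  p
}

#' Fit a DEC-family model by bounded maximum likelihood
#'
#' Derivative-free (Nelder-Mead on log-transformed rates, with a penalty
#' outside the bounds d,e,t in \[1e-9, 5\], m2 in \[1e-4, 100\], x in
#' \[-5, 5\]) with three deterministic starts: a default start and the
#' default with d and e multiplied and divided by 10.
#'
#' @param dataset a [BiogeoDataset-class].
#' @param spec a [modelSpec()].
#' @param start optional named vector overriding the default start.
#' @param nStarts number of multi-starts (1-3).
#' @param control passed to [stats::optim()] (`reltol` defaults to 1e-8,
#'   `maxit` to 2000).
#' @return a [BiogeoFit-class] with cached pruning context.
#' @export
fitModel <- function(dataset, spec, start = NULL, nStarts = 3,
                     control = list()) {
  ctx <- pruneContext(dataset, spec)
  free <- freeParamsFor(spec)
  fixed <- unlist(spec$fixed)
  s0 <- defaultStart
  if (!is.null(start)) s0[names(start)] <- start
  starts <- list(s0)
  if (nStarts >= 2) { s <- s0; s[c("d", "e")] <- s0[c("d", "e")] * 10
                      starts <- c(starts, list(s)) }
  if (nStarts >= 3) { s <- s0; s[c("d", "e")] <- s0[c("d", "e")] / 10
                      starts <- c(starts, list(s)) }
  ctrl <- utils::modifyList(list(reltol = 1e-8, maxit = 2000), control)

  nll <- function(theta) {
    p <- fromTheta(theta, free)
    for (nm in free) {
      b <- paramBounds[[nm]]
      if (p[nm] < b[1] || p[nm] > b[2])
        return(1e10 + abs(theta[match(nm, free)]))
    }
    ll <- ctxLoglik(ctx, c(p, fixed))
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  best <- NULL
  fails <- 0L
  for (s in starts) {
    th0 <- toTheta(pmin(pmax(s, vapply(names(s), function(n)
      paramBounds[[n]][1], 0)), vapply(names(s), function(n)
      paramBounds[[n]][2], 0))[free], free)
    opt <- tryCatch(
      if (length(free) == 1) {
        b <- paramBounds[[free]]
        if (free %in% logScaleParams) b <- log(b)
        stats::optim(th0, nll, method = "Brent", lower = b[1],
                     upper = b[2], control = ctrl[names(ctrl) != "reltol"])
      } else {
        stats::optim(th0, nll, method = "Nelder-Mead", control = ctrl)
      },
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value) || opt$value >= 1e10) {
      fails <- fails + 1L
      next
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stopf("all %d optimizer starts failed for %s", length(starts),
          modelLabel(spec))
  params <- fromTheta(best$par, free)
  params <- c(params, fixed)
  full <- ctxLoglik(ctx, params, full = TRUE)
  lnL <- full$loglik
  k <- length(free)
  n <- nTips(dataset)
  methods::new("BiogeoFit", modelSpec = spec, params = params, lnL = lnL,
               k = as.integer(k), AICc = aicc(lnL, k, n),
               convergence = list(code = best$convergence,
                                  evals = best$counts[["function"]],
                                  failedStarts = fails),
               cache = list(ctx = ctx, B = full$B, U = full$U,
                            Qs = full$Qs))
}

#' Likelihood evaluation at fixed parameters, packaged as a fit
#'
#' Builds a [BiogeoFit-class] without optimization, so downstream
#' reconstruction and stochastic mapping can be run under known (for
#' example, simulated) parameter values. `k` is set to 0 (no parameters
#' were estimated).
#'
#' @inheritParams fitModel
#' @param params named parameter vector.
#' @return a [BiogeoFit-class].
#' @export
fixedFit <- function(dataset, spec, params) {
  checkParams(params)
  ctx <- pruneContext(dataset, spec)
  params <- unlist(params)
  full <- ctxLoglik(ctx, params, full = TRUE)
  if (!is.finite(full$loglik)) stopf("non-finite likelihood at given params")
  methods::new("BiogeoFit", modelSpec = spec, params = params,
               lnL = full$loglik, k = 0L,
               AICc = aicc(full$loglik, 0, nTips(dataset)),
               convergence = list(code = NA_integer_),
               cache = list(ctx = ctx, B = full$B, U = full$U,
                            Qs = full$Qs))
}

#' Select the best base model and MDMM scenario
#'
#' Fits the nine trait- and distance-independent combinations (DEC,
#' DIVALIKE, BAYAREALIKE x equal/half/tenth MDMM) and returns the
#' combination with the highest AICc weight. Ties (within 1e-9 AICc) break
#' toward fewer effective assumptions: the equal-weight MDMM first, then
#' DEC before DIVALIKE before BAYAREALIKE.
#'
#' @param dataset a [BiogeoDataset-class].
#' @param models candidate cladogenesis schemes, in tie-break order.
#' @param scenarios candidate MDMM scenarios, in tie-break order.
#' @param nStarts multi-starts per fit.
#' @return list with `base`, `mdmm`, `fits` (named list of
#'   [BiogeoFit-class]), `weights`.
#' @export
selectBaseModel <- function(dataset,
                            models = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                            scenarios = c("equal", "half", "tenth"),
                            nStarts = 3) {
  fits <- list()
  for (sc in scenarios)
    for (mo in models)
      fits[[paste(mo, sc, sep = "/")]] <-
        fitModel(dataset, modelSpec(mo, mdmm = sc), nStarts = nStarts)
  av <- vapply(fits, methods::slot, numeric(1), "AICc")
  # ties within the optimizer's convergence tolerance break toward the
  # candidate listed first (equal MDMM, then DEC)
  best <- 1L
  for (i in seq_along(av)) if (av[i] < av[best] - 1e-6) best <- i
  pick <- strsplit(names(fits)[best], "/")[[1]]
  list(base = pick[1], mdmm = pick[2], fits = fits,
       weights = modelWeights(av))
}

#' Fit the 10-model candidate set for one trait factor
#'
#' On the chosen base model and MDMM, fits the trait-independent pair
#' (base, +x) once and the trait-dependent pair (+m2, +m2x) under each of
#' the four binarization splits; AICc weights are normalized over all ten
#' models. The base fit's d and e seed the other starts.
#'
#' @param dataset a [BiogeoDataset-class].
#' @param trait trait factor column in `traitTable(dataset)`.
#' @param base base cladogenesis scheme (from [selectBaseModel()]).
#' @param mdmm MDMM scenario id.
#' @param splits binarization split ids.
#' @param nStarts multi-starts per fit.
#' @return a [BiogeoModelSet-class].
#' @export
fitModelSet <- function(dataset, trait, base = "DEC", mdmm = "equal",
                        splits = c("median", "first25", "last25",
                                   "extreme50"), nStarts = 3) {
  if (!trait %in% colnames(dataset@traits))
    stopf("trait column '%s' not in dataset", trait)
  fits <- list()
  fits[["base"]] <- fitModel(dataset, modelSpec(base, mdmm = mdmm),
                             nStarts = nStarts)
  warm <- fits[["base"]]@params[c("d", "e")]
  fits[["+x"]] <- fitModel(dataset, modelSpec(base, hasX = TRUE,
                                              mdmm = mdmm),
                           start = warm, nStarts = nStarts)
  for (sp in splits) {
    fm2 <- fitModel(dataset, modelSpec(base, hasM2 = TRUE, split = sp,
                                       mdmm = mdmm, trait = trait),
                    start = warm, nStarts = nStarts)
    fits[[paste0("+m2[", sp, "]")]] <- fm2
    # seed the joint trait+distance model from the trait-only optimum
    fits[[paste0("+m2x[", sp, "]")]] <-
      fitModel(dataset, modelSpec(base, hasX = TRUE, hasM2 = TRUE,
                                  split = sp, mdmm = mdmm, trait = trait),
               start = fm2@params, nStarts = nStarts)
  }
  av <- vapply(fits, methods::slot, numeric(1), "AICc")
  methods::new("BiogeoModelSet", fits = fits, weights = modelWeights(av),
               baseModel = base, mdmm = mdmm, trait = trait,
               dataset = dataset)
}

#' Relative AICc weight of trait-dependent models
#'
#' With `method = "per_split"` (default), the trait-dependent weight is
#' computed within each binarization split's four-model subset
#' \{base, +x, +m2, +m2x\} — the sum of the +m2 and +m2x weights after
#' renormalizing AICc weights over those four — and averaged across the
#' splits. This two-vs-two construction puts equal prior mass on the
#' trait-dependent and trait-independent alternatives; the alternative
#' `"joint"` sum over the full ten-model set compares eight trait models
#' against two and therefore overstates trait support when the trait has
#' no effect.
#'
#' @param modelSet a [BiogeoModelSet-class].
#' @param method `"per_split"` or `"joint"`.
#' @return scalar in \[0, 1\].
#' @export
traitDependentWeight <- function(modelSet,
                                 method = c("per_split", "joint")) {
  method <- match.arg(method)
  dep <- vapply(modelSet@fits, function(f) isTRUE(f@modelSpec$hasM2),
                logical(1))
  if (method == "joint") return(sum(modelSet@weights[dep]))
  av <- vapply(modelSet@fits, methods::slot, numeric(1), "AICc")
  splits <- setSplits(modelSet)
  mean(vapply(splits, function(sp) {
    mem <- vapply(modelSet@fits, function(f) {
      s <- f@modelSpec$split
      is.null(s) || identical(s, sp)
    }, logical(1))
    w <- modelWeights(av[mem])
    sum(w[dep[mem]])
  }, numeric(1)))
}
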