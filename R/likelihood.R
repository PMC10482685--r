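#' Model specification for a DEC-family fit
#'
#' @param base cladogenesis scheme: `"DEC"`, `"DIVALIKE"` or
#'   `"BAYAREALIKE"`.
#' @param hasX include the distance exponent x as a free parameter?
#' @param hasM2 include binary-trait-dependent dispersal (free `m2` and
#'   trait switch rate `t`; the state-1 multiplier is fixed at 1)?
#' @param split binarization split id (`"median"`, `"first25"`, `"last25"`,
#'   `"extreme50"`) — or a named integer vector of explicit tip trait
#'   states (1/2, `NA` = ambiguous) for simulation and validation work;
#'   required when `hasM2`.
#' @param mdmm MDMM scenario: `"equal"`, `"half"`, `"tenth"`, or `"custom"`
#'   to use the dataset epochs' own multiplier matrices.
#' @param trait trait factor column name (required when `hasM2`).
#' @param fixed named list of parameters to hold fixed during fitting.
#' @return list understood by [computeLogLik()] and [fitModel()].
#' @export
modelSpec <- function(base = c("DEC", "DIVALIKE", "BAYAREALIKE"),
                      hasX = FALSE, hasM2 = FALSE, split = NULL,
                      mdmm = "equal", trait = NULL, fixed = list()) {
  base <- match.arg(base)
  if (hasM2 && is.null(split))
    stopf("trait-dependent models need a binarization split id (or explicit tip states)")
  if (hasM2 && is.character(split) && is.null(trait))
    stopf("trait-dependent models need a trait column")
  list(base = base, hasX = hasX, hasM2 = hasM2, split = split,
       mdmm = mdmm, trait = trait, fixed = fixed)
}

# Replace epoch MDMMs by a named scenario built from the barrier matrix.
epochsForSpec <- function(dataset, spec) {
  ep <- dataset@epochs
  if (!is.null(spec$mdmm) && spec$mdmm %in% c("equal", "half", "tenth")) {
    m <- mdmmScenario(spec$mdmm, dataset@barriers)
    ep <- lapply(ep, function(sl) { sl$mdmm <- m; sl })
  }
  ep
}

# Per-edge time slices: matrix with columns (duration, epoch index),
# ordered young -> old along the branch.
edgeSegments <- function(tree, epochs) {
  ages <- nodeAges(tree)
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  lapply(seq_len(nrow(tree$edge)), function(e) {
    aC <- ages[tree$edge[e, 2]]
    aP <- ages[tree$edge[e, 1]]
    if (aP < aC) aP <- aC
    lo <- aC
    segs <- NULL
    for (i in seq_along(epochs)) {
      hi <- min(ends[i], aP)
      if (hi > lo + 1e-12) {
        segs <- rbind(segs, c(hi - lo, i))
        lo <- hi
      }
      if (lo >= aP - 1e-12) break
    }
    if (is.null(segs)) segs <- matrix(c(0, epochOf(aC, epochs)), 1, 2)
    segs
  })
}

epochOf <- function(age, epochs) {
  ends <- vapply(epochs, `[[`, numeric(1), "end")
  i <- which(age <= ends + 1e-9)[1]
  if (is.na(i)) length(epochs) else i
}

# S x nEpoch indicator: state allowed iff every occupied area allowed.
stateAllowedMatrix <- function(stateSpace, epochs) {
  A <- length(stateSpace@areas)
  R <- length(stateSpace@masks)
  out <- vapply(epochs, function(sl) {
    ok <- vapply(stateSpace@masks, function(m)
      all(sl$allowed[maskAreas(m, A)]) || m == 0L, logical(1))
    if (stateSpace@traitAugmented) ok <- c(ok, ok)
    ok
  }, logical(nStates(stateSpace)))
  matrix(as.integer(out), nrow = nStates(stateSpace))
}

# Uniform root prior over allowed non-null states (x trait states),
# using the oldest epoch's allowed-area mask.
rootPriorFor <- function(stateSpace, epochs) {
  allowed <- stateAllowedMatrix(stateSpace, epochs)[, length(epochs)]
  R <- length(stateSpace@masks)
  nonnull <- rep(stateSpace@masks != 0L,
                 if (stateSpace@traitAugmented) 2 else 1)
  pri <- as.numeric(allowed == 1L & nonnull)
  pri / sum(pri)
}

# Observed binary trait states (1/2/NA) per tip, in tree tip order. The
# split is normally a binarization id; a named integer vector of explicit
# states (1/2/NA) is accepted for simulation and validation work.
traitTipStates <- function(dataset, spec) {
  if (is.numeric(spec$split)) {
    st <- rep(NA_integer_, nTips(dataset))
    names(st) <- dataset@tree$tip.label
    st[names(spec$split)] <- as.integer(spec$split)
    return(st)
  }
  scores <- dataset@traits[[spec$trait]]
  names(scores) <- rownames(dataset@traits)
  bin <- binarizeFactor(scores, spec$split)
  bin$states[dataset@tree$tip.label]
}

# Log-likelihood of the observed binary trait states alone under the
# symmetric two-state switch chain at rate t (uniform root prior). Used to
# condition the trait-augmented likelihood on the trait data, so that
# trait-dependent and trait-independent models describe the same data
# (the geographic ranges, given the traits): with m2 = 1 the joint
# likelihood factorizes and the conditional equals the base model exactly.
traitOnlyLnL <- function(ctx, tsw) {
  st <- ctx$traitStates
  tree <- ctx$tree
  nTip <- ctx$nTip
  nTotal <- 2 * nTip - 1
  up <- matrix(1, 2, nTotal)
  for (i in seq_len(nTip)) if (!is.na(st[i])) {
    up[, i] <- 0; up[st[i], i] <- 1
  }
  logs <- 0
  msg <- matrix(1, 2, nrow(tree$edge))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    b <- up[, v]
    if (v > nTip) {
      s <- sum(b)
      if (s <= 0) return(-Inf)
      b <- b / s
      logs <- logs + log(s)
    }
    a <- (1 + exp(-2 * tsw * tree$edge.length[e])) / 2
    m <- c(a * b[1] + (1 - a) * b[2], (1 - a) * b[1] + a * b[2])
    up[, p] <- up[, p] * m
  }
  root <- tree$edge[nrow(tree$edge), 1]
  z <- sum(0.5 * up[, root])
  if (z <= 0) return(-Inf)
  log(z) + logs
}

# Tip partial vectors: indicator of the observed range (x binary trait
# state from the binarization; ambiguous trait = 1 in both blocks).
tipPartialsFor <- function(dataset, stateSpace, spec) {
  tree <- dataset@tree
  A <- length(stateSpace@areas)
  R <- length(stateSpace@masks)
  S <- nStates(stateSpace)
  idx <- integer(2 ^ A)
  idx[stateSpace@masks + 1L] <- seq_len(R)
  n <- ape::Ntip(tree)
  P <- matrix(0, S, n)
  pres <- dataset@presence[tree$tip.label, , drop = FALSE]
  rmask <- as.integer(pres %*% bitwShiftL(1L, seq_len(A) - 1L))
  ri <- idx[rmask + 1L]
  if (any(ri == 0L))
    stopf("tip range exceeds maxRangeSize: %s",
          tree$tip.label[which(ri == 0L)[1]])
  if (stateSpace@traitAugmented) {
    st <- traitTipStates(dataset, spec)[tree$tip.label]
    for (i in seq_len(n)) {
      if (is.na(st[i])) {
        P[ri[i], i] <- 1; P[R + ri[i], i] <- 1
      } else {
        P[(st[i] - 1L) * R + ri[i], i] <- 1
      }
    }
  } else {
    P[cbind(ri, seq_len(n))] <- 1
  }
  P
}

# Static pruning context for one model specification; parameters enter
# only through the per-epoch rate matrices assembled at evaluation time.
pruneContext <- function(dataset, spec) {
  epochs <- epochsForSpec(dataset, spec)
  ss <- enumerateRanges(areaNames(dataset),
                        maxRangeSize = dataset@metadata$maxRangeSize %||%
                          length(areaNames(dataset)),
                        traitAugmented = isTRUE(spec$hasM2))
  clado <- cladogenesisTable(spec$base, ss)
  tp <- postorderEdges(dataset@tree)
  trSt <- if (isTRUE(spec$hasM2))
    traitTipStates(dataset, spec)[tp$tip.label] else NULL
  list(dataset = dataset, spec = spec, epochs = epochs, stateSpace = ss,
       clado = clado, tree = tp, edge = tp$edge, traitStates = trSt,
       edgeSegs = edgeSegments(tp, epochs),
       allowed = stateAllowedMatrix(ss, epochs),
       tipPartials = tipPartialsFor(dataset, ss, spec),
       rootPrior = rootPriorFor(ss, epochs),
       distances = dataset@distances, nTip = ape::Ntip(tp))
}

# Assemble the per-epoch generator stack for a parameter vector.
ctxQs <- function(ctx, params) {
  S <- nStates(ctx$stateSpace)
  Qs <- array(0, c(S, S, length(ctx$epochs)))
  for (i in seq_along(ctx$epochs))
    Qs[, , i] <- buildRateMatrix(ctx$stateSpace, params, ctx$epochs[[i]],
                                 ctx$distances)
  Qs
}

checkParams <- function(params) {
  p <- as.list(params)
  if (is.null(p$d) || is.null(p$e)) stopf("params must include d and e")
  if (p$d < 0 || p$e < 0) stopf("d and e must be non-negative")
  if (!is.null(p$t) && p$t < 0) stopf("trait switch rate t must be >= 0")
  if (!is.null(p$m2) && p$m2 <= 0) stopf("m2 must be positive")
  if (!is.null(p$x) && !is.finite(p$x)) stopf("x must be finite")
  invisible(p)
}

ctxLoglik <- function(ctx, params, full = FALSE) {
  Qs <- ctxQs(ctx, params)
  res <- pruneLoglikCpp(ctx$edge, ctx$edgeSegs, Qs, ctx$allowed,
                        as.matrix(ctx$clado[, c("anc", "left", "right")]),
                        ctx$clado$prob, ctx$tipPartials, ctx$rootPrior,
                        ctx$nTip)
  if (isTRUE(ctx$spec$hasM2)) {
    # condition on the observed trait states so every candidate model
    # describes the same data (ranges given traits); exact factorization
    # makes this equal the base model when m2 = 1
    tl <- traitOnlyLnL(ctx, as.list(params)$t %||% 0)
    res$loglik <- if (is.finite(tl)) res$loglik - tl else -Inf
  }
  if (full) c(res, list(Qs = Qs)) else res$loglik
}

#' Phylogenetic log-likelihood of a DEC-family model
#'
#' Felsenstein pruning over the range (x trait) state space: tip partials
#' are indicator vectors (ambiguity = 1 over all compatible states), branch
#' propagation uses the matrix exponential of the epoch-specific generator
#' per time segment, internal nodes combine daughters through the
#' cladogenesis table, and the root sums over a uniform prior on allowed
#' non-null states. Per-node rescaling guards against underflow.
#'
#' Trait-dependent models (`hasM2`) report the likelihood of the ranges
#' conditional on the observed binary trait states: the joint
#' trait-augmented pruning likelihood minus the likelihood of the trait
#' data alone under the same two-state switch chain. This keeps all ten
#' candidate models comparable (they all describe the geographic data),
#' and reduces exactly to the trait-independent base model when `m2 = 1`.
#'
#' @param dataset a [BiogeoDataset-class].
#' @param spec a [modelSpec()].
#' @param params named vector/list with `d`, `e` and, as applicable, `x`,
#'   `m2`, `t`.
#' @return log-likelihood (scalar); `-Inf` flags an invalid parameter
#'   combination.
#' @examples
#' ds <- twoTipDataset()
#' computeLogLik(ds, modelSpec("DEC"), c(d = 0, e = 0))  # log(1/3)
#' @export
computeLogLik <- function(dataset, spec, params) {
  checkParams(params)
  ctx <- pruneContext(dataset, spec)
  ctxLoglik(ctx, params)
}

#' Minimal two-tip example dataset
#'
#' Two sister species 1 My apart, both restricted to area A of a two-area
#' system. Under DEC with d = e = 0 the only consistent history keeps the
#' root in A, and with the uniform root prior over \{A, B, AB\} the
#' log-likelihood is exactly `log(1/3)`.
#'
#' @return a [BiogeoDataset-class].
#' @export
twoTipDataset <- function() {
  tr <- ape::read.tree(text = "(t1:1,t2:1);")
  pres <- matrix(c(1L, 0L, 1L, 0L), 2, 2, byrow = TRUE,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  D <- matrix(c(0, 1000, 1000, 0), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  B <- matrix(c("self", "oceanic", "oceanic", "self"), 2, 2,
              dimnames = dimnames(D))
  buildDataset(tr, pres, D, B, clade = "twoTip")
}
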