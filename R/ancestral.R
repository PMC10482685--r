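# Per-epoch spectral propagators recomputed in R for the down-pass and for
# stochastic mapping; falls back to Matrix::expm when the generator is
# ill-conditioned for eigendecomposition.
epochPropagators <- function(ctx, Qs) {
  lapply(seq_len(dim(Qs)[3]), function(i) {
    Q <- Qs[, , i]
    eg <- tryCatch(eigen(Q), error = function(e) NULL)
    ok <- !is.null(eg)
    Vi <- NULL
    if (ok) {
      Vi <- tryCatch(solve(eg$vectors), error = function(e) NULL)
      ok <- !is.null(Vi)
    }
    if (ok) {
      # reject near-defective decompositions by reconstruction residual
      rec <- Re(eg$vectors %*% (eg$values * Vi))
      ok <- sqrt(sum((rec - Q)^2)) / (sqrt(sum(Q^2)) + 1e-300) < 1e-10
    }
    if (ok) {
      list(expm = FALSE, V = eg$vectors, Vi = Vi, lam = eg$values)
    } else {
      list(expm = TRUE, Q = Q)
    }
  })
}

segmentP <- function(prop, t) {
  if (t <= 0) return(NULL)
  if (prop$expm) {
    P <- as.matrix(Matrix::expm(prop$Q * t))
  } else {
    P <- Re(prop$V %*% (exp(prop$lam * t) * prop$Vi))
  }
  P[P < 0] <- 0
  P
}

# Per-edge list of per-segment transition matrices (young -> old segment
# order, matching pruneContext$edgeSegs).
edgeSegmentPs <- function(ctx, Qs) {
  props <- epochPropagators(ctx, Qs)
  lapply(ctx$edgeSegs, function(segs)
    lapply(seq_len(nrow(segs)), function(i)
      segmentP(props[[segs[i, 2]]], segs[i, 1])))
}

# child-edge indices per internal node, in the order the pruning pass
# encountered them (defines left/right for the cladogenesis table)
childEdgeList <- function(ctx) {
  nTotal <- ctx$nTip * 2 - 1
  ce <- vector("list", nTotal)
  for (e in seq_len(nrow(ctx$edge))) {
    p <- ctx$edge[e, 1]
    ce[[p]] <- c(ce[[p]], e)
  }
  ce
}

#' Marginal ancestral state probabilities at internal nodes
#'
#' Standard two-pass marginal reconstruction: the cached pruning (tip-to-
#' root) partials are combined with a root-to-node flow through the
#' cladogenesis table, giving, for every internal node, the posterior
#' probability of each state immediately before cladogenesis.
#'
#' @param fit a [BiogeoFit-class] (from [fitModel()] or [fixedFit()]).
#' @return matrix, internal nodes (ape numbering, rownames) x states
#'   (labels); rows sum to 1.
#' @export
ancestralMarginals <- function(fit) {
  ctx <- fit@cache$ctx
  B <- fit@cache$B
  U <- fit@cache$U
  Qs <- fit@cache$Qs
  S <- nStates(ctx$stateSpace)
  nTip <- ctx$nTip
  nTotal <- 2 * nTip - 1
  segPs <- edgeSegmentPs(ctx, Qs)
  ce <- childEdgeList(ctx)
  root <- ctx$edge[nrow(ctx$edge), 1]
  D <- matrix(0, S, nTotal)
  D[, root] <- ctx$rootPrior
  clado <- ctx$clado
  # parent-before-child order = reverse postorder
  for (e in rev(seq_len(nrow(ctx$edge)))) {
    u <- ctx$edge[e, 1]
    v <- ctx$edge[e, 2]
    sib <- setdiff(ce[[u]], e)
    isLeft <- ce[[u]][1] == e
    uSib <- U[, sib]
    du <- D[, u]
    M <- numeric(S)
    if (isLeft) {
      w <- clado$prob * du[clado$anc] * uSib[clado$right]
      acc <- rowsum(w, clado$left)
    } else {
      w <- clado$prob * du[clado$anc] * uSib[clado$left]
      acc <- rowsum(w, clado$right)
    }
    M[as.integer(rownames(acc))] <- acc[, 1]
    # propagate old -> young through the branch segments
    segs <- ctx$edgeSegs[[e]]
    for (i in rev(seq_len(nrow(segs)))) {
      P <- segPs[[e]][[i]]
      if (!is.null(P)) M <- as.numeric(M %*% P)
      if (i > 1) M[ctx$allowed[, segs[i, 2]] == 0L] <- 0
    }
    s <- sum(M)
    D[, v] <- if (s > 0) M / s else M
  }
  internal <- (nTip + 1):nTotal
  marg <- t(vapply(internal, function(v) {
    m <- D[, v] * B[, v]
    m / sum(m)
  }, numeric(S)))
  dimnames(marg) <- list(internal, stateLabels(ctx$stateSpace))
  marg
}

#' Collapse trait-augmented state marginals to range marginals
#'
#' @param marginals matrix from [ancestralMarginals()].
#' @param stateSpace the [RangeStateSpace-class] the marginals live on.
#' @return matrix over ranges (trait axis summed out, if present).
#' @export
rangeMarginals <- function(marginals, stateSpace) {
  R <- nRanges(stateSpace)
  if (!stateSpace@traitAugmented) return(marginals)
  out <- marginals[, seq_len(R), drop = FALSE] +
    marginals[, R + seq_len(R), drop = FALSE]
  colnames(out) <- stateLabels(stateSpace)[seq_len(R)]
  out
}

#' Resolution of an ancestral-range reconstruction
#'
#' The mean, over internal nodes, of the probability of the most likely
#' range at each node: 1 means every node is reconstructed with certainty,
#' 1/S is the uniform floor over S states.
#'
#' @param marginals matrix of per-node probability vectors (rows sum to 1),
#'   e.g. from [ancestralMarginals()], possibly range-collapsed.
#' @return scalar in (0, 1\].
#' @examples
#' rangeResolution(rbind(c(0.5, 0.5, 0), c(0.9, 0.05, 0.05)))  # 0.7
#' @export
rangeResolution <- function(marginals) {
  if (nrow(marginals) < 1) stopf("need at least one internal node")
  mean(apply(marginals, 1, max))
}
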