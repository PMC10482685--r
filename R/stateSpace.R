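#' Enumerate geographic range states
#'
#' Builds the ordered state space over `A` areas: the null range first, then
#' ranges by increasing size, lexicographically within a size class (AB
#' before AC before BC). With `traitAugmented = TRUE` every range is crossed
#' with a binary trait axis; all `s1` states precede all `s2` states.
#'
#' @param areas character vector of area names (A <= 10 unless `guard`
#'   raised; the state count grows as 2^A).
#' @param maxRangeSize largest allowed range size (default: all areas).
#' @param traitAugmented add the binary trait axis?
#' @param guard maximum number of areas accepted (state-space guard).
#' @return a [RangeStateSpace-class].
#' @examples
#' enumerateRanges(c("A", "B", "C"))
#' @export
enumerateRanges <- function(areas, maxRangeSize = length(areas),
                            traitAugmented = FALSE, guard = 10L) {
  A <- length(areas)
  if (A < 1) stopf("need at least one area")
  if (A > guard)
    stopf("%d areas exceeds the state-space guard (%d); raise `guard` to override",
          A, guard)
  if (maxRangeSize < 1 || maxRangeSize > A)
    stopf("maxRangeSize must lie in [1, %d]", A)
  masks <- 0L
  for (k in seq_len(maxRangeSize)) {
    combs <- utils::combn(A, k)
    # lexicographic order on area-index tuples = column order of combn
    masks <- c(masks, apply(combs, 2, function(ix) sum(bitwShiftL(1L,
                                                                  ix - 1L))))
  }
  masks <- as.integer(masks)
  rangeLab <- vapply(masks, function(m) {
    if (m == 0L) "_" else paste(areas[bitwAnd(bitwShiftR(m,
      seq_len(A) - 1L), 1L) == 1L], collapse = "")
  }, character(1))
  labels <- if (traitAugmented)
    c(paste0(rangeLab, "|s1"), paste0(rangeLab, "|s2")) else rangeLab
  methods::new("RangeStateSpace", areas = areas, masks = masks,
               maxRangeSize = as.integer(maxRangeSize),
               traitAugmented = traitAugmented, labels = labels)
}

# areas (integer indices) contained in a bitmask
maskAreas <- function(mask, A) {
  which(bitwAnd(bitwShiftR(mask, seq_len(A) - 1L), 1L) == 1L)
}

#' Distance- and barrier-modulated dispersal weight between two areas
#'
#' The per-pair multiplier on the dispersal rate d:
#' `MDMM[j,k] * (D[j,k] / Dbar)^x`, where `Dbar` is the mean off-diagonal
#' distance. Normalizing by `Dbar` keeps d on a comparable scale across
#' positive and negative exponents. The weight is 0 if the target area is
#' disallowed in the epoch.
#'
#' @param j,k source and target area indices (j != k).
#' @param epoch epoch slice (`list(mdmm=, allowed=, ...)`).
#' @param distances inter-area distance matrix (km).
#' @param x distance exponent (0 = distance-independent).
#' @return non-negative scalar.
#' @export
dispersalWeight <- function(j, k, epoch, distances, x = 0) {
  if (j == k) stopf("dispersal weight needs two distinct areas")
  if (!epoch$allowed[k]) return(0)
  w <- epoch$mdmm[j, k]
  if (x != 0) {
    D <- distances[j, k]
    if (D == 0)
      stopf("zero distance between areas %d and %d with x != 0", j, k)
    dbar <- mean(distances[row(distances) != col(distances)])
    w <- w * (D / dbar) ^ x
  }
  w
}

# Full A x A weight matrix for one epoch (vectorized dispersalWeight).
weightMatrix <- function(epoch, distances, x = 0) {
  A <- nrow(distances)
  W <- epoch$mdmm
  diag(W) <- 0
  if (x != 0) {
    off <- row(distances) != col(distances)
    if (any(distances[off] == 0))
      stopf("zero off-diagonal distance with x != 0")
    dbar <- mean(distances[off])
    S <- (distances / dbar) ^ x
    diag(S) <- 0
    W <- W * S
  }
  W[, !epoch$allowed] <- 0
  W
}

#' Anagenetic rate matrix over range (x trait) states
#'
#' Builds the CTMC generator for one epoch: range expansion
#' `r -> r + {k}` at rate `m_trait * d * sum_{j in r} w(j,k)`, range
#' contraction `r -> r - {j}` at rate `e` per occupied area (a single-area
#' range contracts into the absorbing null range), and, for trait-augmented
#' spaces, symmetric trait switching at rate `t`. Rows sum to zero.
#'
#' @param stateSpace a [RangeStateSpace-class].
#' @param params named list/vector with `d`, `e` and optionally `x`, `m2`,
#'   `t` (defaults 0, 1, 0).
#' @param epoch epoch slice (`list(mdmm=, allowed=, ...)`).
#' @param distances inter-area distance matrix.
#' @return dense numeric generator matrix with state labels.
#' @export
buildRateMatrix <- function(stateSpace, params, epoch, distances) {
  p <- as.list(params)
  d <- p$d; e <- p$e
  x <- p$x %||% 0; m2 <- p$m2 %||% 1; tsw <- p$t %||% 0
  A <- length(stateSpace@areas)
  masks <- stateSpace@masks
  R <- length(masks)
  idx <- integer(2 ^ A); idx[masks + 1L] <- seq_len(R)
  W <- weightMatrix(epoch, distances, x)
  base <- matrix(0, R, R)   # range process with unit trait multiplier
  disp <- matrix(0, R, R)   # dispersal part only (scaled by m_trait)
  for (i in seq_len(R)) {
    m <- masks[i]
    if (m == 0L) next       # null range absorbing
    occ <- maskAreas(m, A)
    if (length(occ) < stateSpace@maxRangeSize) {
      for (k in setdiff(seq_len(A), occ)) {
        tgt <- idx[bitwOr(m, bitwShiftL(1L, k - 1L)) + 1L]
        if (tgt == 0L) next
        rate <- d * sum(W[occ, k])
        disp[i, tgt] <- disp[i, tgt] + rate
      }
    }
    for (j in occ) {
      tgt <- idx[bitwAnd(m, bitwNot(bitwShiftL(1L, j - 1L))) + 1L]
      base[i, tgt] <- base[i, tgt] + e
    }
  }
  if (stateSpace@traitAugmented) {
    Q <- matrix(0, 2 * R, 2 * R)
    Q[seq_len(R), seq_len(R)] <- base + disp
    Q[R + seq_len(R), R + seq_len(R)] <- base + m2 * disp
    nonnull <- masks != 0L
    swIdx <- which(nonnull)
    for (i in swIdx) {
      Q[i, R + i] <- tsw
      Q[R + i, i] <- tsw
    }
  } else {
    Q <- base + disp
  }
  diag(Q) <- diag(Q) - rowSums(Q)
  dimnames(Q) <- list(stateSpace@labels, stateSpace@labels)
  Q
}

#' Cladogenesis event table
#'
#' Enumerates the allowed daughter-range scenarios at a node for each
#' ancestral range, with equal probability across a model's scenarios:
#' \describe{
#'   \item{DEC}{single-area ancestors copy; widespread ancestors split by
#'     subset sympatry (one daughter a single area `s` of the range, the
#'     other the full range) or narrow vicariance (`s` vs the remainder),
#'     over all distinct ordered daughter pairs.}
#'   \item{DIVALIKE}{single-area ancestors copy; widespread ancestors split
#'     by any ordered bipartition into two nonempty disjoint covering sets.}
#'   \item{BAYAREALIKE}{both daughters always copy the ancestor.}
#' }
#' The trait state, when present, is inherited identically by both
#' daughters. Daughters are never the null range.
#'
#' @param modelType `"DEC"`, `"DIVALIKE"` or `"BAYAREALIKE"`.
#' @param stateSpace a [RangeStateSpace-class].
#' @return data.frame with integer state-index columns `anc`, `left`,
#'   `right` and numeric `prob`; probabilities sum to 1 per ancestor.
#' @export
cladogenesisTable <- function(modelType = c("DEC", "DIVALIKE",
                                            "BAYAREALIKE"), stateSpace) {
  modelType <- match.arg(modelType)
  A <- length(stateSpace@areas)
  masks <- stateSpace@masks
  R <- length(masks)
  idx <- integer(2 ^ A); idx[masks + 1L] <- seq_len(R)
  anc <- left <- right <- integer(); prob <- numeric()
  for (i in seq_len(R)) {
    m <- masks[i]
    if (m == 0L) next
    occ <- maskAreas(m, A)
    pairs <- NULL  # matrix of (left mask, right mask)
    if (length(occ) == 1L || modelType == "BAYAREALIKE") {
      pairs <- cbind(m, m)
    } else if (modelType == "DEC") {
      for (s in occ) {
        sm <- bitwShiftL(1L, s - 1L)
        rest <- bitwAnd(m, bitwNot(sm))
        pairs <- rbind(pairs, c(sm, m), c(m, sm), c(sm, rest), c(rest, sm))
      }
      pairs <- unique(pairs)
    } else { # DIVALIKE: ordered bipartitions
      for (sub in seq_len(2 ^ length(occ) - 2)) {
        pick <- occ[bitwAnd(bitwShiftR(sub, seq_along(occ) - 1L), 1L) == 1L]
        lm <- sum(bitwShiftL(1L, pick - 1L))
        pairs <- rbind(pairs, c(lm, bitwAnd(m, bitwNot(as.integer(lm)))))
      }
    }
    keep <- idx[pairs[, 1] + 1L] > 0L & idx[pairs[, 2] + 1L] > 0L
    pairs <- pairs[keep, , drop = FALSE]
    if (nrow(pairs) == 0L)
      stopf("range %s has no cladogenetic outcome within maxRangeSize",
            stateSpace@labels[i])
    np <- nrow(pairs)
    anc <- c(anc, rep.int(i, np))
    left <- c(left, idx[pairs[, 1] + 1L])
    right <- c(right, idx[pairs[, 2] + 1L])
    prob <- c(prob, rep.int(1 / np, np))
  }
  tab <- data.frame(anc = anc, left = left, right = right, prob = prob)
  if (stateSpace@traitAugmented) {
    tab2 <- data.frame(anc = tab$anc + R, left = tab$left + R,
                       right = tab$right + R, prob = tab$prob)
    tab <- rbind(tab, tab2)
  }
  tab
}

#' Dump a rate matrix or cladogenesis table as TSV for inspection
#'
#' @param x a matrix from [buildRateMatrix()] or data.frame from
#'   [cladogenesisTable()].
#' @param path output file.
#' @param stateSpace needed to label cladogenesis states.
#' @return `path`, invisibly.
#' @export
dumpModelTable <- function(x, path, stateSpace = NULL) {
  if (is.matrix(x)) {
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  } else {
    if (!is.null(stateSpace)) {
      lab <- stateLabels(stateSpace)
      x <- data.frame(anc = lab[x$anc], left = lab[x$left],
                      right = lab[x$right], prob = x$prob)
    }
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
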