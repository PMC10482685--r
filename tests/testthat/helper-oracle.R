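# Independent brute-force oracle: exhaustive enumeration over all joint
# internal-node state/event assignments, with per-branch transition
# probabilities from Matrix::expm. Shares no code with the package's
# pruning path (own state list, own rate matrix, own cladogenesis
# enumeration, own traversal).

# states: list of list(range = integer vector of area indices, trait = 1/2)
oracleStates <- function(A, maxSize = A, traitAug = FALSE) {
  subsets <- list(integer(0))
  for (k in seq_len(A)) subsets <- c(subsets,
    lapply(seq_len(ncol(utils::combn(A, k))), function(i)
      utils::combn(A, k)[, i]))
  subsets <- Filter(function(s) length(s) <= maxSize, subsets)
  if (!traitAug) return(lapply(subsets, function(s)
    list(range = s, trait = 1L)))
  c(lapply(subsets, function(s) list(range = s, trait = 1L)),
    lapply(subsets, function(s) list(range = s, trait = 2L)))
}

oracleStateIndex <- function(states, range, trait) {
  for (i in seq_along(states))
    if (identical(sort(states[[i]]$range), sort(range)) &&
        states[[i]]$trait == trait) return(i)
  stop("state not found")
}

oracleQ <- function(states, params, mdmm, distances, maxSize) {
  d <- params[["d"]]; e <- params[["e"]]
  x <- if ("x" %in% names(params)) params[["x"]] else 0
  m2 <- if ("m2" %in% names(params)) params[["m2"]] else 1
  tsw <- if ("t" %in% names(params)) params[["t"]] else 0
  A <- nrow(mdmm)
  dbar <- mean(distances[row(distances) != col(distances)])
  n <- length(states)
  Q <- matrix(0, n, n)
  for (i in seq_len(n)) {
    si <- states[[i]]
    r <- si$range
    if (length(r) == 0) next
    mult <- if (si$trait == 2L) m2 else 1
    for (j in seq_len(n)) {
      sj <- states[[j]]
      if (sj$trait == si$trait) {
        if (length(sj$range) == length(r) + 1 && all(r %in% sj$range) &&
            length(sj$range) <= maxSize) {
          k <- setdiff(sj$range, r)
          w <- sum(vapply(r, function(jj)
            mdmm[jj, k] * (distances[jj, k] / dbar) ^ x, numeric(1)))
          Q[i, j] <- mult * d * w
        }
        if (length(sj$range) == length(r) - 1 && all(sj$range %in% r))
          Q[i, j] <- e
      } else if (identical(sort(sj$range), sort(r))) {
        Q[i, j] <- tsw
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

oracleClado <- function(model, states) {
  n <- length(states)
  out <- list()
  for (i in seq_len(n)) {
    si <- states[[i]]
    r <- si$range
    if (length(r) == 0) next
    pairs <- list()
    if (length(r) == 1 || model == "BAYAREALIKE") {
      pairs <- list(list(r, r))
    } else if (model == "DEC") {
      for (s in r) {
        rest <- setdiff(r, s)
        pairs <- c(pairs, list(list(s, r), list(r, s),
                               list(s, rest), list(rest, s)))
      }
      # drop duplicates (|r| = 2 double-counts the vicariance pairs)
      key <- vapply(pairs, function(p) paste(paste(sort(p[[1]]),
        collapse = ","), paste(sort(p[[2]]), collapse = ","), sep = "|"),
        character(1))
      pairs <- pairs[!duplicated(key)]
    } else { # DIVALIKE
      for (mset in seq_len(2 ^ length(r) - 2)) {
        pick <- r[bitwAnd(bitwShiftR(mset, seq_along(r) - 1L), 1L) == 1L]
        pairs <- c(pairs, list(list(pick, setdiff(r, pick))))
      }
    }
    for (p in pairs)
      out[[length(out) + 1]] <- list(
        anc = i,
        left = oracleStateIndex(states, p[[1]], si$trait),
        right = oracleStateIndex(states, p[[2]], si$trait),
        prob = 1 / length(pairs))
  }
  out
}

# exhaustive joint enumeration of the likelihood and node posteriors
oracleLoglik <- function(tree, tipRangeList, tipTraitList = NULL, params,
                         model = "DEC", mdmm, distances, maxSize = NULL,
                         marginals = FALSE) {
  A <- nrow(mdmm)
  if (is.null(maxSize)) maxSize <- A
  traitAug <- !is.null(tipTraitList)
  states <- oracleStates(A, maxSize, traitAug)
  nS <- length(states)
  Q <- oracleQ(states, params, mdmm, distances, maxSize)
  clado <- oracleClado(model, states)
  nTip <- ape::Ntip(tree)
  edge <- tree$edge
  Pe <- lapply(seq_len(nrow(edge)), function(e)
    as.matrix(Matrix::expm(Q * tree$edge.length[e])))
  # tip compatibility vectors
  tipOK <- matrix(FALSE, nS, nTip)
  for (i in seq_len(nTip)) {
    r <- tipRangeList[[tree$tip.label[i]]]
    tr <- if (traitAug) tipTraitList[[tree$tip.label[i]]] else 1L
    for (s in seq_len(nS))
      if (identical(sort(states[[s]]$range), sort(r)) &&
          (is.na(tr) || states[[s]]$trait == tr))
        tipOK[s, i] <- TRUE
  }
  tipFactor <- lapply(seq_len(nrow(edge)), function(e)
    if (edge[e, 2] <= nTip) Pe[[e]] %*% tipOK[, edge[e, 2]] else NULL)
  prior <- vapply(states, function(s)
    length(s$range) > 0, numeric(1))
  prior <- prior / sum(prior)
  root <- nTip + 1L
  nTotal <- nTip + tree$Nnode
  # internal nodes in parent-before-child order
  intNodes <- root
  repeat {
    more <- setdiff(edge[edge[, 1] %in% intNodes, 2], seq_len(nTip))
    more <- setdiff(more, intNodes)
    if (!length(more)) break
    intNodes <- c(intNodes, more)
  }
  ce <- lapply(seq_len(nTotal), function(u) which(edge[, 1] == u))
  nodePost <- matrix(0, nS, nTotal)
  total <- 0
  topSt <- integer(nTotal)     # branch-top state of each non-root node
  curAnc <- integer(nTotal)
  rec <- function(idx, w) {
    if (idx > length(intNodes)) {
      total <<- total + w
      if (marginals)
        for (u in intNodes)
          nodePost[curAnc[u], u] <<- nodePost[curAnc[u], u] + w
      return(invisible())
    }
    u <- intNodes[idx]
    for (ev in clado) {
      a <- ev$anc
      base <- if (u == root) prior[a] else {
        e <- which(edge[, 2] == u)
        Pe[[e]][topSt[u], a]
      }
      lw <- w * base * ev$prob
      if (lw == 0) next
      tops <- c(ev$left, ev$right)
      for (ci in 1:2) {
        e <- ce[[u]][ci]
        v <- edge[e, 2]
        if (v <= nTip) lw <- lw * tipFactor[[e]][tops[ci]] else
          topSt[v] <<- tops[ci]
      }
      if (lw == 0) next
      curAnc[u] <<- a
      rec(idx + 1, lw)
    }
    invisible()
  }
  rec(1, 1)
  if (marginals) {
    keep <- (nTip + 1):nTotal
    post <- nodePost[, keep, drop = FALSE]
    post <- sweep(post, 2, colSums(post), "/")
    return(list(loglik = log(total), post = t(post), states = states))
  }
  log(total)
}
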