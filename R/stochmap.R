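# endpoint-conditioned CTMC path sampling ---------------------------------

# Forward Gillespie path under generator Q from state x for duration t.
# Returns list(times, states) of jumps (possibly empty).
forwardPath <- function(Q, x, t) {
  times <- numeric(0); states <- integer(0)
  cur <- x; now <- 0
  repeat {
    rate <- -Q[cur, cur]
    if (rate <= 0) break
    now <- now + stats::rexp(1, rate)
    if (now >= t) break
    probs <- Q[cur, ]; probs[cur] <- 0
    cur <- sample.int(length(probs), 1, prob = probs)
    times <- c(times, now); states <- c(states, cur)
  }
  list(times = times, states = states, end = cur)
}

# Rejection sampler: forward paths until the endpoint matches.
rejectionPath <- function(Q, x, y, t, cap = 10000) {
  for (i in seq_len(cap)) {
    p <- forwardPath(Q, x, t)
    if (p$end == y) return(p[c("times", "states")])
  }
  NULL
}

# Uniformization sampler (exact, used as fallback or directly).
uniformizationPath <- function(Q, x, y, t) {
  S <- nrow(Q)
  lam <- max(-diag(Q))
  if (lam <= 0) {
    if (x != y) stopf("unreachable endpoint pair under a zero generator")
    return(list(times = numeric(0), states = integer(0)))
  }
  R <- diag(S) + Q / lam
  nmax <- max(stats::qpois(1 - 1e-12, lam * t) + 10, 5)
  Rpow <- vector("list", nmax + 1)
  Rpow[[1]] <- diag(S)
  for (n in seq_len(nmax)) Rpow[[n + 1]] <- Rpow[[n]] %*% R
  wts <- vapply(0:nmax, function(n)
    stats::dpois(n, lam * t) * Rpow[[n + 1]][x, y], numeric(1))
  if (sum(wts) <= 0) stopf("unreachable endpoint pair (x=%d, y=%d)", x, y)
  n <- sample.int(nmax + 1, 1, prob = wts) - 1L
  states <- integer(0)
  if (n > 0) {
    cur <- x
    chain <- integer(n)
    for (i in seq_len(n)) {
      if (i == n) {
        chain[i] <- y
      } else {
        pr <- R[cur, ] * Rpow[[n - i + 1]][, y]
        chain[i] <- sample.int(S, 1, prob = pr)
      }
      cur <- chain[i]
    }
    keep <- chain != c(x, chain[-n])  # drop virtual (self) jumps
    states <- chain[keep]
    times <- sort(stats::runif(n, 0, t))[keep]
    return(list(times = times, states = states))
  }
  list(times = numeric(0), states = integer(0))
}

conditionedPath <- function(Q, x, y, t, sampler = "auto", cap = 10000) {
  if (t <= 0) {
    if (x != y) stopf("state change over a zero-length segment")
    return(list(times = numeric(0), states = integer(0)))
  }
  if (sampler == "uniformization") return(uniformizationPath(Q, x, y, t))
  p <- rejectionPath(Q, x, y, t, cap = if (sampler == "rejection") cap
                     else cap)
  if (is.null(p)) {
    if (sampler == "rejection")
      stopf("rejection sampler exhausted %d tries", cap)
    p <- uniformizationPath(Q, x, y, t)
  }
  p
}

# classify an expansion event: barrier class of the dominant source route
classifyExpansion <- function(fromMask, newArea, W, barriers, A) {
  occ <- maskAreas(fromMask, A)
  w <- W[occ, newArea]
  src <- occ[which.max(w)]
  barriers[src, newArea]
}

#' Biogeographic stochastic maps
#'
#' Samples full histories of range (and trait) states consistent with the
#' tip data and a fitted model: node states are drawn from their joint
#' conditional distribution root-down (using the cached pruning partials and
#' the cladogenesis table), then each branch path is drawn conditioned on
#' its endpoints, by rejection sampling (forward simulation, retry cap
#' `cap`) with an exact uniformization fallback. Every anagenetic event is
#' recorded with its age, type (`expansion`, `contraction`,
#' `trait-switch`), the area gained or lost, and, for expansions, the
#' oceanic/continental class of the dominant (highest dispersal weight)
#' source route.
#'
#' @param fit a [BiogeoFit-class].
#' @param nMaps number of maps.
#' @param seed RNG seed (maps are reproducible given the seed).
#' @param sampler `"auto"` (rejection, then uniformization), `"rejection"`
#'   or `"uniformization"`.
#' @param cap rejection retry cap per branch segment.
#' @return list with `events` (data.frame: map, parent, child, age_Ma,
#'   type, area, barrier), `nodeStates` (nMaps x nodes matrix of sampled
#'   pre-split state indices), `tipStates`, `stateSpace`, `nMaps`.
#' @export
stochasticMaps <- function(fit, nMaps = 100, seed = 1, sampler = c("auto",
                           "rejection", "uniformization"), cap = 10000) {
  sampler <- match.arg(sampler)
  set.seed(seed)
  ctx <- fit@cache$ctx
  B <- fit@cache$B
  U <- fit@cache$U
  Qs <- fit@cache$Qs
  ss <- ctx$stateSpace
  S <- nStates(ss)
  R <- nRanges(ss)
  A <- length(ss@areas)
  nTip <- ctx$nTip
  nTotal <- 2 * nTip - 1
  segPs <- edgeSegmentPs(ctx, Qs)
  ce <- childEdgeList(ctx)
  root <- ctx$edge[nrow(ctx$edge), 1]
  clado <- ctx$clado
  ages <- nodeAges(ctx$tree)
  x <- fit@params["x"]; if (is.na(x)) x <- 0
  Ws <- lapply(ctx$epochs, weightMatrix, distances = ctx$distances, x = x)
  masks <- ss@masks

  maskOf <- function(state) masks[(state - 1L) %% R + 1L]
  traitOf <- function(state) (state - 1L) %/% R + 1L

  # per-edge cumulative products H_k ... H_1 (suffix from the old end)
  edgeTot <- vector("list", nrow(ctx$edge))
  for (e in seq_len(nrow(ctx$edge))) {
    segs <- ctx$edgeSegs[[e]]
    Ptot <- diag(S)
    for (i in seq_len(nrow(segs))) {
      P <- segPs[[e]][[i]]
      Hi <- if (is.null(P)) diag(S) else P
      if (i > 1) Hi <- Hi %*% diag(as.numeric(ctx$allowed[, segs[i, 2]]))
      Ptot <- Hi %*% Ptot
    }
    edgeTot[[e]] <- Ptot
  }

  allEvents <- vector("list", nMaps)
  nodeStates <- matrix(NA_integer_, nMaps, nTotal)
  for (m in seq_len(nMaps)) {
    events <- list()
    state <- integer(nTotal)         # state at each node (bottom/pre-split)
    topState <- rep(NA_integer_, nrow(ctx$edge))
    pr <- ctx$rootPrior * B[, root]
    state[root] <- sample.int(S, 1, prob = pr)
    # traverse parent-before-child
    for (e in rev(seq_len(nrow(ctx$edge)))) {
      u <- ctx$edge[e, 1]
      v <- ctx$edge[e, 2]
      if (is.na(topState[e])) {
        # sample the cladogenetic outcome for both daughters at once,
        # left/right in the order the pruning pass used
        eL <- ce[[u]][1]; eR <- ce[[u]][2]
        rows <- which(clado$anc == state[u])
        w <- clado$prob[rows] * U[clado$left[rows], eL] *
          U[clado$right[rows], eR]
        ev <- rows[sample.int(length(rows), 1, prob = w)]
        topState[eL] <- clado$left[ev]
        topState[eR] <- clado$right[ev]
      }
      top <- topState[e]
      # bottom state of this edge
      bProb <- edgeTot[[e]][top, ] * B[, v]
      bot <- sample.int(S, 1, prob = bProb)
      state[v] <- bot
      # boundary states old -> young, then per-segment paths
      segs <- ctx$edgeSegs[[e]]
      k <- nrow(segs)
      bnd <- integer(k + 1)          # bnd[i] = state at young end of seg i-1
      bnd[k + 1] <- top; bnd[1] <- bot
      if (k > 1) {
        # suffix products of H_i for i = 1..k
        suff <- vector("list", k + 1) # suff[[i]] = H_{i-1}...H_1
        suff[[1]] <- diag(S)
        for (i in seq_len(k)) {
          P <- segPs[[e]][[i]]
          Hi <- if (is.null(P)) diag(S) else P
          if (i > 1) Hi <- Hi %*% diag(as.numeric(ctx$allowed[, segs[i,
                                                                     2]]))
          suff[[i + 1]] <- Hi %*% suff[[i]]
        }
        for (i in k:2) {
          P <- segPs[[e]][[i]]
          Hi <- if (is.null(P)) diag(S) else P
          prv <- Hi[bnd[i + 1], ] * vapply(seq_len(S), function(mm)
            suff[[i]][mm, bot], numeric(1))
          if (i > 1) prv <- prv * ctx$allowed[, segs[i, 2]]
          bnd[i] <- sample.int(S, 1, prob = prv)
        }
      }
      # sample the path within each segment (old to young)
      topAge <- ages[u]
      off <- sum(segs[, 1])          # distance from child, young end
      for (i in k:1) {
        tlen <- segs[i, 1]
        if (tlen <= 0) next
        ep <- segs[i, 2]
        pth <- conditionedPath(Qs[, , ep], bnd[i + 1], bnd[i], tlen,
                               sampler = sampler, cap = cap)
        if (length(pth$states)) {
          cur <- bnd[i + 1]
          segTopAge <- ages[v] + off
          for (j in seq_along(pth$states)) {
            nxt <- pth$states[j]
            age <- segTopAge - pth$times[j]
            mC <- maskOf(cur); mN <- maskOf(nxt)
            if (traitOf(cur) != traitOf(nxt)) {
              type <- "trait-switch"; area <- NA_character_
              barrier <- NA_character_
            } else if (bitwAnd(mN, bitwNot(mC)) > 0) {
              added <- maskAreas(bitwAnd(mN, bitwNot(mC)), A)
              type <- "expansion"; area <- ss@areas[added[1]]
              barrier <- classifyExpansion(mC, added[1], Ws[[ep]],
                                           ctx$dataset@barriers, A)
            } else {
              removed <- maskAreas(bitwAnd(mC, bitwNot(mN)), A)
              type <- "contraction"; area <- ss@areas[removed[1]]
              barrier <- NA_character_
            }
            events[[length(events) + 1]] <-
              data.frame(map = m, parent = u, child = v, age_Ma = age,
                         type = type, area = area, barrier = barrier)
            cur <- nxt
          }
        }
        off <- off - tlen
      }
    }
    nodeStates[m, ] <- state
    allEvents[[m]] <- if (length(events)) do.call(rbind, events) else
      data.frame(map = integer(0), parent = integer(0), child = integer(0),
                 age_Ma = numeric(0), type = character(0),
                 area = character(0), barrier = character(0))
  }
  events <- do.call(rbind, allEvents)
  rownames(events) <- NULL
  tips <- seq_len(nTip)
  list(events = events, nodeStates = nodeStates[, -tips, drop = FALSE],
       tipStates = nodeStates[, tips, drop = FALSE], stateSpace = ss,
       nMaps = nMaps, seed = seed)
}

#' Dispersal-event accounting over stochastic maps
#'
#' Counts range-expansion events only: the total per map, the mean total
#' divided by the number of tips (events per lineage), and the percentage
#' of expansion events classified oceanic.
#'
#' @param maps result of [stochasticMaps()].
#' @param nTips number of species in the clade.
#' @return list: `total` (mean over maps), `perLineage`, `oceanicPct`
#'   (`NA` when no expansion occurred), `perMap` (data.frame of per-map
#'   totals and oceanic counts).
#' @export
countDispersal <- function(maps, nTips) {
  ev <- maps$events
  ex <- ev[ev$type == "expansion", , drop = FALSE]
  perMap <- data.frame(map = seq_len(maps$nMaps))
  tot <- tabulate(ex$map, nbins = maps$nMaps)
  oce <- tabulate(ex$map[ex$barrier == "oceanic"], nbins = maps$nMaps)
  perMap$total <- tot
  perMap$oceanic <- oce
  total <- mean(tot)
  list(total = total,
       perLineage = total / nTips,
       oceanicPct = if (sum(tot) > 0) 100 * sum(oce) / sum(tot) else
         NA_real_,
       perMap = perMap)
}
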