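#' Simulation configuration for a synthetic clade
#'
#' Bundles the generative conditions: a birth-death tree conditioned on the
#' number of surviving tips, a Brownian-motion trait factor, and a
#' trait-dependent DEC range history over a four-area system with both
#' continental and oceanic barriers. Defaults produce the package's
#' standard strong-effect fixture: 60 tips, dispersal rate d = 0.02
#' events/My/area-pair, contraction rate e = 0.01 events/My/area, and a
#' dispersal multiplier m2 = 4 for lineages below the trait median
#' (mirroring the pipeline's median binarization).
#'
#' @param n surviving tips (>= 8).
#' @param lambda,mu birth and death rates (/My); `lambda > mu >= 0`.
#' @param sig2 Brownian variance rate of the trait factor (/My).
#' @param d,e,x,m2,t true model parameters ([modelSpec()] semantics).
#' @param seed master seed; per-component streams are derived from it.
#' @param scenario MDMM scenario used both to simulate and as truth.
#' @param base cladogenesis scheme of the generative model.
#' @param rootRange root range as an area-name string, e.g. `"AB"`.
#' @param traitMode `"threshold"` (trait states by thresholding the BM
#'   factor at its simulated tip median; the default, mirroring the median
#'   split) or `"chain"` (independent two-state chain at rate `t`).
#' @param curve optional length-4 multiplier curve (Q1..Q4); overrides
#'   `m2`/`traitMode` and assigns each branch the multiplier of its
#'   child-node factor quartile (used to generate shaped relationships).
#' @param geo geography bundle (`list(areas, distances, barriers)`);
#'   default [defaultGeography()].
#' @param maxTries rejection cap for tree and history simulation.
#' @return config list for [simulateClade()] / [makeFixture()].
#' @export
simConfig <- function(n = 60, lambda = 0.1, mu = 0, sig2 = 1,
                      d = 0.02, e = 0.01, x = 0, m2 = 4, t = 0.1,
                      seed = 42, scenario = "equal", base = "DEC",
                      rootRange = "AB", traitMode = "threshold",
                      curve = NULL, geo = defaultGeography(),
                      maxTries = 1000) {
  if (n < 8) stopf("need n >= 8 tips")
  if (!(lambda > mu && mu >= 0)) stopf("need lambda > mu >= 0")
  if (!all(strsplit(rootRange, "")[[1]] %in% geo$areas))
    stopf("root range uses unknown areas")
  as.list(environment())
}

#' Default four-area synthetic geography
#'
#' Two continental pairs (A-B and C-D) separated from each other by ocean;
#' distances are great-circle-scale values in km chosen so that continental
#' neighbours are closer than any oceanic pair.
#'
#' @return list with `areas`, `distances` (km), `barriers`.
#' @export
defaultGeography <- function() {
  areas <- c("A", "B", "C", "D")
  D <- matrix(c(0, 600, 1800, 2400,
                600, 0, 1500, 2000,
                1800, 1500, 0, 800,
                2400, 2000, 800, 0), 4, 4,
              dimnames = list(areas, areas))
  B <- matrix("oceanic", 4, 4, dimnames = list(areas, areas))
  B[cbind(c(1, 2), c(2, 1))] <- "continental"
  B[cbind(c(3, 4), c(4, 3))] <- "continental"
  diag(B) <- "self"
  list(areas = areas, distances = D, barriers = B)
}

#' Simulate a birth-death tree conditioned on the number of surviving tips
#'
#' Forward Gillespie simulation of a constant-rate birth-death process,
#' stopped at the moment the (n+1)-th birth would occur among survivors;
#' replicates that go extinct first are rejected and re-drawn. For a pure
#' birth process the time spent with k lineages is Exp(k lambda), so the
#' expected root age is `sum_{k=2..n} 1/(k lambda)`.
#'
#' @param n surviving tips.
#' @param lambda,mu birth and death rates (/My).
#' @param seed RNG seed.
#' @param maxTries rejection cap.
#' @return an ultrametric `ape::phylo` with `n` tips labelled `sp<i>`.
#' @export
simulateTree <- function(n, lambda = 0.1, mu = 0, seed = 1,
                         maxTries = 1000) {
  if (!(lambda > mu && mu >= 0)) stopf("need lambda > mu >= 0")
  set.seed(seed)
  for (try in seq_len(maxTries)) {
    parent <- 0L; btime <- 0; alive <- TRUE
    kids <- list(integer(0))
    tnow <- 0; done <- FALSE
    repeat {
      k <- sum(alive)
      if (k == 0L) break
      tnow <- tnow + stats::rexp(1, k * (lambda + mu))
      isBirth <- stats::runif(1) < lambda / (lambda + mu)
      if (isBirth && k == n) { done <- TRUE; break }
      who <- which(alive)[sample.int(k, 1)]
      if (isBirth) {
        parent <- c(parent, who); btime <- c(btime, tnow)
        alive <- c(alive, TRUE)
        kids[[who]] <- c(kids[[who]], length(parent))
        kids[[length(parent)]] <- integer(0)
      } else {
        alive[who] <- FALSE
      }
      if (length(parent) > 50 * n)
        stopf("birth-death simulation exploded; check lambda, mu, n")
    }
    if (!done) next
    T <- tnow
    subExt <- rep(NA, length(parent))
    subExtant <- function(i) {
      if (!is.na(subExt[i])) return(subExt[i])
      v <- alive[i] || any(vapply(kids[[i]], subExtant, logical(1)))
      subExt[i] <<- v
      v
    }
    extAfter <- function(i, tau)
      alive[i] || any(vapply(kids[[i]], function(k2)
        btime[k2] > tau && subExtant(k2), logical(1)))
    build <- function(i, t0) {
      repeat {
        ks <- kids[[i]][btime[kids[[i]]] > t0]
        ks <- ks[vapply(ks, subExtant, logical(1))]
        ks <- ks[order(btime[ks])]
        if (!length(ks)) return(sprintf("sp%d:%.10g", i, T - t0))
        k1 <- ks[1]; t1 <- btime[k1]
        if (extAfter(i, t1))
          return(sprintf("(%s,%s):%.10g", build(i, t1), build(k1, t1),
                         t1 - t0))
        i <- k1   # the i-side continuation is doomed; pass through
      }
    }
    if (!subExtant(1L)) next
    tr <- ape::read.tree(text = paste0(build(1L, 0), ";"))
    # contiguous, order-preserving tip labels
    o <- order(as.integer(sub("sp", "", tr$tip.label)))
    map <- stats::setNames(sprintf("sp%d", seq_len(n)), tr$tip.label[o])
    tr$tip.label <- unname(map[tr$tip.label])
    tr$root.edge <- NULL
    return(tr)
  }
  stopf("could not condition on %d survivors in %d tries", n, maxTries)
}

#' Simulate a Brownian-motion trait factor on a tree
#'
#' @param tree `ape::phylo`.
#' @param sig2 variance rate per My.
#' @param seed RNG seed.
#' @return list with `tips` (named scores) and `nodes` (scores for all
#'   nodes, indexed by ape node id; root value 0).
#' @export
simulateFactor <- function(tree, sig2 = 1, seed = 1) {
  set.seed(seed)
  n <- ape::Ntip(tree)
  if (sig2 == 0) {
    vals <- rep(0, 2 * n - 1)
  } else {
    v <- phytools::fastBM(tree, a = 0, sig2 = sig2, internal = TRUE)
    vals <- numeric(2 * n - 1)
    vals[seq_len(n)] <- v[tree$tip.label]
    vals[(n + 1):(2 * n - 1)] <- v[as.character((n + 1):(2 * n - 1))]
  }
  list(tips = stats::setNames(vals[seq_len(n)], tree$tip.label),
       nodes = vals)
}

rangeMaskFromString <- function(s, areas)
  sum(bitwShiftL(1L, match(strsplit(s, "")[[1]], areas) - 1L))

#' Forward-simulate a trait-dependent range history along a tree
#'
#' Gillespie simulation of the anagenetic range process along every branch
#' (per-epoch rates; expansions scaled by the branch's dispersal
#' multiplier) with cladogenetic outcomes drawn from the model's event
#' table at every node. Replicates in which any lineage is absorbed into
#' the null range are rejected whole and redrawn (clean conditioning on the
#' observed-data regime, where every tip occupies at least one area).
#'
#' @param tree `ape::phylo`.
#' @param geo geography bundle (`list(areas, distances, barriers)`).
#' @param params true parameters (`d`, `e`, optionally `x`).
#' @param edgeMultipliers per-edge dispersal multiplier (rows of
#'   `tree$edge`), e.g. m2 for state-2 branches, 1 otherwise.
#' @param rootRange root range as an area string, e.g. `"AB"`.
#' @param base cladogenesis scheme.
#' @param scenario MDMM scenario for the epoch multipliers.
#' @param epochs optional epoch list (default: one slice, all areas).
#' @param maxRangeSize cap on range size (default: all areas).
#' @param seed RNG seed.
#' @param maxTries whole-replicate rejection cap.
#' @return list: `tipRanges` (binary species x areas matrix), `events`
#'   (data.frame: parent, child, age_Ma, type, area, barrier),
#'   `nodeStates`, `edgeTopStates` (range indices), `stateSpace`,
#'   `nRejected`.
#' @export
simulateHistory <- function(tree, geo, params, edgeMultipliers,
                            rootRange = "AB", base = "DEC",
                            scenario = "equal", epochs = NULL,
                            maxRangeSize = NULL, seed = 1,
                            maxTries = 1000) {
  set.seed(seed)
  areas <- geo$areas
  A <- length(areas)
  mdmm <- mdmmScenario(scenario, geo$barriers)
  rootAge <- max(nodeAges(tree))
  if (is.null(epochs))
    epochs <- list(list(start = 0, end = rootAge, mdmm = mdmm,
                        allowed = rep(TRUE, A)))
  ss <- enumerateRanges(areas, maxRangeSize %||% A)
  R <- nRanges(ss)
  idx <- integer(2 ^ A); idx[ss@masks + 1L] <- seq_len(R)
  clado <- cladogenesisTable(base, ss)
  x <- params[["x"]] %||% 0
  Ws <- lapply(epochs, weightMatrix, distances = geo$distances, x = x)
  tp <- postorderEdges(tree)
  segsList <- edgeSegments(tp, epochs)
  ages <- nodeAges(tp)
  nTip <- ape::Ntip(tp)
  nTotal <- 2 * nTip - 1
  root <- tp$edge[nrow(tp$edge), 1]
  rootIdx <- idx[rangeMaskFromString(rootRange, areas) + 1L]
  if (rootIdx == 0L) stopf("root range not in state space")
  ce <- childEdgeList(list(edge = tp$edge, nTip = nTip))
  d <- params[["d"]]; e <- params[["e"]]

  # per-epoch, per-state event tables precomputed once: expansions carry
  # unit multiplier (scaled by the branch multiplier at draw time),
  # contractions rate e per occupied area
  rateTab <- lapply(seq_along(epochs), function(ep) {
    lapply(seq_len(R), function(i) {
      msk <- ss@masks[i]
      occ <- maskAreas(msk, A)
      tgt <- integer(0); base <- numeric(0); isExp <- logical(0)
      ar <- integer(0)
      if (length(occ) && length(occ) < ss@maxRangeSize) {
        for (k in setdiff(seq_len(A), occ)) {
          j <- idx[bitwOr(msk, bitwShiftL(1L, k - 1L)) + 1L]
          if (j == 0L) next
          r <- d * sum(Ws[[ep]][occ, k])
          if (r > 0) { tgt <- c(tgt, j); base <- c(base, r)
                       isExp <- c(isExp, TRUE); ar <- c(ar, k) }
        }
      }
      if (e > 0 && length(occ)) for (j2 in occ) {
        tgt <- c(tgt, idx[bitwAnd(msk, bitwNot(bitwShiftL(1L, j2 - 1L))) +
                            1L])
        base <- c(base, e); isExp <- c(isExp, FALSE); ar <- c(ar, j2)
      }
      list(tgt = tgt, base = base, isExp = isExp, area = ar)
    })
  })
  stepRates <- function(i, ep, m) {
    rt <- rateTab[[ep]][[i]]
    rate <- rt$base
    rate[rt$isExp] <- rate[rt$isExp] * m
    list(tgt = rt$tgt, rate = rate,
         typ = ifelse(rt$isExp, "expansion", "contraction"),
         area = rt$area)
  }

  for (try in seq_len(maxTries)) {
    ok <- TRUE
    evP <- evC <- integer(0); evAge <- numeric(0)
    evType <- evArea <- evBar <- character(0)
    state <- integer(nTotal)
    topState <- rep(NA_integer_, nrow(tp$edge))
    state[root] <- rootIdx
    for (eI in rev(seq_len(nrow(tp$edge)))) {
      u <- tp$edge[eI, 1]; v <- tp$edge[eI, 2]
      if (is.na(topState[eI])) {
        eL <- ce[[u]][1]; eR <- ce[[u]][2]
        rows <- which(clado$anc == state[u])
        ev <- rows[sample.int(length(rows), 1, prob = clado$prob[rows])]
        topState[eL] <- clado$left[ev]; topState[eR] <- clado$right[ev]
      }
      cur <- topState[eI]
      segs <- segsList[[eI]]
      m <- edgeMultipliers[eI]
      off <- sum(segs[, 1])
      for (si in rev(seq_len(nrow(segs)))) {
        tlen <- segs[si, 1]; ep <- segs[si, 2]
        segTopAge <- ages[v] + off
        tEl <- 0
        repeat {
          rr <- stepRates(cur, ep, m)
          tot <- sum(rr$rate)
          if (tot <= 0) break
          tEl <- tEl + stats::rexp(1, tot)
          if (tEl >= tlen) break
          pick <- sample.int(length(rr$rate), 1, prob = rr$rate)
          barrier <- NA_character_
          if (rr$typ[pick] == "expansion") {
            barrier <- classifyExpansion(ss@masks[cur], rr$area[pick],
                                         Ws[[ep]], geo$barriers, A)
          }
          evP <- c(evP, u); evC <- c(evC, v)
          evAge <- c(evAge, segTopAge - tEl)
          evType <- c(evType, rr$typ[pick])
          evArea <- c(evArea, areas[rr$area[pick]])
          evBar <- c(evBar, barrier)
          cur <- rr$tgt[pick]
          if (ss@masks[cur] == 0L) { ok <- FALSE; break }
        }
        if (!ok) break
        off <- off - tlen
      }
      if (!ok) break
      state[v] <- cur
    }
    if (!ok) next
    ev <- data.frame(parent = evP, child = evC, age_Ma = evAge,
                     type = evType, area = evArea, barrier = evBar,
                     stringsAsFactors = FALSE)
    tipRanges <- t(vapply(seq_len(nTip), function(i) {
      as.integer(bitwAnd(bitwShiftR(ss@masks[state[i]],
                                    seq_len(A) - 1L), 1L))
    }, integer(A)))
    dimnames(tipRanges) <- list(tp$tip.label, areas)
    return(list(tipRanges = tipRanges, events = ev, nodeStates = state,
                edgeTopStates = topState, edge = tp$edge,
                stateSpace = ss, nRejected = try - 1L, tree = tp))
  }
  stopf("history simulation rejected %d times (null-range absorption)",
        maxTries)
}

#' Replay a simulated event log and recover the tip ranges
#'
#' Applies the recorded anagenetic events of each branch to the recorded
#' post-cladogenesis (branch-top) states; the resulting tip ranges must
#' equal the simulated ones exactly — the invariant that the event log is a
#' complete history.
#'
#' @param truth result of [simulateHistory()].
#' @return binary tips x areas matrix.
#' @export
replayHistory <- function(truth) {
  ss <- truth$stateSpace
  A <- length(ss@areas)
  nTip <- nrow(truth$tipRanges)
  out <- matrix(0L, nTip, A, dimnames = dimnames(truth$tipRanges))
  for (eI in seq_len(nrow(truth$edge))) {
    v <- truth$edge[eI, 2]
    if (v > nTip) next
    msk <- ss@masks[truth$edgeTopStates[eI]]
    ev <- truth$events[truth$events$child == v, , drop = FALSE]
    ev <- ev[order(-ev$age_Ma), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      bit <- bitwShiftL(1L, match(ev$area[i], ss@areas) - 1L)
      msk <- if (ev$type[i] == "expansion") bitwOr(msk, bit) else
        bitwAnd(msk, bitwNot(bit))
    }
    out[v, ] <- as.integer(bitwAnd(bitwShiftR(msk, seq_len(A) - 1L), 1L))
  }
  out
}

#' Simulate a complete synthetic clade in memory
#'
#' Chains [simulateTree()], [simulateFactor()] and [simulateHistory()]
#' under one master seed and assembles a validated [BiogeoDataset-class]
#' plus the generating truth. Branch dispersal multipliers come from the
#' configured trait mode: under `"threshold"`, branches whose child-node
#' factor value lies below the simulated tip median carry multiplier `m2`
#' (trait state 2, matching the pipeline's median split of low scores);
#' under a `curve` configuration each branch carries the multiplier of its
#' child-node factor quartile.
#'
#' @param config a [simConfig()].
#' @return list: `dataset`, `truth` (with `factor`, `edgeStates`,
#'   `edgeMultipliers` added), `config`.
#' @export
simulateClade <- function(config) {
  cfg <- config
  tr <- simulateTree(cfg$n, cfg$lambda, cfg$mu,
                     seed = deriveSeed(cfg$seed, "tree"),
                     maxTries = cfg$maxTries)
  fac <- simulateFactor(tr, cfg$sig2, seed = deriveSeed(cfg$seed,
                                                        "factor"))
  tp <- postorderEdges(tr)
  childVals <- fac$nodes[tp$edge[, 2]]
  if (!is.null(cfg$curve)) {
    qs <- stats::quantile(fac$tips, c(0.25, 0.5, 0.75), type = 1)
    quart <- findInterval(childVals, qs, left.open = TRUE) + 1L
    mult <- cfg$curve[quart]
    edgeStates <- quart
  } else {
    med <- stats::median(fac$tips)
    edgeStates <- ifelse(childVals < med, 2L, 1L)
    mult <- ifelse(edgeStates == 2L, cfg$m2, 1)
  }
  truth <- simulateHistory(tp, cfg$geo,
                           list(d = cfg$d, e = cfg$e, x = cfg$x),
                           edgeMultipliers = mult,
                           rootRange = cfg$rootRange, base = cfg$base,
                           scenario = cfg$scenario,
                           seed = deriveSeed(cfg$seed, "history"),
                           maxTries = cfg$maxTries)
  truth$factor <- fac
  truth$edgeStates <- edgeStates
  truth$edgeMultipliers <- mult
  traits <- data.frame(factor1 = unname(fac$tips),
                       row.names = names(fac$tips))
  ds <- buildDataset(tp, truth$tipRanges, cfg$geo$distances,
                     cfg$geo$barriers, traits = traits,
                     mdmm = mdmmScenario(cfg$scenario, cfg$geo$barriers),
                     clade = sprintf("synthetic-n%d-seed%d", cfg$n,
                                     cfg$seed))
  list(dataset = ds, truth = truth, config = cfg)
}

#' Write a synthetic clade as a pipeline-ready fixture on disk
#'
#' Produces the seven plain-text inputs the reading layer consumes — newick
#' tree, lagrange-style geography, trait CSV, distance CSV, MDMM CSV,
#' barrier-class CSV and a truth JSON with the full event log — and checks
#' that they round-trip through [buildDataset()].
#'
#' @param config a [simConfig()].
#' @param outdir output directory (created if needed).
#' @return invisible list: `files` (named paths), `dataset`, `truth`.
#' @export
makeFixture <- function(config, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateClade(config)
  p <- function(f) file.path(outdir, f)
  ape::write.tree(sim$truth$tree, p("tree.nwk"))
  writeGeography(sim$dataset@presence, p("geography.data"))
  utils::write.csv(data.frame(species = rownames(sim$dataset@traits),
                              sim$dataset@traits),
                   p("traits.csv"), row.names = FALSE, quote = FALSE)
  writeAreaMatrix(config$geo$distances, p("distances.csv"))
  writeAreaMatrix(config$geo$barriers, p("barriers.csv"))
  writeAreaMatrix(mdmmScenario(config$scenario, config$geo$barriers),
                  p("mdmm.csv"))
  truthOut <- list(
    seed = config$seed, params = list(d = config$d, e = config$e,
                                      x = config$x, m2 = config$m2),
    rootRange = config$rootRange, scenario = config$scenario,
    base = config$base, nRejected = sim$truth$nRejected,
    edge = as.data.frame(sim$truth$edge),
    edgeTopStates = sim$truth$edgeTopStates,
    nodeStates = sim$truth$nodeStates,
    events = sim$truth$events)
  jsonlite::write_json(truthOut, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  files <- list(tree = p("tree.nwk"), geography = p("geography.data"),
                traits = p("traits.csv"), distances = p("distances.csv"),
                barriers = p("barriers.csv"), mdmm = p("mdmm.csv"),
                truth = p("truth.json"))
  invisible(list(files = files, dataset = sim$dataset,
                 truth = sim$truth))
}
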