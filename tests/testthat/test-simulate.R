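test_that("birth-death simulation conditions on the tip count", {
  tr <- simulateTree(10, lambda = 0.2, mu = 0, seed = 1)
  expect_equal(ape::Ntip(tr), 10)
  expect_true(ape::is.binary(tr))
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  # determinism
  t2 <- simulateTree(10, lambda = 0.2, mu = 0, seed = 1)
  expect_identical(ape::write.tree(tr), ape::write.tree(t2))
  # with extinction, still n surviving tips
  t3 <- simulateTree(12, lambda = 0.3, mu = 0.1, seed = 5)
  expect_equal(ape::Ntip(t3), 12)
})

test_that("Yule root ages match the analytic expectation", {
  lambda <- 0.25; n <- 12; reps <- 200
  ages <- vapply(seq_len(reps), function(s)
    max(nodeAges(simulateTree(n, lambda, 0, seed = 6000 + s))),
    numeric(1))
  expected <- sum(1 / (lambda * (2:n)))
  se <- stats::sd(ages) / sqrt(reps)
  expect_lt(abs(mean(ages) - expected), 3 * se)
})

test_that("Brownian factor has the right moments and determinism", {
  tr <- simulateTree(8, lambda = 0.2, mu = 0, seed = 2)
  f0 <- simulateFactor(tr, sig2 = 0, seed = 1)
  expect_true(all(f0$tips == 0))
  f1 <- simulateFactor(tr, sig2 = 1, seed = 3)
  f2 <- simulateFactor(tr, sig2 = 1, seed = 3)
  expect_identical(f1, f2)
  # tip variance across replicates approximates sig2 * depth
  reps <- 400
  tipVals <- vapply(seq_len(reps), function(s)
    simulateFactor(tr, sig2 = 1, seed = 100 + s)$tips[[1]], numeric(1))
  depth <- max(nodeAges(tr))
  expect_equal(stats::var(tipVals), depth, tolerance = 0.2)
})

test_that("range histories are complete, replayable event logs", {
  sim <- simulateClade(simConfig(n = 20, seed = 23))
  tru <- sim$truth
  expect_identical(replayHistory(tru), tru$tipRanges)
  # d = 0: no expansions, tips inherit fragments of the root range
  cfgs <- simConfig(n = 10, d = 0, e = 0.002, m2 = 1, seed = 3,
                    rootRange = "ABCD")
  s0 <- simulateClade(cfgs)
  expect_equal(sum(s0$truth$events$type == "expansion"), 0)
  rootAreas <- c("A", "B", "C", "D")
  occupied <- colnames(s0$truth$tipRanges)[colSums(s0$truth$tipRanges) >
                                             0]
  expect_true(all(occupied %in% rootAreas))
})

test_that("state-2 lineages disperse more when m2 > 1", {
  # two-sided construction check at the event-log level: expansions per
  # My of branch length, strong effect
  exp2 <- exp1 <- len2 <- len1 <- 0
  for (s in 1:25) {
    sim <- simulateClade(simConfig(n = 25, seed = 300 + s, m2 = 5))
    tp <- sim$truth$tree
    st <- sim$truth$edgeStates
    ev <- sim$truth$events
    # attribute events to edges by child node
    e2 <- tp$edge[st == 2L, 2]
    nE2 <- sum(ev$type == "expansion" & ev$child %in% e2)
    nE1 <- sum(ev$type == "expansion") - nE2
    exp2 <- exp2 + nE2; exp1 <- exp1 + nE1
    len2 <- len2 + sum(tp$edge.length[st == 2L])
    len1 <- len1 + sum(tp$edge.length[st != 2L])
  }
  expect_gt(exp2 / len2, exp1 / len1)
})

test_that("short-branch transition frequencies match exp(Qt)", {
  # CTMC check: from a fixed widespread state over a short interval the
  # empirical end-state distribution matches the matrix exponential
  geo <- defaultGeography()
  tr <- ape::read.tree(text = "(a:0.8,b:0.8);")
  reps <- 2000
  params <- list(d = 0.15, e = 0.1)
  ends <- character(reps)
  for (s in seq_len(reps)) {
    h <- simulateHistory(tr, geo, params,
                         edgeMultipliers = c(1, 1), rootRange = "AB",
                         base = "BAYAREALIKE", seed = 9000 + s,
                         maxTries = 50)
    ends[s] <- paste(colnames(h$tipRanges)[h$tipRanges[1, ] == 1],
                     collapse = "")
  }
  ss <- enumerateRanges(geo$areas)
  ep <- list(mdmm = mdmmScenario("equal", geo$barriers),
             allowed = rep(TRUE, 4))
  Q <- buildRateMatrix(ss, params, ep, geo$distances)
  P <- as.matrix(Matrix::expm(Q * 0.8))
  pTheory <- P[which(stateLabels(ss) == "AB"), ]
  # conditioning: replicates where the lineage hit the null range were
  # rejected and redrawn, so renormalize theory over non-null states
  pTheory[1] <- 0; pTheory <- pTheory / sum(pTheory)
  for (lab in c("AB", "A", "ABC", "ABD", "ABCD")) {
    pObs <- mean(ends == lab)
    pE <- pTheory[which(stateLabels(ss) == lab)]
    se <- sqrt(pE * (1 - pE) / reps)
    expect_lt(abs(pObs - pE), 4 * se + 1e-3)
  }
})

test_that("fixtures round-trip through the readers", {
  dir <- withr::local_tempdir()
  fx <- makeFixture(simConfig(n = 20, seed = 42), dir)
  expect_true(all(file.exists(unlist(fx$files))))
  tr <- readNewick(fx$files$tree)
  pres <- readGeography(fx$files$geography)
  D <- readAreaMatrix(fx$files$distances, "distances")
  B <- readAreaMatrix(fx$files$barriers, "barriers")
  M <- readAreaMatrix(fx$files$mdmm, "mdmm")
  trt <- utils::read.csv(fx$files$traits, row.names = 1)
  ds <- buildDataset(tr, pres, D, B, traits = trt, mdmm = M)
  expect_equal(nTips(ds), 20)
  expect_identical(unname(presenceMatrix(ds)[rownames(fx$dataset@presence), ]),
                   unname(fx$dataset@presence))
  # truth JSON carries the full event log
  truth <- jsonlite::read_json(fx$files$truth, simplifyVector = TRUE)
  expect_equal(length(truth$events$type), nrow(fx$truth$events))
  # different seeds give different histories
  fx2 <- makeFixture(simConfig(n = 20, seed = 43), withr::local_tempdir())
  expect_false(identical(fx$truth$events, fx2$truth$events))
})
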