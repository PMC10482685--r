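# Pruning likelihood against the exhaustive-enumeration oracle and the
# analytic identities. The acceptance suite widens the oracle sweep to 50
# parameter draws; here a smaller sweep guards each model family.

test_that("two-tip d=e=0 DEC instance gives lnL = log(1/3)", {
  ds <- twoTipDataset()
  expect_equal(computeLogLik(ds, modelSpec("DEC"), c(d = 0, e = 0)),
               log(1 / 3), tolerance = 1e-12)
})

test_that("pruning equals joint enumeration across model families", {
  suppressWarnings(
    for (s in 1:9) {
      model <- c("DEC", "DIVALIKE", "BAYAREALIKE")[(s - 1) %% 3 + 1]
      inst <- randomOracleInstance(nTip = 2 + (s %% 3),
                                   model = model, withX = s %% 2 == 0,
                                   seed = 400 + s)
      ds <- oracleInstanceDataset(inst)
      sp <- modelSpec(model, hasX = "x" %in% names(inst$params),
                      mdmm = "custom")
      tr <- ape::read.tree(text = inst$newick)
      expect_equal(computeLogLik(ds, sp, inst$params),
                   oracleLoglik(tr, oracleTipRanges(inst), NULL,
                                inst$params, model, inst$mdmm,
                                inst$distances),
                   tolerance = 1e-8, info = paste("seed", s))
    }
  )
})

test_that("trait-augmented pruning equals enumeration (conditional lnL)", {
  suppressWarnings(
    for (s in 1:4) {
      inst <- randomOracleInstance(nTip = 4, areas = c("A", "B"),
                                   withTrait = TRUE, seed = 500 + s)
      ds <- oracleInstanceDataset(inst)
      sp <- modelSpec("DEC", hasM2 = TRUE, split = inst$traitStates,
                      mdmm = "custom")
      ctx <- traitDEC:::pruneContext(ds, sp)
      tr <- ape::read.tree(text = inst$newick)
      joint <- oracleLoglik(tr, oracleTipRanges(inst),
                            as.list(inst$traitStates), inst$params,
                            "DEC", inst$mdmm, inst$distances)
      conditional <- joint - traitDEC:::traitOnlyLnL(ctx,
                                                     inst$params[["t"]])
      expect_equal(traitDEC:::ctxLoglik(ctx, inst$params), conditional,
                   tolerance = 1e-8, info = paste("seed", s))
    }
  )
})

test_that("nested models collapse to the base model exactly", {
  sim <- simulateClade(simConfig(n = 20, seed = 3))
  ds <- sim$dataset
  p <- c(d = 0.03, e = 0.008)
  base <- computeLogLik(ds, modelSpec("DEC"), p)
  # x = 0
  expect_equal(computeLogLik(ds, modelSpec("DEC", hasX = TRUE),
                             c(p, x = 0)), base, tolerance = 1e-10)
  # m2 = 1 with observed traits (conditional likelihood), any switch rate
  spM <- modelSpec("DEC", hasM2 = TRUE, split = "median",
                   trait = "factor1")
  expect_equal(computeLogLik(ds, spM, c(p, m2 = 1, t = 0.2)), base,
               tolerance = 1e-6)
  # m2 = 1, t -> 0 with fully ambiguous trait tips
  amb <- stats::setNames(rep(NA_integer_, nTips(ds)),
                         datasetTree(ds)$tip.label)
  spA <- modelSpec("DEC", hasM2 = TRUE, split = amb)
  expect_equal(computeLogLik(ds, spA, c(p, m2 = 1, t = 0)), base,
               tolerance = 1e-6)
})

test_that("likelihood is invariant to tip order and newick rotation", {
  ranges <- list(a = "A", b = "AB", c = "B", d = "AC")
  p <- c(d = 0.05, e = 0.02)
  d1 <- manualDataset("(((a:1,b:1):1,c:2):1,d:3);", ranges)
  d2 <- manualDataset("(d:3,(c:2,(b:1,a:1):1):1);", ranges)
  expect_equal(computeLogLik(d1, modelSpec("DEC"), p),
               computeLogLik(d2, modelSpec("DEC"), p), tolerance = 1e-10)
})

test_that("time-stratified likelihood responds to epoch MDMMs", {
  areas <- c("A", "B")
  m1 <- matrix(1, 2, 2, dimnames = list(areas, areas))
  m0 <- matrix(0, 2, 2, dimnames = list(areas, areas)); diag(m0) <- 1
  ranges <- list(a = "A", b = "B", c = "AB")
  mk <- function(mOld) manualDataset("((a:1,b:1):1,c:2);", ranges,
    areas = areas,
    epochs = list(list(start = 0, end = 0.5, mdmm = m1,
                       allowed = c(TRUE, TRUE)),
                  list(start = 0.5, end = 2, mdmm = mOld,
                       allowed = c(TRUE, TRUE))))
  p <- c(d = 0.3, e = 0.05)
  sp <- modelSpec("DEC", mdmm = "custom")
  llOpen <- computeLogLik(mk(m1), sp, p)
  llClosed <- computeLogLik(mk(m0), sp, p)
  # closing dispersal in the old epoch must change (here: lower) the
  # likelihood of a widespread tip given dispersal is needed deep in time
  expect_false(isTRUE(all.equal(llOpen, llClosed, tolerance = 1e-6)))
  # and a single-epoch equal-MDMM analysis equals the "custom" route
  dsE <- manualDataset("((a:1,b:1):1,c:2);", ranges, areas = areas)
  expect_equal(computeLogLik(dsE, modelSpec("DEC"), p),
               computeLogLik(dsE, sp, p), tolerance = 1e-12)
})
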