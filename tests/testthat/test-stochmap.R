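test_that("maps on an event-free model have no events", {
  ds <- twoTipDataset()
  f <- fixedFit(ds, modelSpec("DEC"), c(d = 0, e = 0))
  mp <- stochasticMaps(f, nMaps = 25, seed = 4)
  expect_equal(nrow(mp$events), 0)
  cd <- countDispersal(mp, nTips(ds))
  expect_equal(cd$total, 0)
  expect_true(is.na(cd$oceanicPct))
})

test_that("maps are byte-identical under the same seed", {
  suppressWarnings({
    inst <- randomOracleInstance(nTip = 4, seed = 21)
    ds <- oracleInstanceDataset(inst)
    f <- fixedFit(ds, modelSpec("DEC", mdmm = "custom"), inst$params)
    m1 <- stochasticMaps(f, nMaps = 40, seed = 9)
    m2 <- stochasticMaps(f, nMaps = 40, seed = 9)
    expect_identical(m1$events, m2$events)
    expect_identical(m1$nodeStates, m2$nodeStates)
    m3 <- stochasticMaps(f, nMaps = 40, seed = 10)
    expect_false(identical(m1$events, m3$events))
  })
})

test_that("node-state frequencies converge to the analytic marginals", {
  suppressWarnings({
    inst <- randomOracleInstance(nTip = 4, seed = 21)
    ds <- oracleInstanceDataset(inst)
    f <- fixedFit(ds, modelSpec("DEC", mdmm = "custom"), inst$params)
    mp <- stochasticMaps(f, nMaps = 1000, seed = 5)
    mg <- ancestralMarginals(f)
    freq <- t(apply(mp$nodeStates, 2, tabulate, nbins = ncol(mg))) / 1000
    # binomial Monte-Carlo error at n = 1000: ~4 sd of worst-case p = 0.5
    expect_lt(max(abs(freq - unname(mg))), 0.065)
  })
})

test_that("rejection and uniformization samplers agree in distribution", {
  suppressWarnings({
    inst <- randomOracleInstance(nTip = 4, seed = 21)
    ds <- oracleInstanceDataset(inst)
    f <- fixedFit(ds, modelSpec("DEC", mdmm = "custom"), inst$params)
    n <- 600
    mr <- stochasticMaps(f, nMaps = n, seed = 9, sampler = "rejection")
    mu <- stochasticMaps(f, nMaps = n, seed = 10,
                         sampler = "uniformization")
    cr <- countDispersal(mr, 4)$perMap$total
    cu <- countDispersal(mu, 4)$perMap$total
    se <- sqrt(stats::var(cr) / n + stats::var(cu) / n)
    expect_lt(abs(mean(cr) - mean(cu)), 4 * se)
  })
})

test_that("tip states of every map match the observations", {
  sim <- simulateClade(simConfig(n = 12, seed = 13))
  f <- fixedFit(sim$dataset, modelSpec("DEC"), c(d = 0.03, e = 0.01))
  mp <- stochasticMaps(f, nMaps = 15, seed = 2)
  ctx <- f@cache$ctx
  obs <- apply(ctx$tipPartials, 2, which.max)
  for (m in seq_len(15))
    expect_equal(unname(mp$tipStates[m, ]), unname(obs))
})

test_that("expansion events carry a barrier class, contractions do not", {
  sim <- simulateClade(simConfig(n = 12, seed = 13))
  f <- fixedFit(sim$dataset, modelSpec("DEC"),
                c(d = 0.05, e = 0.02))
  mp <- stochasticMaps(f, nMaps = 30, seed = 2)
  ex <- mp$events[mp$events$type == "expansion", ]
  expect_true(all(ex$barrier %in% c("continental", "oceanic")))
  co <- mp$events[mp$events$type == "contraction", ]
  expect_true(all(is.na(co$barrier)))
  # per-lineage accounting
  cd <- countDispersal(mp, nTips(sim$dataset))
  expect_equal(cd$perLineage, cd$total / 12)
  expect_true(is.na(cd$oceanicPct) ||
                (cd$oceanicPct >= 0 && cd$oceanicPct <= 100))
})

test_that("dispersal accounting divides events by species", {
  fake <- list(events = data.frame(map = c(1, 1, 1),
                                   parent = 1, child = 2, age_Ma = 1,
                                   type = "expansion", area = "B",
                                   barrier = c("oceanic", "oceanic",
                                               "continental")),
               nMaps = 1)
  cd <- countDispersal(fake, 30)
  expect_equal(cd$perLineage, 0.1)
  expect_equal(cd$oceanicPct, 200 / 3, tolerance = 1e-10)
})
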