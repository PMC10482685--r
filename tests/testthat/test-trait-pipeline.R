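test_that("binarization ranks, splits and tie-breaks deterministically", {
  sc <- stats::setNames(1:8, paste0("s", 1:8))
  b <- binarizeFactor(sc, "median")
  expect_equal(unname(b$states[paste0("s", 1:4)]), rep(2L, 4))
  expect_equal(unname(b$states[paste0("s", 5:8)]), rep(1L, 4))
  b2 <- binarizeFactor(sc, "extreme50")
  expect_equal(names(which(b2$states == 2L)),
               paste0("s", c(1, 2, 7, 8)))
  b3 <- binarizeFactor(sc, "first25")
  expect_equal(names(which(b3$states == 2L)), c("s1", "s2"))
  b4 <- binarizeFactor(sc, "last25")
  expect_equal(names(which(b4$states == 2L)), c("s7", "s8"))

  # ties at the boundary resolved by species name, stable across runs
  tied <- stats::setNames(c(1, 1, 1, 1, 1, 2, 2, 2), paste0("s", 8:1))
  t1 <- binarizeFactor(tied, "median")
  t2 <- binarizeFactor(tied, "median")
  expect_identical(t1$states, t2$states)
  # rank order is (score, name): the five score-1 species sort by name,
  # so the lower half is s4..s7
  expect_equal(sort(names(which(t1$quartile <= 2))),
               c("s4", "s5", "s6", "s7"))

  # unscored species stay ambiguous
  sc2 <- c(sc, s9 = NA)
  b5 <- binarizeFactor(sc2, "median")
  expect_true(is.na(b5$states["s9"]))
  expect_error(binarizeFactor(stats::setNames(1:5, letters[1:5]),
                              "median"), ">= 8")
})

test_that("dispersal curve averages multipliers over the model set", {
  # hand example: base weight 0.4, median-split +m2 (m2 = 2) weight 0.6
  mkFit <- function(spec, params, AICc) methods::new("BiogeoFit",
    modelSpec = spec, params = params, lnL = -1, k = 2L, AICc = AICc,
    convergence = list(), cache = list())
  # AICc chosen so weights are exactly 0.4 / 0.6
  a2 <- -2 * log(0.6 / 0.4)
  ds <- twoTipDataset()
  ms <- methods::new("BiogeoModelSet",
    fits = list(base = mkFit(modelSpec("DEC"), c(d = .1, e = .1), 0),
                `+m2[median]` = mkFit(
                  modelSpec("DEC", hasM2 = TRUE, split = "median",
                            trait = "f"),
                  c(d = .1, e = .1, m2 = 2, t = .1), a2)),
    weights = c(base = 0.4, `+m2[median]` = 0.6),
    baseModel = "DEC", mdmm = "equal", trait = "f", dataset = ds)
  cu <- dispersalCurve(ms)
  expect_equal(unname(cu), c(1.6, 1.6, 1.0, 1.0), tolerance = 1e-12)
  expect_equal(curveMagnitude(cu), 37.5)

  # all weight on trait-independent models gives a flat curve
  ms2 <- methods::new("BiogeoModelSet",
    fits = list(base = mkFit(modelSpec("DEC"), c(d = .1, e = .1), 0)),
    weights = c(base = 1), baseModel = "DEC", mdmm = "equal",
    trait = "f", dataset = ds)
  expect_equal(unname(dispersalCurve(ms2)), rep(1, 4))
})

test_that("curve magnitude is the relative max-min difference", {
  expect_equal(curveMagnitude(c(1, 1, 1, 1)), 0)
  expect_equal(curveMagnitude(c(1.6, 1.6, 1, 1)), 37.5)
  for (s in 1:20) {
    set.seed(s)
    cu <- exp(stats::rnorm(4))
    m <- curveMagnitude(cu)
    expect_true(m >= 0 && m < 100)
    expect_equal(m == 0, max(cu) == min(cu))
  }
})

test_that("shape classification follows the linear/quadratic rule", {
  expect_equal(classifyShape(c(1, 0.5, 0.5, 1)), "U")
  expect_equal(classifyShape(c(0.5, 1, 1, 0.5)), "bell")
  expect_equal(classifyShape(c(1, 1.2, 1.5, 2)), "positive")
  expect_equal(classifyShape(c(2, 1.5, 1.2, 1)), "negative")
  expect_equal(classifyShape(c(1, 1.05, 1.02, 1.04)), "none")
  # exact |quad| = |lin| tie goes to the linear class
  expect_equal(classifyShape(c(1, 1, 2, 2)), "positive")
  # threshold boundary: magnitude exactly 10% is still "none"
  expect_equal(classifyShape(c(1, 1, 1, 0.9)), "none")
  expect_equal(classifyShape(c(1, 1, 1, 0.89)), "negative")
})

test_that("pipeline produces a deterministic, well-formed report", {
  sim <- simulateClade(simConfig(n = 30, seed = 17))
  cfg <- list(seed = 7, nStarts = 1, base = "DEC", mdmm = "equal",
              compare = TRUE, nMaps = 0)
  rep1 <- runCladePipeline(sim$dataset, cfg)[["factor1"]]
  expect_s4_class(rep1, "CladeReport")
  expect_length(rep1@curve, 4)
  expect_true(rep1@shape %in% c("positive", "negative", "U", "bell",
                                "none"))
  expect_equal((rep1@shape == "none"),
               rep1@magnitudePct <= rep1@provenance$shapeThreshold)
  expect_equal(nrow(rep1@modelTable), 10)
  expect_equal(sum(rep1@modelTable$weight), 1, tolerance = 1e-9)
  # disagreement metrics are proportions
  expect_true(rep1@comparison$trait$disagreement >= 0 &&
                rep1@comparison$trait$disagreement <= 1)

  # identical config + seed: byte-identical serialized report
  rep2 <- runCladePipeline(sim$dataset, cfg)[["factor1"]]
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  writeCladeReport(rep1, f1)
  writeCladeReport(rep2, f2)
  expect_identical(readLines(f1), readLines(f2))
})
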