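test_that("range enumeration is ordered and counted correctly", {
  ss <- enumerateRanges(c("A", "B", "C"))
  expect_equal(stateLabels(ss),
               c("_", "A", "B", "C", "AB", "AC", "BC", "ABC"))
  expect_equal(nStates(ss), 8)

  ss2 <- enumerateRanges(c("A", "B", "C"), maxRangeSize = 2)
  expect_equal(nStates(ss2), 7)
  expect_false("ABC" %in% stateLabels(ss2))

  ss3 <- enumerateRanges(c("A", "B", "C", "D"), traitAugmented = TRUE)
  expect_equal(nStates(ss3), 32)
  expect_equal(nRanges(ss3), 16)
  # lexicographic within a size class
  expect_equal(stateLabels(ss3)[6:11],
               paste0(c("AB", "AC", "AD", "BC", "BD", "CD"), "|s1"))

  expect_error(enumerateRanges(letters[1:11]), "guard")
})

test_that("dispersal weights follow the MDMM and distance power law", {
  areas <- c("A", "B", "C")
  D <- unevenDistances(areas)
  dbar <- mean(D[row(D) != col(D)])
  ep <- list(mdmm = matrix(0.5, 3, 3), allowed = rep(TRUE, 3))
  # at the mean distance the power term vanishes
  D2 <- matrix(dbar, 3, 3); diag(D2) <- 0
  expect_equal(dispersalWeight(1, 2, ep, D2, x = -1.3), 0.5)
  # doubling the distance with x = -1 halves the weight
  D3 <- D2; D3[1, 2] <- D3[2, 1] <- 2 * dbar
  dbar3 <- mean(D3[row(D3) != col(D3)])
  ep1 <- list(mdmm = matrix(1, 3, 3), allowed = rep(TRUE, 3))
  expect_equal(dispersalWeight(1, 2, ep1, D3, x = -1),
               (2 * dbar / dbar3) ^ (-1))
  # x = 0 reduces to the bare MDMM entry
  expect_equal(dispersalWeight(1, 3, ep, D, x = 0), 0.5)
  # disallowed target area
  ep0 <- list(mdmm = matrix(1, 3, 3), allowed = c(TRUE, TRUE, FALSE))
  expect_equal(dispersalWeight(1, 3, ep0, D, x = 0), 0)
  # degenerate zero distance with x != 0
  Dz <- D; Dz[1, 2] <- Dz[2, 1] <- 0
  expect_error(dispersalWeight(1, 2, ep1, Dz, x = -1), "zero distance")
})

test_that("rate matrix implements expansion, contraction and trait switch", {
  areas <- c("A", "B")
  D <- matrix(c(0, 1000, 1000, 0), 2, 2, dimnames = list(areas, areas))
  ep <- list(mdmm = matrix(1, 2, 2), allowed = c(TRUE, TRUE))
  ss <- enumerateRanges(areas, traitAugmented = TRUE)
  Q <- buildRateMatrix(ss, list(d = 0.1, e = 0.03, m2 = 2, t = 0.05), ep,
                       D)
  # state order: _|s1 A|s1 B|s1 AB|s1 _|s2 A|s2 B|s2 AB|s2
  expect_equal(Q["A|s2", "AB|s2"], 0.2)     # m2 * d
  expect_equal(Q["A|s1", "AB|s1"], 0.1)
  expect_equal(Q["AB|s1", "A|s1"], 0.03)    # contraction e per area
  expect_equal(Q["AB|s2", "B|s2"], 0.03)
  expect_equal(Q["A|s1", "A|s2"], 0.05)     # trait switch
  expect_equal(Q["A|s1", "_|s1"], 0.03)     # last-area loss
  expect_true(all(abs(rowSums(Q)) < 1e-12))
  expect_true(all(Q["_|s1", ] == 0))        # null range absorbing

  # m2 = 1 makes the two trait blocks identical
  Q1 <- buildRateMatrix(ss, list(d = 0.1, e = 0.03, m2 = 1, t = 0.05), ep,
                        D)
  expect_equal(unname(Q1[2:4, 2:4]), unname(Q1[6:8, 6:8]))
})

test_that("transition probabilities are proper", {
  ss <- enumerateRanges(c("A", "B", "C"))
  D <- unevenDistances(c("A", "B", "C"))
  ep <- list(mdmm = matrix(c(1, .5, .2, .5, 1, .7, .2, .7, 1), 3, 3),
             allowed = rep(TRUE, 3))
  Q <- buildRateMatrix(ss, list(d = 0.2, e = 0.1, x = -1), ep, D)
  P <- as.matrix(Matrix::expm(Q * 3.7))
  expect_true(all(abs(rowSums(P) - 1) < 1e-9))
  expect_true(all(P >= -1e-12 & P <= 1 + 1e-12))
})

test_that("cladogenesis tables enumerate the allowed scenarios", {
  ss <- enumerateRanges(c("A", "B"))
  dec <- cladogenesisTable("DEC", ss)
  ab <- dec[dec$anc == which(stateLabels(ss) == "AB"), ]
  expect_equal(nrow(ab), 6)
  expect_true(all(ab$prob == 1 / 6))
  got <- sort(paste(stateLabels(ss)[ab$left], stateLabels(ss)[ab$right]))
  expect_equal(got, sort(c("A AB", "B AB", "AB A", "AB B", "A B", "B A")))

  diva <- cladogenesisTable("DIVALIKE", ss)
  ab2 <- diva[diva$anc == which(stateLabels(ss) == "AB"), ]
  expect_equal(nrow(ab2), 2)
  expect_true(all(ab2$prob == 0.5))

  ss3 <- enumerateRanges(c("A", "B", "C"))
  bay <- cladogenesisTable("BAYAREALIKE", ss3)
  abc <- bay[bay$anc == which(stateLabels(ss3) == "ABC"), ]
  expect_equal(nrow(abc), 1)
  expect_equal(abc$left, abc$anc)
  expect_equal(abc$prob, 1)

  # probabilities sum to one for every ancestor, every model, A <= 4
  ss4 <- enumerateRanges(c("A", "B", "C", "D"), traitAugmented = TRUE)
  for (m in c("DEC", "DIVALIKE", "BAYAREALIKE")) {
    tab <- cladogenesisTable(m, ss4)
    sums <- tapply(tab$prob, tab$anc, sum)
    expect_true(all(abs(sums - 1) < 1e-12), info = m)
    # daughters never null (in either trait block)
    R <- nRanges(ss4)
    expect_true(all(!tab$left %in% c(1, R + 1) &
                      !tab$right %in% c(1, R + 1)))
    # trait inherited identically
    expect_true(all((tab$anc > R) == (tab$left > R)))
    expect_true(all((tab$anc > R) == (tab$right > R)))
  }
})
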