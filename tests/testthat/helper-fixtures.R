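# Small in-code fixtures shared across test files.

# Manual dataset from a newick string and named range strings ("A", "AB").
manualDataset <- function(newick, ranges, areas = c("A", "B", "C"),
                          traits = NULL, distances = NULL,
                          barriers = NULL, mdmm = NULL, epochs = NULL) {
  tr <- ape::read.tree(text = newick)
  A <- length(areas)
  pres <- matrix(0L, length(ranges), A,
                 dimnames = list(names(ranges), areas))
  for (sp in names(ranges))
    pres[sp, match(strsplit(ranges[[sp]], "")[[1]], areas)] <- 1L
  if (is.null(distances)) {
    distances <- matrix(1000, A, A, dimnames = list(areas, areas))
    diag(distances) <- 0
  }
  if (is.null(barriers)) {
    barriers <- matrix("oceanic", A, A, dimnames = list(areas, areas))
    diag(barriers) <- "self"
  }
  buildDataset(tr, pres, distances, barriers, traits = traits,
               mdmm = mdmm, epochs = epochs, clade = "test")
}

# Distance matrix with unequal entries, for exercising the x exponent.
unevenDistances <- function(areas) {
  A <- length(areas)
  D <- outer(seq_len(A), seq_len(A), function(i, j) 500 * abs(i - j) + 300)
  diag(D) <- 0
  dimnames(D) <- list(areas, areas)
  (D + t(D)) / 2
}

# Random small instance for oracle comparisons: a tree with nTip tips,
# random tip ranges over `areas`, random parameters. Returns everything
# both the package path and the oracle need.
randomOracleInstance <- function(nTip = 4, areas = c("A", "B", "C"),
                                 model = "DEC", withX = FALSE,
                                 withTrait = FALSE, seed = 1) {
  set.seed(seed)
  topo <- if (nTip == 2) "(t1:%.3f,t2:%.3f);" else if (nTip == 3)
    "((t1:%.3f,t2:%.3f):%.3f,t3:%.3f);" else if (runif(1) < 0.5)
    "(((t1:%.3f,t2:%.3f):%.3f,t3:%.3f):%.3f,t4:%.3f);" else
    "((t1:%.3f,t2:%.3f):%.3f,(t3:%.3f,t4:%.3f):%.3f);"
  nb <- lengths(regmatches(topo, gregexpr("%\\.3f", topo)))
  newick <- do.call(sprintf, c(list(topo), as.list(round(runif(nb, 0.2,
                                                               3), 3))))
  A <- length(areas)
  rangeStr <- function() {
    k <- sample.int(A, 1)
    paste(sort(sample(areas, k)), collapse = "")
  }
  ranges <- stats::setNames(replicate(nTip, rangeStr()),
                            paste0("t", seq_len(nTip)))
  params <- c(d = runif(1, 0.01, 0.4), e = runif(1, 0.005, 0.3))
  if (withX) params <- c(params, x = runif(1, -2, 2))
  if (withTrait) params <- c(params, m2 = exp(runif(1, -1.2, 1.2)),
                             t = runif(1, 0.02, 0.6))
  traitStates <- NULL
  traits <- NULL
  if (withTrait) {
    # >= 8 scored species are required for binarization, so attach the
    # trait states directly (fixed split) via a crafted score vector is
    # impossible at 4 tips; instead the tests pass explicit tip states to
    # the oracle and use fixedTraitDataset() below for the package side.
    traitStates <- stats::setNames(sample(c(1L, 2L), nTip, replace = TRUE),
                                   names(ranges))
  }
  distances <- unevenDistances(areas)
  barriers <- matrix("oceanic", A, A, dimnames = list(areas, areas))
  diag(barriers) <- "self"
  mdmm <- matrix(1, A, A, dimnames = list(areas, areas))
  list(newick = newick, ranges = ranges, params = params, model = model,
       areas = areas, distances = distances, barriers = barriers,
       mdmm = mdmm, traitStates = traitStates)
}

# Package-side dataset for an oracle instance.
oracleInstanceDataset <- function(inst) {
  manualDataset(inst$newick, as.list(inst$ranges), areas = inst$areas,
                distances = inst$distances, barriers = inst$barriers,
                mdmm = inst$mdmm)
}

# Oracle-side tip range list (area index vectors).
oracleTipRanges <- function(inst) {
  lapply(stats::setNames(as.list(inst$ranges), names(inst$ranges)),
         function(s) match(strsplit(s, "")[[1]], inst$areas))
}

# A dataset whose binarized trait states are fully controlled: scores are
# chosen so that a median split reproduces `states` (1 = upper half,
# 2 = lower half); needs >= 8 tips for the pipeline path, so trait-model
# oracle checks use 8+ tips.
scoresForStates <- function(states) {
  sc <- ifelse(states == 2L, -1, 1) * (1 + seq_along(states) / 10)
  stats::setNames(sc, names(states))
}
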