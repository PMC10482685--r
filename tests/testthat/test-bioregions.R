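starTreeCells <- function() {
  tr <- ape::read.tree(text = "(sp1:1,sp2:1,sp3:1);")
  cells <- rbind(c1 = c(1, 1, 0), c2 = c(0, 1, 1), c3 = c(1, 0, 0))
  colnames(cells) <- paste0("sp", 1:3)
  list(tree = tr, cells = cells)
}

test_that("PhyloSor dissimilarity matches hand accounting", {
  x <- starTreeCells()
  b <- phyloBeta(x$cells, x$tree)
  # identical sets
  expect_equal(b["c1", "c1"], 0)
  # {sp1,sp2} vs {sp2,sp3}: shared branch length 1, each set subtends 2
  expect_equal(b["c1", "c2"], 0.5)
  # disjoint sets share nothing
  expect_equal(b["c2", "c3"], 1)
  # semimetric properties
  expect_equal(b, t(b))
  expect_true(all(b >= 0 & b <= 1))
  empty <- matrix(0, 1, 3, dimnames = list("c4", paste0("sp", 1:3)))
  expect_error(phyloBeta(empty, x$tree), "no species")
})

test_that("PhyloSor agrees with picante on random assemblages", {
  skip_if_not_installed("picante")
  set.seed(42)
  tr <- ape::rtree(12)
  cells <- matrix(rbinom(5 * 12, 1, 0.5), 5, 12,
                  dimnames = list(paste0("c", 1:5), tr$tip.label))
  cells[rowSums(cells) == 0, 1] <- 1
  mine <- phyloBeta(cells, tr)
  ref <- as.matrix(picante::phylosor(cells, tr))
  # picante reports the shared fraction (similarity): ours = 1 - theirs
  off <- row(mine) != col(mine)
  expect_equal(unname((ref[rownames(mine), colnames(mine)] + mine)[off]),
               rep(1, sum(off)), tolerance = 1e-10)
})

test_that("distance weighting preserves scale at the maximum", {
  beta <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  co <- rbind(c(0, 0), c(90, 0))   # quarter of the globe apart
  comb <- weightByDistance(beta, co)
  expect_equal(comb[1, 2], 0.5)    # geo at maximum: scale preserved
  # three cells: geo mid-point scales by eps + (1 - eps) * 0.5
  co3 <- rbind(c(0, 0), c(45, 0), c(90, 0))
  beta3 <- matrix(0.5, 3, 3); diag(beta3) <- 0
  comb3 <- weightByDistance(beta3, co3)
  expect_equal(comb3[1, 2], 0.5 * (0.01 + 0.99 * 0.5), tolerance = 1e-9)
  # beta 0 stays 0
  beta3[1, 2] <- beta3[2, 1] <- 0
  expect_equal(weightByDistance(beta3, co3)[1, 2], 0)
})

test_that("UPGMA reproduces the hand-computed toy dendrogram", {
  d <- matrix(c(0, 2, 8,
                2, 0, 8,
                8, 8, 0), 3, 3,
              dimnames = list(1:3, 1:3))
  h <- upgmaCluster(d)
  expect_equal(h$height, c(1, 4))
  expect_equal(h$merge[1, ], c(-1L, -2L))
  cut <- cutRegions(h, k = 2)
  expect_equal(unname(cut$regions), c(1, 1, 2))
  # all-equal distances: merge heights all equal
  de <- matrix(1, 4, 4); diag(de) <- 0
  he <- upgmaCluster(de)
  expect_equal(he$height, rep(0.5, 3))
})

test_that("UPGMA matches hclust average linkage on random matrices", {
  for (s in 1:10) {
    set.seed(s)
    n <- 12
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    mine <- upgmaCluster(m)
    ref <- stats::hclust(stats::as.dist(m), method = "average")
    # same merge heights (ref heights are full distances, ours are the
    # ultrametric node heights = half)
    expect_equal(mine$height, ref$height / 2, tolerance = 1e-10)
    # same partitions at every k
    for (k in c(2, 4, 7)) {
      a <- stats::cutree(mine, k = k)
      b <- stats::cutree(ref, k = k)
      expect_equal(length(unique(paste(a, b))), k, info = paste(s, k))
    }
  }
})

test_that("region cutting honours k and the silhouette auto mode", {
  # two well-separated blobs
  set.seed(9)
  co <- rbind(matrix(rnorm(10, 0), 5, 2), matrix(rnorm(10, 8), 5, 2))
  d <- as.matrix(stats::dist(co))
  h <- upgmaCluster(d)
  cutN <- cutRegions(h, k = nrow(d))
  expect_equal(length(unique(cutN$regions)), nrow(d))  # singletons
  auto <- cutRegions(h, k = "auto", d = d)
  expect_equal(auto$k, 2)
  expect_equal(length(unique(auto$regions)), 2)
  expect_error(cutRegions(h, k = 1), "k must lie")
  # assignment invariant to cell reordering (up to labels)
  perm <- sample(nrow(d))
  h2 <- upgmaCluster(d[perm, perm])
  a <- cutRegions(h, k = 2)$regions
  b <- cutRegions(h2, k = 2)$regions[order(perm)]
  expect_equal(length(unique(paste(a, b))), 2)
})
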