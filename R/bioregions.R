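# total branch length subtending a species set: sum of edges with at least
# one descendant tip in the set
subtendingLength <- function(tree, tipSets) {
  nTip <- ape::Ntip(tree)
  tp <- postorderEdges(tree)
  nTotal <- 2 * nTip - 1
  # descendant-tip incidence per node, one column per set
  inc <- matrix(FALSE, nTotal, length(tipSets))
  for (s in seq_along(tipSets))
    inc[match(tipSets[[s]], tree$tip.label), s] <- TRUE
  for (e in seq_len(nrow(tp$edge)))
    inc[tp$edge[e, 1], ] <- inc[tp$edge[e, 1], ] | inc[tp$edge[e, 2], ]
  list(inc = inc, edge = tp$edge, len = tp$edge.length)
}

#' Phylogenetic Sorensen (PhyloSor) dissimilarity between cells
#'
#' For each pair of cells, `1 - 2 BL_shared / (BL_i + BL_j)`, where `BL_i`
#' is the total branch length subtending cell i's species (every edge with
#' at least one descendant tip in the set) and `BL_shared` the branch
#' length subtending both sets. Identical assemblages give 0, assemblages
#' sharing no branches give 1.
#'
#' @param cells binary cell x species presence matrix (colnames are
#'   species, a subset of the tree's tips; every cell needs >= 1 species on
#'   the tree).
#' @param tree `ape::phylo` with branch lengths.
#' @return symmetric dissimilarity matrix in \[0, 1\].
#' @export
phyloBeta <- function(cells, tree) {
  sp <- colnames(cells)
  unknown <- setdiff(sp[colSums(cells) > 0], tree$tip.label)
  if (length(unknown))
    stopf("species not on the tree: %s", paste(unknown, collapse = ", "))
  sets <- lapply(seq_len(nrow(cells)), function(i)
    sp[cells[i, ] > 0])
  empty <- lengths(sets) == 0
  if (any(empty))
    stopf("cell with no species on the tree: %s",
          paste(rownames(cells)[empty], collapse = ", "))
  sub <- subtendingLength(tree, sets)
  n <- length(sets)
  # per-edge incidence rows aligned with edge child nodes
  edgeInc <- sub$inc[sub$edge[, 2], , drop = FALSE]
  BL <- colSums(edgeInc * sub$len)
  out <- matrix(0, n, n, dimnames = list(rownames(cells), rownames(cells)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- sum(sub$len[edgeInc[, i] & edgeInc[, j]])
    out[i, j] <- out[j, i] <- 1 - 2 * shared / (BL[i] + BL[j])
  }
  out
}

#' Combine phylogenetic beta-diversity with geographic distance
#'
#' Great-circle distances between cell centroids (haversine, Earth radius
#' 6371 km) are rescaled to \[0, 1\] by their maximum and multiplied into
#' the beta-diversity matrix with a small floor:
#' `combined = beta * (eps + (1 - eps) * geo)`. The floor keeps coincident
#' cells (zero distance) from collapsing the dissimilarity entirely while
#' leaving the scale unchanged at the maximum distance.
#'
#' @param beta dissimilarity matrix from [phyloBeta()].
#' @param coordinates two-column matrix/data.frame (longitude, latitude in
#'   decimal degrees), rows matching `beta`'s order.
#' @param eps floor weight for zero-distance pairs.
#' @return combined dissimilarity matrix.
#' @export
weightByDistance <- function(beta, coordinates, eps = 0.01) {
  co <- as.matrix(coordinates)
  if (nrow(co) != nrow(beta)) stopf("coordinate rows must match beta")
  if (any(abs(co[, 2]) > 90) || any(abs(co[, 1]) > 360))
    stopf("coordinates must be lon/lat in decimal degrees")
  n <- nrow(co)
  geo <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    geo[i, j] <- geo[j, i] <-
      geosphere::distHaversine(co[i, ], co[j, ], r = 6371)
  mx <- max(geo)
  if (mx > 0) geo <- geo / mx
  beta * (eps + (1 - eps) * geo)
}

#' UPGMA (average-linkage) clustering with a deterministic tie-break
#'
#' Classic unweighted pair group method with arithmetic mean: repeatedly
#' merge the pair of clusters at smallest average dissimilarity, averaging
#' with cluster-size weights; exact ties merge the pair with the smallest
#' cell ids. Returns an `stats::hclust`-compatible object (heights are
#' half the merge dissimilarity, the conventional dendrogram scale), so
#' [stats::cutree()] and plotting work directly.
#'
#' @param d symmetric zero-diagonal dissimilarity matrix.
#' @return an object of class `hclust`.
#' @export
upgmaCluster <- function(d) {
  d <- as.matrix(d)
  if (max(abs(d - t(d))) > 1e-9) stopf("dissimilarity must be symmetric")
  n <- nrow(d)
  if (n < 2) stopf("need at least two cells")
  labels <- rownames(d) %||% as.character(seq_len(n))
  size <- rep(1, n)
  id <- -seq_len(n)          # hclust convention: negatives = singletons
  active <- seq_len(n)
  D <- d; diag(D) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (step in seq_len(n - 1)) {
    # smallest distance; ties -> smallest (i, j) pair among active ids
    sub <- D[active, active, drop = FALSE]
    m <- min(sub)
    cand <- which(sub <= m + 0, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- active[cand[1, 1]]; j <- active[cand[1, 2]]
    merge[step, ] <- c(id[i], id[j])
    height[step] <- m / 2
    # UPGMA update: size-weighted average to every other cluster
    for (k in setdiff(active, c(i, j)))
      D[i, k] <- D[k, i] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    size[i] <- size[i] + size[j]
    id[i] <- step
    active <- setdiff(active, j)
  }
  out <- list(merge = merge, height = height,
              order = hclustOrder(merge, n), labels = labels,
              method = "upgma", call = match.call(),
              dist.method = "user")
  class(out) <- "hclust"
  out
}

# leaf order for plotting (standard recursive unfolding of the merge tree)
hclustOrder <- function(merge, n) {
  expand <- function(i) {
    if (i < 0) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' Cut a dendrogram into biogeographic regions
#'
#' Cuts an UPGMA dendrogram into `k` regions, or, with `k = "auto"`,
#' selects k in \[2, kMax\] maximizing the mean silhouette width on the
#' supplied dissimilarity.
#'
#' @param dendrogram `hclust` object from [upgmaCluster()].
#' @param k number of regions, or `"auto"`.
#' @param d dissimilarity matrix (required for `"auto"`).
#' @param kMax largest k tried in auto mode.
#' @return list: `regions` (named integer vector, labels 1..k), `k`,
#'   `silhouette` (mean width, auto mode only).
#' @export
cutRegions <- function(dendrogram, k = "auto", d = NULL, kMax = 8) {
  n <- length(dendrogram$labels)
  if (identical(k, "auto")) {
    if (is.null(d)) stopf("auto mode needs the dissimilarity matrix")
    kMax <- min(kMax, n - 1)
    best <- NULL
    for (kk in 2:kMax) {
      cl <- stats::cutree(dendrogram, k = kk)
      sil <- mean(cluster::silhouette(cl, dmatrix = as.matrix(d))[,
                                                                  "sil_width"])
      if (is.null(best) || sil > best$silhouette)
        best <- list(regions = cl, k = kk, silhouette = sil)
    }
    return(best)
  }
  if (k < 2 || k > n) stopf("k must lie in [2, %d]", n)
  list(regions = stats::cutree(dendrogram, k = k), k = k,
       silhouette = NA_real_)
}
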