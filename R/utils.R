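#' Node ages (Ma before present) for a dated tree
#'
#' Depths are measured from the most recent tip (age 0); the root has the
#' largest age. Works on any rooted tree with branch lengths in My.
#'
#' @param tree an `ape::phylo`.
#' @return numeric vector of ages indexed by node id (tips first).
#' @export
nodeAges <- function(tree) {
  n <- ape::Ntip(tree)
  depth <- ape::node.depth.edgelength(tree)  # distance from root
  max(depth) - depth
}

# Derive a reproducible sub-seed (< 2^31) from a master seed and a label.
deriveSeed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629) + 1L
}

# Postorder edge indices: children before parents.
postorderEdges <- function(tree) {
  reorder(tree, "postorder")
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

#' @describeIn BiogeoDataset number of tips in the dataset's tree
#' @param object,x a `BiogeoDataset`
#' @export
nTips <- function(object) ape::Ntip(object@tree)

#' @describeIn BiogeoDataset the phylogeny
#' @export
datasetTree <- function(object) object@tree

#' @describeIn BiogeoDataset ordered area names
#' @export
areaNames <- function(object) colnames(object@presence)

#' @describeIn BiogeoDataset tips x areas presence matrix
#' @export
presenceMatrix <- function(object) object@presence

#' @describeIn BiogeoDataset inter-area distance matrix (km)
#' @export
distanceMatrix <- function(object) object@distances

#' @describeIn BiogeoDataset oceanic/continental barrier classification
#' @export
barrierMatrix <- function(object) object@barriers

#' @describeIn BiogeoDataset trait factor score table
#' @export
traitTable <- function(object) object@traits

#' @describeIn BiogeoDataset epoch slices (young to old)
#' @export
epochSlices <- function(object) object@epochs

setMethod("show", "BiogeoDataset", function(object) {
  cat("BiogeoDataset:", object@metadata$clade %||% "<unnamed>", "\n")
  cat(" ", nTips(object), "tips,", ncol(object@presence), "areas (",
      paste(areaNames(object), collapse = " "), ")\n")
  cat(" ", length(object@epochs), "epoch slice(s); root age",
      sprintf("%.3f", max(nodeAges(object@tree))), "Ma\n")
  if (ncol(object@traits))
    cat("  trait factors:", paste(colnames(object@traits), collapse = ", "),
        "\n")
  amb <- object@metadata$ambiguousTrait
  if (length(amb))
    cat(" ", length(amb), "species with missing trait scores (ambiguous)\n")
})

#' @describeIn RangeStateSpace number of states (ranges x trait levels)
#' @param object a `RangeStateSpace`
#' @export
nStates <- function(object) length(object@labels)

#' @describeIn RangeStateSpace number of distinct geographic ranges
#' @export
nRanges <- function(object) length(object@masks)

#' @describeIn RangeStateSpace state labels
#' @export
stateLabels <- function(object) object@labels

setMethod("show", "RangeStateSpace", function(object) {
  cat("RangeStateSpace:", length(object@areas), "areas, max range size",
      object@maxRangeSize, "\n  ", nStates(object), "states",
      if (object@traitAugmented) "(trait-augmented)" else "", "\n")
})

setMethod("show", "BiogeoFit", function(object) {
  cat("BiogeoFit:", modelLabel(object@modelSpec), "\n")
  cat("  lnL =", sprintf("%.4f", object@lnL),
      " k =", object@k, " AICc =", sprintf("%.4f", object@AICc), "\n")
  cat("  params:", paste(sprintf("%s=%.5g", names(object@params),
                                 object@params), collapse = ", "), "\n")
})

setMethod("show", "BiogeoModelSet", function(object) {
  cat("BiogeoModelSet:", length(object@fits), "models |",
      object@baseModel, "/", object@mdmm, "| trait:", object@trait, "\n")
  w <- sort(object@weights, decreasing = TRUE)
  cat("  top weights:", paste(sprintf("%s=%.3f", names(w)[seq_len(min(3,
      length(w)))], w[seq_len(min(3, length(w)))]), collapse = ", "), "\n")
})

setMethod("show", "CladeReport", function(object) {
  cat("CladeReport: trait", object@trait, "\n")
  cat("  curve (Q1..Q4):", paste(sprintf("%.4f", object@curve),
                                 collapse = ", "), "\n")
  cat("  magnitude:", sprintf("%.2f%%", object@magnitudePct),
      " shape:", object@shape,
      " trait-dependent weight:", sprintf("%.3f", object@traitWeight), "\n")
})

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical label for a model specification, e.g. "DEC+m2x[median]".
modelLabel <- function(spec) {
  suffix <- if (isTRUE(spec$hasM2) && isTRUE(spec$hasX)) "+m2x"
            else if (isTRUE(spec$hasM2)) "+m2"
            else if (isTRUE(spec$hasX)) "+x"
            else ""
  lab <- paste0(spec$base, suffix)
  if (isTRUE(spec$hasM2) && is.character(spec$split))
    lab <- paste0(lab, "[", spec$split, "]")
  lab
}
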