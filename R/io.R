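#' Read and validate a dated phylogeny from a newick file
#'
#' Wraps `ape::read.tree` and enforces the invariants the DEC-family
#' machinery relies on: rooted, strictly bifurcating, non-negative branch
#' lengths (in My), unique tip labels. Ultrametricity is not enforced; a
#' warning is emitted if tip depths differ by more than 1e-6 x root age,
#' since epoch slicing uses node ages measured from the deepest tip.
#'
#' @param path newick file.
#' @return an `ape::phylo`.
#' @examples
#' tf <- tempfile(fileext = ".nwk")
#' writeLines("((a:1,b:1):1,c:2);", tf)
#' tr <- readNewick(tf)
#' @export
readNewick <- function(path) {
  if (!file.exists(path)) stopf("newick file not found: %s", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stopf("newick parse failure: %s",
                                           conditionMessage(e)))
  if (is.null(tr)) stopf("newick parse failure: %s", path)
  checkTree(tr)
  tr
}

checkTree <- function(tr) {
  if (is.null(tr$edge.length)) stopf("tree has no branch lengths")
  if (!ape::is.rooted(tr)) stopf("tree must be rooted")
  if (!ape::is.binary(tr)) stopf("tree contains polytomies")
  if (any(tr$edge.length < 0)) stopf("negative branch length in tree")
  if (anyDuplicated(tr$tip.label))
    stopf("duplicate tip label: %s",
          tr$tip.label[duplicated(tr$tip.label)][1])
  ages <- nodeAges(tr)[seq_len(ape::Ntip(tr))]
  rootAge <- max(nodeAges(tr))
  if (diff(range(ages)) > 1e-6 * max(rootAge, 1))
    warning("tree is not ultrametric; node ages measured from deepest tip",
            call. = FALSE)
  invisible(tr)
}

#' Read a lagrange/PHYLIP-style geography file
#'
#' Format: a header line `"<n_species> <n_areas> (<name1> <name2> ...)"`
#' followed by one line per species: label, whitespace, and a binary string
#' of length `n_areas` (1 = present). Every species must occupy at least one
#' area.
#'
#' @param path geography file.
#' @return binary matrix, species as rownames, area names as colnames.
#' @examples
#' tf <- tempfile(fileext = ".data")
#' writeLines(c("3 2 (A B)", "sp1 10", "sp2 01", "sp3 11"), tf)
#' readGeography(tf)
#' @export
readGeography <- function(path) {
  if (!file.exists(path)) stopf("geography file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hd <- regmatches(lines[1],
                   regexec("^\\s*(\\d+)\\s+(\\d+)\\s*\\(([^)]*)\\)\\s*$",
                           lines[1]))[[1]]
  if (length(hd) != 4)
    stopf("malformed geography header: %s", lines[1])
  nsp <- as.integer(hd[2]); na <- as.integer(hd[3])
  areas <- strsplit(trimws(hd[4]), "\\s+")[[1]]
  if (length(areas) != na)
    stopf("header declares %d areas but names %d", na, length(areas))
  body <- lines[-1]
  if (length(body) != nsp)
    stopf("header declares %d species but file has %d rows", nsp,
          length(body))
  parts <- strsplit(trimws(body), "\\s+")
  labs <- vapply(parts, `[[`, character(1), 1)
  bits <- vapply(parts, function(p) paste(p[-1], collapse = ""),
                 character(1))
  if (anyDuplicated(labs)) stopf("duplicate species label: %s",
                                 labs[duplicated(labs)][1])
  m <- matrix(0L, nsp, na, dimnames = list(labs, areas))
  for (i in seq_len(nsp)) {
    if (nchar(bits[i]) != na)
      stopf("species %s: range string has length %d, expected %d",
            labs[i], nchar(bits[i]), na)
    v <- strsplit(bits[i], "")[[1]]
    if (!all(v %in% c("0", "1")))
      stopf("species %s: non-binary character in range string", labs[i])
    m[i, ] <- as.integer(v)
    if (sum(m[i, ]) == 0)
      stopf("species %s occupies no area", labs[i])
  }
  m
}

#' Read an area-by-area matrix (distances, MDMM or barrier classes) from CSV
#'
#' The CSV must carry area names as both header row and first column, in the
#' same order as the geography file. Symmetry is enforced to 1e-9; MDMMs
#' must lie in \[0,1\]; barrier entries must be `continental`/`oceanic` off
#' the diagonal and `self` on it.
#'
#' @param path CSV file.
#' @param kind one of `"distances"`, `"mdmm"`, `"barriers"`.
#' @param areas optional area names to check order against.
#' @return numeric matrix (character for `"barriers"`).
#' @export
readAreaMatrix <- function(path, kind = c("distances", "mdmm", "barriers"),
                           areas = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stopf("%s matrix is not square", kind)
  if (!identical(rownames(m), colnames(m)))
    stopf("%s matrix row/column names disagree", kind)
  if (!is.null(areas) && !identical(colnames(m), areas))
    stopf("%s matrix area order does not match geography (%s)", kind,
          paste(areas, collapse = " "))
  checkAreaMatrix(m, kind)
}

# shared validation for in-memory and file-based matrices
checkAreaMatrix <- function(m, kind) {
  if (kind == "barriers") {
    if (!identical(m, t(m))) stopf("barrier matrix not symmetric")
    if (!all(diag(m) == "self")) stopf("barrier diagonal must be 'self'")
    off <- m[row(m) != col(m)]
    bad <- setdiff(unique(off), c("continental", "oceanic"))
    if (length(bad)) stopf("unknown barrier label: %s", bad[1])
    return(m)
  }
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stopf("%s matrix has non-finite entries", kind)
  if (max(abs(m - t(m))) > 1e-9) stopf("%s matrix asymmetric beyond 1e-9",
                                       kind)
  if (kind == "distances") {
    if (any(m < 0)) stopf("negative distance")
    if (any(diag(m) != 0)) stopf("distance diagonal must be zero")
  } else {
    if (any(m < 0 | m > 1)) stopf("dispersal multiplier outside [0,1]")
  }
  m
}

#' Build a manual dispersal multiplier matrix from a barrier classification
#'
#' Three standard scenarios are supported: `"equal"` puts no penalty on any
#' pair (all multipliers 1); `"half"` sets continental pairs to 0.5 and
#' oceanic pairs to 0.125; `"tenth"` sets continental pairs to 0.5 and
#' oceanic pairs to 0.05 (oceanic dispersal ten times less likely than
#' continental).
#'
#' @param scenario `"equal"`, `"half"` or `"tenth"`.
#' @param barriers symmetric character barrier matrix (see
#'   [readAreaMatrix()]).
#' @return numeric MDMM with 1 on the diagonal (diagonal is ignored by the
#'   rate construction).
#' @export
mdmmScenario <- function(scenario = c("equal", "half", "tenth"), barriers) {
  scenario <- match.arg(scenario)
  vals <- switch(scenario,
                 equal = c(continental = 1, oceanic = 1),
                 half = c(continental = 0.5, oceanic = 0.125),
                 tenth = c(continental = 0.5, oceanic = 0.05))
  m <- matrix(1, nrow(barriers), ncol(barriers),
              dimnames = dimnames(barriers))
  for (lab in names(vals)) m[barriers == lab] <- vals[[lab]]
  diag(m) <- 1
  m
}

#' Cross-link components into a validated BiogeoDataset
#'
#' Checks label consistency across the tree, geography, trait table and
#' matrices. Tips without geography are an error; tips without a trait score
#' are retained and flagged ambiguous (their binary trait state carries
#' likelihood 1 for both states downstream). Epoch slices must tile
#' \[0, root age\]; if `epochs` is `NULL`, a single slice covering the whole
#' tree with the supplied `mdmm` and all areas allowed is used.
#'
#' @param tree `ape::phylo` (see [readNewick()]).
#' @param presence binary species x areas matrix (see [readGeography()]).
#' @param distances inter-area distance matrix, km.
#' @param barriers barrier classification matrix.
#' @param traits data.frame of continuous factor scores, rownames species;
#'   may be `NULL` (no trait analyses possible).
#' @param mdmm A x A multiplier matrix used when `epochs` is `NULL`.
#' @param epochs optional list of slices, each
#'   `list(start=, end=, mdmm=, allowed=)` with times in Ma (young to old).
#' @param clade clade name for reports.
#' @return a [BiogeoDataset-class].
#' @export
buildDataset <- function(tree, presence, distances, barriers, traits = NULL,
                         mdmm = NULL, epochs = NULL, clade = "clade") {
  checkTree(tree)
  tips <- tree$tip.label
  miss <- setdiff(tips, rownames(presence))
  if (length(miss))
    stopf("tip(s) missing from geography: %s",
          paste(miss, collapse = ", "))
  extra <- setdiff(rownames(presence), tips)
  if (length(extra))
    stopf("geography species absent from tree: %s",
          paste(extra, collapse = ", "))
  presence <- presence[tips, , drop = FALSE]
  areas <- colnames(presence)
  distances <- checkAreaMatrix(distances, "distances")
  barriers <- checkAreaMatrix(barriers, "barriers")
  if (!identical(colnames(distances), areas))
    stopf("distance matrix areas do not match geography")
  if (!identical(colnames(barriers), areas))
    stopf("barrier matrix areas do not match geography")
  if (is.null(traits)) {
    traits <- data.frame(row.names = character())
  } else {
    traits <- as.data.frame(traits)
    unknown <- setdiff(rownames(traits), tips)
    if (length(unknown))
      stopf("trait table species absent from tree: %s",
            paste(unknown, collapse = ", "))
    if (!all(vapply(traits, is.numeric, logical(1))))
      stopf("trait factor scores must be numeric")
    if (any(vapply(traits, function(x) any(is.infinite(x)), logical(1))))
      stopf("trait factor scores must be finite or NA")
  }
  rootAge <- max(nodeAges(tree))
  if (is.null(epochs)) {
    if (is.null(mdmm)) mdmm <- mdmmScenario("equal", barriers)
    mdmm <- checkAreaMatrix(mdmm, "mdmm")
    epochs <- list(list(start = 0, end = rootAge, mdmm = mdmm,
                        allowed = rep(TRUE, length(areas))))
  } else {
    epochs <- lapply(epochs, function(sl) {
      sl$mdmm <- checkAreaMatrix(sl$mdmm, "mdmm")
      if (is.null(sl$allowed)) sl$allowed <- rep(TRUE, length(areas))
      sl
    })
  }
  ambiguous <- character()
  if (ncol(traits) > 0) {
    scored <- rownames(traits)[stats::complete.cases(traits)]
    ambiguous <- setdiff(tips, scored)
  }
  methods::new("BiogeoDataset", tree = tree, presence = presence,
               distances = distances, barriers = barriers, epochs = epochs,
               traits = traits,
               metadata = list(clade = clade, nTips = length(tips),
                               ambiguousTrait = ambiguous))
}

#' Write a clade report to JSON
#'
#' Serializes a [CladeReport-class] deterministically (full double
#' precision, stable key order), so identical configuration and seed yield
#' byte-identical files.
#'
#' @param report a `CladeReport`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeCladeReport <- function(report, path) {
  obj <- list(
    trait = report@trait,
    curve = as.list(stats::setNames(as.numeric(report@curve),
                                    c("Q1", "Q2", "Q3", "Q4"))),
    magnitude_pct = report@magnitudePct,
    shape = report@shape,
    trait_dependent_weight = report@traitWeight,
    comparison = report@comparison,
    models = report@modelTable,
    provenance = report@provenance
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Write stochastic-map event tables as TSV
#'
#' @param maps result of [stochasticMaps()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeEventTable <- function(maps, path) {
  ev <- maps$events
  utils::write.table(ev, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a geography file in the lagrange/PHYLIP dialect
#'
#' @param presence binary species x areas matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGeography <- function(presence, path) {
  hdr <- sprintf("%d %d (%s)", nrow(presence), ncol(presence),
                 paste(colnames(presence), collapse = " "))
  rows <- vapply(seq_len(nrow(presence)), function(i)
    paste0(rownames(presence)[i], " ",
           paste(presence[i, ], collapse = "")), character(1))
  writeLines(c(hdr, rows), path)
  invisible(path)
}

writeAreaMatrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, quote = FALSE)
  invisible(path)
}
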