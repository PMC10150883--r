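#' @import methods
NULL

.OMICS_KINDS <- c("rnaseq", "cna", "methylation")

#' OmicsMatrix: one omics block, features x samples
#'
#' Container for a single omics data block with `m` features in rows and `n`
#' samples in columns. Values must be complete (no missing entries); copy
#' number blocks must be integer-valued and methylation blocks must lie in
#' \[0, 1\].
#'
#' @slot values numeric matrix, features x samples, with feature IDs as
#'   rownames and sample IDs as colnames.
#' @slot omicsKind one of `"rnaseq"`, `"cna"`, `"methylation"`.
#' @slot droppedFeatures number of features removed (e.g. for missing values)
#'   while constructing the object from a file.
#'
#' @seealso [readOmicsMatrix()], [writeOmicsMatrix()]
#' @export
setClass("OmicsMatrix",
  representation(
    values = "matrix",
    omicsKind = "character",
    droppedFeatures = "integer"
  ),
  prototype(droppedFeatures = 0L)
)

setValidity("OmicsMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry feature IDs (rownames) and sample IDs (colnames)")
  if (nrow(v) < 2L) msg <- c(msg, "need at least 2 features")
  if (ncol(v) < 3L) msg <- c(msg, "need at least 3 samples")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, paste("duplicate feature IDs:",
      paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
  if (anyDuplicated(colnames(v)))
    msg <- c(msg, paste("duplicate sample IDs:",
      paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  if (anyNA(v)) msg <- c(msg, "values contain missing entries")
  if (length(object@omicsKind) != 1L || !object@omicsKind %in% .OMICS_KINDS)
    msg <- c(msg, paste("omicsKind must be one of:", paste(.OMICS_KINDS, collapse = ", ")))
  if (length(msg) == 0L && object@omicsKind == "cna" && !anyNA(v)) {
    bad <- which(v != round(v), arr.ind = TRUE)
    if (nrow(bad) > 0L)
      msg <- c(msg, sprintf("cna values must be integers; first offender: feature '%s', sample '%s' (value %g)",
        rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]], v[bad[1, 1], bad[1, 2]]))
  }
  if (length(msg) == 0L && object@omicsKind == "methylation" && !anyNA(v)) {
    bad <- which(v < 0 | v > 1, arr.ind = TRUE)
    if (nrow(bad) > 0L)
      msg <- c(msg, sprintf("methylation values must lie in [0,1]; first offender: feature '%s', sample '%s' (value %g)",
        rownames(v)[bad[1, 1]], colnames(v)[bad[1, 2]], v[bad[1, 1], bad[1, 2]]))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (features x samples) with dimnames.
#' @param omicsKind `"rnaseq"`, `"cna"` or `"methylation"`.
#' @param droppedFeatures number of features dropped during loading.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'   dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' OmicsMatrix(m, "rnaseq")
#' @export
OmicsMatrix <- function(values, omicsKind, droppedFeatures = 0L) {
  new("OmicsMatrix", values = values, omicsKind = omicsKind,
      droppedFeatures = as.integer(droppedFeatures))
}

#' DrugResponse: per-sample drug response for one drug
#'
#' Holds IC50 values (natural-log scale assumed) and/or binary
#' sensitive/non-sensitive labels for one drug. Label 1 = sensitive,
#' 0 = non-sensitive.
#'
#' @slot sampleIDs character vector of sample identifiers.
#' @slot ic50 numeric IC50 per sample (may be all `NA` if labels are given).
#' @slot labels integer 0/1 per sample (`NA` before binarization).
#' @slot drugID drug identifier.
#' @slot threshold numeric threshold used at binarization (`NA` before).
#' @seealso [binarizeIC50()], [readDrugResponse()]
#' @export
setClass("DrugResponse",
  representation(
    sampleIDs = "character",
    ic50 = "numeric",
    labels = "integer",
    drugID = "character",
    threshold = "numeric"
  ),
  prototype(threshold = NA_real_)
)

setValidity("DrugResponse", function(object) {
  n <- length(object@sampleIDs)
  msg <- character(0)
  if (anyDuplicated(object@sampleIDs))
    msg <- c(msg, "duplicate sample IDs in response table")
  if (length(object@ic50) != n) msg <- c(msg, "ic50 length != number of samples")
  if (length(object@labels) != n) msg <- c(msg, "labels length != number of samples")
  if (!all(object@labels %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "labels must be 0, 1 or NA")
  if (length(object@drugID) != 1L) msg <- c(msg, "drugID must be a single string")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugResponse table
#'
#' @param sampleIDs character sample identifiers.
#' @param ic50 numeric IC50 per sample (optional if `labels` given).
#' @param labels integer 0/1 per sample (optional if `ic50` given).
#' @param drugID drug identifier string.
#' @return A [DrugResponse-class] object.
#' @export
DrugResponse <- function(sampleIDs, ic50 = NULL, labels = NULL, drugID = "drug") {
  n <- length(sampleIDs)
  if (is.null(ic50)) ic50 <- rep(NA_real_, n)
  if (is.null(labels)) labels <- rep(NA_integer_, n)
  new("DrugResponse", sampleIDs = as.character(sampleIDs),
      ic50 = as.numeric(ic50), labels = as.integer(labels),
      drugID = drugID)
}

#' AlignedDataset: omics blocks sharing one sample order, plus labels
#'
#' @slot blocks list of [OmicsMatrix-class] objects with identical sample ID
#'   order, named by omics kind.
#' @slot labels integer 0/1 per sample; both classes must be present.
#' @slot drugID drug identifier.
#' @slot sampleIDs the shared sample order.
#' @seealso [alignSamples()]
#' @export
setClass("AlignedDataset",
  representation(
    blocks = "list",
    labels = "integer",
    drugID = "character",
    sampleIDs = "character"
  )
)

setValidity("AlignedDataset", function(object) {
  msg <- character(0)
  n <- length(object@sampleIDs)
  for (b in object@blocks) {
    if (!is(b, "OmicsMatrix")) msg <- c(msg, "blocks must be OmicsMatrix objects")
    else if (!identical(colnames(b@values), object@sampleIDs))
      msg <- c(msg, sprintf("block '%s' sample order differs from dataset order", b@omicsKind))
  }
  if (length(object@labels) != n) msg <- c(msg, "labels length != number of samples")
  if (anyNA(object@labels) || !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1 with no NA")
  if (length(unique(object@labels)) < 2L)
    msg <- c(msg, "both classes must be present")
  if (length(msg)) msg else TRUE
})

#' SparseComponent: rank-1 sparse PCA solution
#'
#' Result of the L0-constrained rank-1 problem
#' \eqn{\max_{u,v} u^\top X v} s.t. \eqn{\|u\|_0 \le s}, \eqn{\|u\|_2 = \|v\|_2 = 1}.
#'
#' @slot u sparse loading vector (length m, unit norm, at most `s` nonzeros).
#' @slot v component score vector (length n, unit norm).
#' @slot support integer indices where `u` is nonzero.
#' @slot s sparsity budget.
#' @slot objective final objective value \eqn{u^\top X v}.
#' @slot objectiveTrace per-iteration objective values (non-decreasing).
#' @slot iterations number of inner iterations run.
#' @slot converged whether the inner tolerance was reached.
#' @seealso [spcaRank1()]
#' @export
setClass("SparseComponent",
  representation(
    u = "numeric", v = "numeric", support = "integer", s = "integer",
    objective = "numeric", objectiveTrace = "numeric",
    iterations = "integer", converged = "logical"
  )
)

setValidity("SparseComponent", function(object) {
  msg <- character(0)
  if (length(object@support) > object@s)
    msg <- c(msg, "support larger than sparsity budget s")
  if (abs(sqrt(sum(object@u^2)) - 1) > 1e-9) msg <- c(msg, "u is not unit norm")
  if (abs(sqrt(sum(object@v^2)) - 1) > 1e-9) msg <- c(msg, "v is not unit norm")
  if (any(object@u[setdiff(seq_along(object@u), object@support)] != 0))
    msg <- c(msg, "u has nonzeros outside its support")
  if (length(msg)) msg else TRUE
})

#' ImportanceScores: normalized per-feature random-forest Gini importance
#'
#' @slot scores named numeric vector of per-feature importance; non-negative,
#'   summing to 1 when `normalized`.
#' @slot normalized whether scores are normalized to sum 1.
#' @slot oobAccuracy out-of-bag accuracy of the forest the scores came from.
#' @slot method `"node_gini"` (sum of node Gini values over nodes splitting on
#'   the feature, per tree, summed over the forest) or `"impurity"`
#'   (conventional mean decrease in impurity).
#' @seealso [rfFeatureImportance()]
#' @export
setClass("ImportanceScores",
  representation(
    scores = "numeric", normalized = "logical",
    oobAccuracy = "numeric", method = "character"
  )
)

setValidity("ImportanceScores", function(object) {
  msg <- character(0)
  if (any(object@scores < 0)) msg <- c(msg, "importance scores must be non-negative")
  if (isTRUE(object@normalized) && abs(sum(object@scores) - 1) > 1e-9)
    msg <- c(msg, "normalized scores must sum to 1")
  if (length(msg)) msg else TRUE
})

#' SpcaFiResult: outcome of the SPCA / feature-importance loop
#'
#' @slot component final [SparseComponent-class] on the reweighted matrix.
#' @slot importance [ImportanceScores-class] over the final support.
#' @slot selectedFeatureIDs feature IDs in the final support.
#' @slot nOuterIterations outer iterations run.
#' @slot converged TRUE if the support was identical on consecutive outer
#'   iterations before the cap.
#' @slot weights final per-feature row weights.
#' @slot featureIDs all feature IDs of the input block.
#' @seealso [spcaFiLoop()]
#' @export
setClass("SpcaFiResult",
  representation(
    component = "SparseComponent",
    importance = "ImportanceScores",
    selectedFeatureIDs = "character",
    nOuterIterations = "integer",
    converged = "logical",
    weights = "numeric",
    featureIDs = "character"
  )
)

#' SimilarityMatrix: n x n sample similarity for one omics block
#'
#' @slot values symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @slot sampleIDs sample identifiers (row/col names).
#' @slot omicsKind omics kind the similarities were computed from.
#' @slot method `"pearson"` or `"kendall"`.
#' @seealso [pearsonSimilarity()], [kendallSimilarity()]
#' @export
setClass("SimilarityMatrix",
  representation(
    values = "matrix", sampleIDs = "character",
    omicsKind = "character", method = "character"
  )
)

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character(0)
  if (nrow(v) != ncol(v)) msg <- c(msg, "similarity matrix must be square")
  if (nrow(v) != length(object@sampleIDs)) msg <- c(msg, "sampleIDs length mismatch")
  if (max(abs(v - t(v))) > 1e-9) msg <- c(msg, "similarity matrix must be symmetric (1e-9)")
  if (any(abs(diag(v) - 1) > 1e-12)) msg <- c(msg, "diagonal entries must equal 1")
  if (any(v < -1 - 1e-9 | v > 1 + 1e-9)) msg <- c(msg, "entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' FusedMatrix: horizontal concatenation of per-omics similarity networks
#'
#' An n x (B*n) matrix for B omics blocks; slicing columns
#' `((b-1)*n+1):(b*n)` recovers the b-th similarity matrix exactly.
#'
#' @slot values the fused matrix, rows = samples.
#' @slot blockOrder omics kinds in concatenation order.
#' @slot sampleIDs sample identifiers.
#' @seealso [fuseNetworks()], [extractBlock()]
#' @export
setClass("FusedMatrix",
  representation(
    values = "matrix", blockOrder = "character", sampleIDs = "character"
  )
)

setValidity("FusedMatrix", function(object) {
  n <- length(object@sampleIDs)
  msg <- character(0)
  if (nrow(object@values) != n) msg <- c(msg, "row count != number of samples")
  if (ncol(object@values) != n * length(object@blockOrder))
    msg <- c(msg, "column count != blocks * n")
  if (length(msg)) msg else TRUE
})

#' SimDataset: synthetic multi-omics dataset with planted truth
#'
#' @slot dataset an [AlignedDataset-class].
#' @slot truth per-block list of planted informative feature IDs.
#' @slot trapFeatures IDs of uninformative high-variance-direction trap
#'   features (variance_trap fixture only; empty otherwise).
#' @slot config the [simConfig()] list that produced the dataset.
#' @seealso [simulateMultiOmics()], [simulateFixture()]
#' @export
setClass("SimDataset",
  representation(
    dataset = "AlignedDataset",
    truth = "list",
    trapFeatures = "character",
    config = "list"
  ),
  prototype(trapFeatures = character(0))
)

## ---- show methods ----

setMethod("show", "OmicsMatrix", function(object) {
  cat(sprintf("OmicsMatrix [%s]: %d features x %d samples",
    object@omicsKind, nrow(object@values), ncol(object@values)))
  if (object@droppedFeatures > 0L)
    cat(sprintf(" (%d features dropped at load)", object@droppedFeatures))
  cat("\n")
})

setMethod("show", "DrugResponse", function(object) {
  cat(sprintf("DrugResponse '%s': %d samples", object@drugID, length(object@sampleIDs)))
  if (!all(is.na(object@labels)))
    cat(sprintf("; labels: %d sensitive / %d non-sensitive",
      sum(object@labels == 1L, na.rm = TRUE), sum(object@labels == 0L, na.rm = TRUE)))
  cat("\n")
})

setMethod("show", "AlignedDataset", function(object) {
  cat(sprintf("AlignedDataset '%s': %d samples, %d blocks (%s); %d sensitive / %d non-sensitive\n",
    object@drugID, length(object@sampleIDs), length(object@blocks),
    paste(vapply(object@blocks, function(b) b@omicsKind, character(1)), collapse = ", "),
    sum(object@labels == 1L), sum(object@labels == 0L)))
})

setMethod("show", "SparseComponent", function(object) {
  cat(sprintf("SparseComponent: |support| = %d (s = %d), objective = %.6g, %d iterations (%s)\n",
    length(object@support), object@s, object@objective, object@iterations,
    if (object@converged) "converged" else "max iterations"))
})

setMethod("show", "SpcaFiResult", function(object) {
  cat(sprintf("SpcaFiResult: %d features selected of %d, %d outer iterations (%s), OOB accuracy %.3f\n",
    length(object@selectedFeatureIDs), length(object@featureIDs),
    object@nOuterIterations,
    if (object@converged) "support stable" else "support still changing",
    object@importance@oobAccuracy))
})

setMethod("show", "SimilarityMatrix", function(object) {
  cat(sprintf("SimilarityMatrix [%s, %s]: %d x %d samples\n",
    object@omicsKind, object@method, nrow(object@values), ncol(object@values)))
})

setMethod("show", "FusedMatrix", function(object) {
  cat(sprintf("FusedMatrix: %d samples x %d columns (%d blocks: %s)\n",
    nrow(object@values), ncol(object@values), length(object@blockOrder),
    paste(object@blockOrder, collapse = " | ")))
})

setMethod("show", "SimDataset", function(object) {
  cat("SimDataset with planted truth:\n")
  show(object@dataset)
  cat(sprintf("  planted informative features per block: %s\n",
    paste(vapply(object@truth, length, integer(1)), collapse = ", ")))
  if (length(object@trapFeatures))
    cat(sprintf("  trap features: %d\n", length(object@trapFeatures)))
})
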