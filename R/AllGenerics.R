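#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `featureIDs()`,
#' `sampleIDs()`, `omicsKind()`, `responseLabels()`, `drugID()`,
#' `selectedFeatures()`, `importanceScores()`, `blockOrder()`.
#'
#' @param x an object of one of the package's S4 classes.
#' @return The corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("omicsKind", function(x) standardGeneric("omicsKind"))
#' @rdname accessors
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))
#' @rdname accessors
#' @export
setGeneric("drugID", function(x) standardGeneric("drugID"))
#' @rdname accessors
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))
#' @rdname accessors
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))
#' @rdname accessors
#' @export
setGeneric("blockOrder", function(x) standardGeneric("blockOrder"))

#' @rdname accessors
setMethod("featureIDs", "OmicsMatrix", function(x) rownames(x@values))
#' @rdname accessors
setMethod("sampleIDs", "OmicsMatrix", function(x) colnames(x@values))
#' @rdname accessors
setMethod("omicsKind", "OmicsMatrix", function(x) x@omicsKind)
#' @rdname accessors
setMethod("sampleIDs", "DrugResponse", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("responseLabels", "DrugResponse", function(x) x@labels)
#' @rdname accessors
setMethod("drugID", "DrugResponse", function(x) x@drugID)
#' @rdname accessors
setMethod("sampleIDs", "AlignedDataset", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("responseLabels", "AlignedDataset", function(x) x@labels)
#' @rdname accessors
setMethod("drugID", "AlignedDataset", function(x) x@drugID)
#' @rdname accessors
setMethod("selectedFeatures", "SpcaFiResult", function(x) x@selectedFeatureIDs)
#' @rdname accessors
setMethod("importanceScores", "SpcaFiResult", function(x) x@importance)
#' @rdname accessors
setMethod("importanceScores", "ImportanceScores", function(x) x@scores)
#' @rdname accessors
setMethod("sampleIDs", "SimilarityMatrix", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("omicsKind", "SimilarityMatrix", function(x) x@omicsKind)
#' @rdname accessors
setMethod("sampleIDs", "FusedMatrix", function(x) x@sampleIDs)
#' @rdname accessors
setMethod("blockOrder", "FusedMatrix", function(x) x@blockOrder)

#' Matrix views of the S4 containers
#'
#' `as.matrix` on an [OmicsMatrix-class], [SimilarityMatrix-class] or
#' [FusedMatrix-class] returns the underlying numeric matrix.
#'
#' @param x the object.
#' @param ... ignored.
#' @return A numeric matrix.
#' @name as.matrix-methods
NULL

#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "OmicsMatrix", function(x, ...) x@values)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "SimilarityMatrix", function(x, ...) x@values)
#' @rdname as.matrix-methods
#' @export
setMethod("as.matrix", "FusedMatrix", function(x, ...) x@values)

#' @rdname as.matrix-methods
#' @export
setMethod("dim", "OmicsMatrix", function(x) dim(x@values))
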