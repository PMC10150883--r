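# Reading, writing and aligning omics matrices and drug-response tables.

#' Read a delimited omics matrix
#'
#' Expects a header row of sample IDs and a first column of feature IDs, with
#' a numeric body. Features containing any missing value are dropped (and
#' counted in the returned object and in a message); duplicate IDs,
#' non-integer copy-number values and out-of-range methylation values are
#' hard errors. Files ending in `.gz` are decompressed transparently.
#'
#' @param path path to a TSV/CSV file (optionally gzip-compressed).
#' @param omicsKind `"rnaseq"`, `"cna"` or `"methylation"`.
#' @param delimiter field separator, default tab.
#' @return An [OmicsMatrix-class].
#' @seealso [writeOmicsMatrix()]
#' @export
readOmicsMatrix <- function(path, omicsKind, delimiter = "\t") {
  stopifnot(file.exists(path))
  omicsKind <- match.arg(omicsKind, .OMICS_KINDS)
  con <- .openRead(path)
  on.exit(close(con))
  df <- utils::read.table(con, sep = delimiter, header = TRUE,
    check.names = FALSE, stringsAsFactors = FALSE, quote = "",
    comment.char = "", colClasses = NA)
  if (ncol(df) < 2L) stop("omics file must have a feature-ID column plus sample columns")
  fids <- as.character(df[[1L]])
  sids <- colnames(df)[-1L]
  if (anyDuplicated(fids))
    stop("duplicate feature IDs in ", path, ": ",
      paste(unique(fids[duplicated(fids)]), collapse = ", "))
  if (anyDuplicated(sids))
    stop("duplicate sample IDs in ", path, ": ",
      paste(unique(sids[duplicated(sids)]), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric values in omics matrix ", path)
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(fids, sids)
  complete <- !apply(is.na(vals), 1L, any)
  nDropped <- sum(!complete)
  if (nDropped > 0L) {
    message(nDropped, " feature(s) with missing values dropped from ", path)
    vals <- vals[complete, , drop = FALSE]
  }
  OmicsMatrix(vals, omicsKind, droppedFeatures = nDropped)
}

#' Write an omics matrix to a delimited file
#'
#' Numbers are written with full double precision so that
#' `readOmicsMatrix(writeOmicsMatrix(x))` reproduces the values bit-exactly.
#'
#' @param x an [OmicsMatrix-class].
#' @param path output path; a `.gz` suffix enables gzip compression.
#' @param delimiter field separator, default tab.
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(x, path, delimiter = "\t") {
  stopifnot(is(x, "OmicsMatrix"))
  con <- .openWrite(path)
  on.exit(close(con))
  v <- x@values
  writeLines(paste(c("feature_id", colnames(v)), collapse = delimiter), con)
  body <- matrix(.fmtNum(v), nrow = nrow(v))
  lines <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], body[i, ]), collapse = delimiter), character(1))
  writeLines(lines, con)
  invisible(path)
}

#' Read a drug-response table
#'
#' Expects columns `sample_id`, `drug_id` and `ic50` and/or `label`.
#'
#' @param path path to a delimited file (optionally gzip-compressed).
#' @param delimiter field separator, default tab.
#' @return A [DrugResponse-class].
#' @export
readDrugResponse <- function(path, delimiter = "\t") {
  stopifnot(file.exists(path))
  con <- .openRead(path)
  on.exit(close(con))
  df <- utils::read.table(con, sep = delimiter, header = TRUE,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(df)) stop("response table needs a 'sample_id' column")
  if (!any(c("ic50", "label") %in% colnames(df)))
    stop("response table needs an 'ic50' or 'label' column")
  drug <- if ("drug_id" %in% colnames(df)) as.character(df$drug_id[1L]) else "drug"
  DrugResponse(
    sampleIDs = as.character(df$sample_id),
    ic50 = if ("ic50" %in% colnames(df)) as.numeric(df$ic50) else NULL,
    labels = if ("label" %in% colnames(df)) as.integer(df$label) else NULL,
    drugID = drug)
}

#' Binarize IC50 values into sensitive / non-sensitive labels
#'
#' Samples with IC50 strictly below the threshold are labelled sensitive (1),
#' all others non-sensitive (0); values exactly equal to the threshold fall in
#' class 0. With `threshold = "median"` the per-drug median of the IC50
#' values is used, which yields approximately balanced classes.
#'
#' @param table a [DrugResponse-class] with finite IC50 values.
#' @param threshold a numeric cutoff, or `"median"` (default).
#' @return The table with `labels` filled in and the threshold recorded.
#' @examples
#' tab <- DrugResponse(paste0("s", 1:4), ic50 = c(1, 2, 3, 4))
#' responseLabels(binarizeIC50(tab, 2.5))  # 1 1 0 0
#' @export
binarizeIC50 <- function(table, threshold = "median") {
  stopifnot(is(table, "DrugResponse"))
  ic50 <- table@ic50
  if (anyNA(ic50) || any(!is.finite(ic50)))
    stop("binarizeIC50 requires finite IC50 values for every sample")
  thr <- if (identical(threshold, "median")) stats::median(ic50) else {
    stopifnot(is.numeric(threshold), length(threshold) == 1L)
    threshold
  }
  labels <- as.integer(ic50 < thr)
  if (length(unique(labels)) < 2L)
    stop("binarization at threshold ", format(thr),
      " puts all samples of drug '", table@drugID, "' in one class")
  new("DrugResponse", sampleIDs = table@sampleIDs, ic50 = ic50,
      labels = labels, drugID = table@drugID, threshold = thr)
}

#' Align omics blocks and a response table on shared samples
#'
#' Restricts every block and the label vector to the intersection of the
#' sample IDs, in lexicographic order (so all downstream matrices are
#' order-deterministic), and reports how many samples were dropped.
#'
#' @param blocks list of [OmicsMatrix-class] objects.
#' @param table a [DrugResponse-class] with labels present (binarize first).
#' @return An [AlignedDataset-class].
#' @export
alignSamples <- function(blocks, table) {
  stopifnot(length(blocks) >= 1L, is(table, "DrugResponse"))
  if (all(is.na(table@labels)))
    stop("response table has no labels; call binarizeIC50() first")
  idSets <- c(lapply(blocks, function(b) colnames(b@values)), list(table@sampleIDs))
  common <- sort(Reduce(intersect, idSets))
  if (length(common) == 0L)
    stop("no sample IDs are shared by all omics blocks and the response table")
  nDropped <- length(unique(unlist(idSets))) - length(common)
  if (nDropped > 0L)
    message(nDropped, " sample(s) dropped during alignment (not present everywhere)")
  alignedBlocks <- lapply(blocks, function(b) {
    new("OmicsMatrix", values = b@values[, common, drop = FALSE],
        omicsKind = b@omicsKind, droppedFeatures = b@droppedFeatures)
  })
  names(alignedBlocks) <- vapply(alignedBlocks, function(b) b@omicsKind, character(1))
  labels <- table@labels[match(common, table@sampleIDs)]
  if (anyNA(labels)) stop("missing labels for aligned samples")
  if (length(unique(labels)) < 2L)
    stop("only one class remains after alignment")
  new("AlignedDataset", blocks = alignedBlocks, labels = labels,
      drugID = table@drugID, sampleIDs = common)
}

#' Write a drug-response table
#'
#' @param table a [DrugResponse-class].
#' @param path output path; `.gz` enables compression.
#' @param delimiter field separator.
#' @return `path`, invisibly.
#' @export
writeDrugResponse <- function(table, path, delimiter = "\t") {
  stopifnot(is(table, "DrugResponse"))
  con <- .openWrite(path)
  on.exit(close(con))
  cols <- c("sample_id", "drug_id")
  haveIC <- !all(is.na(table@ic50))
  haveLab <- !all(is.na(table@labels))
  if (haveIC) cols <- c(cols, "ic50")
  if (haveLab) cols <- c(cols, "label")
  writeLines(paste(cols, collapse = delimiter), con)
  for (i in seq_along(table@sampleIDs)) {
    row <- c(table@sampleIDs[i], table@drugID)
    if (haveIC) row <- c(row, .fmtNum(table@ic50[i]))
    if (haveLab) row <- c(row, as.character(table@labels[i]))
    writeLines(paste(row, collapse = delimiter), con)
  }
  invisible(path)
}
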