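# Per-omics sample similarity networks and their horizontal fusion.

.asFeatureMatrix <- function(F) {
  if (is(F, "OmicsMatrix")) F@values else as.matrix(F)
}

#' Pearson sample-similarity network
#'
#' Entry (x, y) is the Pearson correlation of the two samples' feature
#' vectors, computed over the `a` (selected) features:
#' \deqn{r_{xy} = \frac{\sum_i (x_i - \bar x)(y_i - \bar y)}
#'   {\sqrt{\sum_i (x_i - \bar x)^2 \sum_i (y_i - \bar y)^2}}.}
#' Suitable for the continuous blocks (RNA-seq expression, methylation).
#'
#' @param F numeric matrix of selected features x samples (or
#'   [OmicsMatrix-class]); at least two features are required, and no sample
#'   may have zero variance across them.
#' @param omicsKind omics kind recorded on the result.
#' @return A [SimilarityMatrix-class] (symmetric, unit diagonal).
#' @examples
#' F <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
#' as.matrix(pearsonSimilarity(F))[1, 2]  # 9 / (2 * sqrt(21))
#' @export
pearsonSimilarity <- function(F, omicsKind = "rnaseq") {
  F <- .asFeatureMatrix(F)
  if (nrow(F) < 2L) stop("need at least 2 features to correlate samples")
  sds <- apply(F, 2L, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(F)[sds == 0]
    if (is.null(bad)) bad <- which(sds == 0)
    stop("zero-variance sample(s): ", paste(bad, collapse = ", "))
  }
  vals <- stats::cor(F)
  diag(vals) <- 1
  sids <- colnames(F)
  if (is.null(sids)) sids <- paste0("sample_", seq_len(ncol(F)))
  dimnames(vals) <- list(sids, sids)
  new("SimilarityMatrix", values = vals, sampleIDs = sids,
      omicsKind = omicsKind, method = "pearson")
}

# Sign vectors over all feature pairs i < j, one column per sample. The
# crossproduct of two columns is C - E (concordant minus discordant pairs);
# tied pairs contribute 0 to both.
.kendallSignMatrix <- function(F) {
  cFeat <- nrow(F)
  i1 <- rep(seq_len(cFeat - 1L), times = (cFeat - 1L):1L)
  i2 <- sequence((cFeat - 1L):1L, from = 2L:cFeat)
  sign(F[i1, , drop = FALSE] - F[i2, , drop = FALSE])
}

#' Kendall (tau-a) sample-similarity network
#'
#' Entry (x, y) is \eqn{\tau = (C - E) / \binom{c}{2}} where C and E count
#' concordant and discordant feature pairs between the two samples and `c` is
#' the number of features; tied pairs count in neither C nor E (no tie
#' correction). Intended for the integer copy-number block. The diagonal is
#' set to 1. `method = "tau_b"` switches to the tie-corrected coefficient
#' via [stats::cor()].
#'
#' @param F numeric matrix of selected features x samples (or
#'   [OmicsMatrix-class]), at least two features.
#' @param omicsKind omics kind recorded on the result.
#' @param method `"tau_a"` (default) or `"tau_b"`.
#' @return A [SimilarityMatrix-class].
#' @examples
#' F <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
#' as.matrix(kendallSimilarity(F))[1, 2]  # (2 - 1) / 3
#' @export
kendallSimilarity <- function(F, omicsKind = "cna",
                              method = c("tau_a", "tau_b")) {
  method <- match.arg(method)
  F <- .asFeatureMatrix(F)
  if (nrow(F) < 2L) stop("need at least 2 features for rank correlation")
  sids <- colnames(F)
  if (is.null(sids)) sids <- paste0("sample_", seq_len(ncol(F)))
  if (method == "tau_b") {
    vals <- stats::cor(F, method = "kendall")
    vals[is.na(vals)] <- 0  # constant samples have undefined tau-b
  } else {
    nPairs <- choose(nrow(F), 2)
    S <- .kendallSignMatrix(F)
    vals <- crossprod(S) / nPairs
  }
  diag(vals) <- 1
  dimnames(vals) <- list(sids, sids)
  new("SimilarityMatrix", values = vals, sampleIDs = sids,
      omicsKind = omicsKind, method = ifelse(method == "tau_a", "kendall", "kendall_b"))
}

# Rectangular similarity of all samples against a reference (training) subset;
# used by the inductive pipeline mode so test samples never enter each
# other's similarity columns.
.crossSimilarity <- function(F, refIdx, method = c("pearson", "kendall")) {
  method <- match.arg(method)
  F <- .asFeatureMatrix(F)
  if (method == "pearson") {
    stats::cor(F, F[, refIdx, drop = FALSE])
  } else {
    S <- .kendallSignMatrix(F)
    crossprod(S, S[, refIdx, drop = FALSE]) / choose(nrow(F), 2)
  }
}

#' Fuse similarity networks by horizontal concatenation
#'
#' Stitches the per-omics n x n similarity matrices side by side into one
#' n x (B*n) matrix in the given order. No rescaling, averaging or diffusion
#' is applied, so extraction of any block is lossless.
#'
#' @param blocks list of [SimilarityMatrix-class] objects sharing one sample
#'   order.
#' @return A [FusedMatrix-class].
#' @export
fuseNetworks <- function(blocks) {
  stopifnot(length(blocks) >= 1L,
    all(vapply(blocks, is, logical(1), "SimilarityMatrix")))
  sids <- blocks[[1L]]@sampleIDs
  for (b in blocks) {
    if (!identical(b@sampleIDs, sids))
      stop("similarity blocks disagree on sample order; align first")
  }
  kinds <- vapply(blocks, function(b) b@omicsKind, character(1))
  vals <- do.call(cbind, lapply(blocks, function(b) b@values))
  colnames(vals) <- unlist(lapply(seq_along(blocks),
    function(i) paste(kinds[i], sids, sep = ":")))
  rownames(vals) <- sids
  new("FusedMatrix", values = vals, blockOrder = kinds, sampleIDs = sids)
}

#' Extract one similarity block from a fused matrix
#'
#' @param fused a [FusedMatrix-class].
#' @param block block index or omics kind.
#' @return The n x n numeric similarity matrix of that block, bit-identical
#'   to the block that was fused.
#' @export
extractBlock <- function(fused, block) {
  stopifnot(is(fused, "FusedMatrix"))
  b <- if (is.character(block)) match(block, fused@blockOrder) else as.integer(block)
  if (is.na(b) || b < 1L || b > length(fused@blockOrder))
    stop("unknown block: ", block)
  n <- length(fused@sampleIDs)
  out <- fused@values[, ((b - 1L) * n + 1L):(b * n), drop = FALSE]
  colnames(out) <- fused@sampleIDs
  out
}

#' Write a similarity or fused matrix as TSV
#'
#' Sample IDs form the header; a sidecar `<path>.meta.json` records the
#' block order and method metadata.
#'
#' @param x a [SimilarityMatrix-class] or [FusedMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSimilarity <- function(x, path) {
  v <- as.matrix(x)
  con <- .openWrite(path)
  writeLines(paste(c("sample_id", colnames(v)), collapse = "\t"), con)
  body <- matrix(.fmtNum(v), nrow = nrow(v))
  writeLines(vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], body[i, ]), collapse = "\t"), character(1)), con)
  close(con)
  meta <- if (is(x, "FusedMatrix")) {
    list(type = "fused", block_order = x@blockOrder, n = length(x@sampleIDs))
  } else {
    list(type = "similarity", omics_kind = x@omicsKind, method = x@method,
         n = length(x@sampleIDs))
  }
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}
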