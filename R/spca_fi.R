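# The SPCA <-> random-forest importance feedback loop.

#' Sparse PCA feature selection with random-forest feedback
#'
#' Alternates (i) rank-1 L0-sparse PCA on a row-reweighted, standardized copy
#' of the omics block, (ii) random-forest Gini importance of the selected
#' features against the drug-sensitivity labels, and (iii) an update of the
#' row weights, until the selected support is identical on consecutive outer
#' iterations or `maxOuter` is reached.
#'
#' The weight update is supervised and gated by the support's predictive
#' shortfall. With `t` the normalized importance over the current support of
#' size `s'` and `g = max(0, 2 * (OOB accuracy - 0.5))` the forest's gain
#' over chance, each selected feature's weight is multiplied by
#' \deqn{((1-\lambda) + \lambda g) \cdot (s' t_j)^{1-g},}
#' clipped to `[weightFloor, weightCap]`; unselected weights are unchanged.
#' A support that classifies perfectly (`g = 1`) provides no evidence
#' against any of its members and is left untouched; a support no better
#' than chance (`g = 0`) is damped wholesale regardless of its internal
#' importance ranking (which is then meaningless), letting high-variance but
#' drug-irrelevant directions be displaced by class-associated features; in
#' between, features are damped or kept according to their relative
#' importance `s' t_j`. The floor keeps eliminated features re-admissible.
#'
#' The loop stops when either the whole support or its *stable core* — the
#' selected features carrying at least half the uniform share `1/(2s')` of
#' importance — is identical on consecutive outer iterations. The
#' low-importance tail of the support is exchangeable noise whose
#' composition can churn without affecting the selected core.
#'
#' @param X an [OmicsMatrix-class] or numeric matrix, features x samples.
#' @param labels 0/1 vector aligned to the samples of `X`.
#' @param s sparsity budget (number of features to retain).
#' @param maxOuter cap on outer SPCA/RF iterations.
#' @param tol,maxIter inner convergence controls passed to [spcaRank1()].
#' @param nTrees forest size per outer iteration.
#' @param seed seed; each outer iteration derives its forest seed from it.
#' @param damping update strength `lambda` in `[0, 1]`.
#' @param center,scale feature standardization before SPCA (defaults on).
#' @param importanceMethod passed to [rfFeatureImportance()].
#' @param weightFloor,weightCap clipping range for the cumulative weights.
#' @return An [SpcaFiResult-class].
#' @seealso [sparseProject()], [spcaRank1()], [rfFeatureImportance()]
#' @export
spcaFiLoop <- function(X, labels, s = 50L, maxOuter = 20L, tol = 1e-6,
                       maxIter = 500L, nTrees = 200L, seed = 1L,
                       damping = 0.5, center = TRUE, scale = TRUE,
                       importanceMethod = c("node_gini", "impurity"),
                       weightFloor = 1e-3, weightCap = 3) {
  importanceMethod <- match.arg(importanceMethod)
  fids <- if (is(X, "OmicsMatrix")) rownames(X@values) else rownames(X)
  if (is(X, "OmicsMatrix")) X <- X@values
  stopifnot(is.matrix(X))
  if (is.null(fids)) fids <- paste0("feature_", seq_len(nrow(X)))
  labels <- as.integer(labels)
  if (length(labels) != ncol(X)) stop("labels must be aligned to the samples of X")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  m <- nrow(X)
  if (s < 1L || s > m) stop("s must satisfy 1 <= s <= number of features")
  stopifnot(damping >= 0, damping <= 1)

  X0 <- .standardizeRows(X, center = center, scale = scale)
  w <- rep(1, m)
  suppPrev <- NULL; corePrev <- NULL
  converged <- FALSE
  comp <- NULL; imp <- NULL; nOuter <- 0L
  for (it in seq_len(maxOuter)) {
    nOuter <- it
    comp <- spcaRank1(w * X0, s, vInit = "svd", tol = tol, maxIter = maxIter)
    supp <- comp@support
    imp <- rfFeatureImportance(X0[supp, , drop = FALSE], labels,
      nTrees = nTrees, seed = seed + it, method = importanceMethod)
    core <- supp[imp@scores >= 1 / (2 * length(supp))]
    if (!is.null(suppPrev) &&
        (identical(supp, suppPrev) || identical(core, corePrev))) {
      converged <- TRUE
      break
    }
    g <- max(0, 2 * (imp@oobAccuracy - 0.5))
    upd <- ((1 - damping) + damping * g) *
      (length(supp) * imp@scores)^(1 - g)
    w[supp] <- pmin(pmax(w[supp] * upd, weightFloor), weightCap)
    suppPrev <- supp
    corePrev <- core
  }
  new("SpcaFiResult", component = comp, importance = imp,
      selectedFeatureIDs = fids[comp@support],
      nOuterIterations = nOuter, converged = converged,
      weights = w, featureIDs = fids)
}

#' Export selected features for downstream enrichment tools
#'
#' Writes one plain-text file per omics block with one selected feature ID per
#' line, plus a TSV of `(feature_id, loading, importance)` — the input format
#' expected by external pathway-enrichment platforms.
#'
#' @param result an [SpcaFiResult-class].
#' @param omicsKind omics kind used in the file names.
#' @param dir output directory (created if needed).
#' @return Character vector of the two file paths, invisibly.
#' @export
exportSelectedFeatures <- function(result, omicsKind, dir) {
  stopifnot(is(result, "SpcaFiResult"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idPath <- file.path(dir, paste0(omicsKind, "_selected.txt"))
  tsvPath <- file.path(dir, paste0(omicsKind, "_selected.tsv"))
  writeLines(result@selectedFeatureIDs, idPath)
  supp <- result@component@support
  df <- data.frame(
    feature_id = result@selectedFeatureIDs,
    loading = .fmtNum(result@component@u[supp]),
    importance = .fmtNum(as.numeric(result@importance@scores)),
    stringsAsFactors = FALSE)
  utils::write.table(df, tsvPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(idPath, tsvPath))
}
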