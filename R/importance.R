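# Random-forest Gini feature importance.

# Binary Gini impurity from class proportions.
.giniImpurity <- function(p) 1 - sum(p^2)

# Node-Gini importance for one ranger forest: for every non-terminal node the
# Gini index of the node's (in-bag, bootstrap-weighted) class proportions is
# credited to the feature the node splits on; credits are summed per tree and
# over the forest. This is the "sum of node Gini values" convention, not the
# conventional impurity decrease.
.nodeGiniScores <- function(rf, xdf, y01, nFeatures) {
  n <- nrow(xdf)
  scores <- numeric(nFeatures)
  for (d in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, d)
    inb <- rf$inbag.counts[[d]]
    members <- vector("list", nrow(ti))
    members[[1L]] <- which(inb > 0)
    for (r in seq_len(nrow(ti))) {
      idx <- members[[r]]
      if (isTRUE(ti$terminal[r]) || is.null(idx) || length(idx) == 0L) next
      w <- inb[idx]
      tot <- sum(w)
      if (tot > 0) {
        p1 <- sum(w[y01[idx] == 1L]) / tot
        svar <- ti$splitvarID[r] + 1L  # ranger IDs are 0-based
        scores[svar] <- scores[svar] + .giniImpurity(c(p1, 1 - p1))
      }
      left <- xdf[idx, ti$splitvarID[r] + 1L] <= ti$splitval[r]
      members[[ti$leftChild[r] + 1L]] <- idx[left]
      members[[ti$rightChild[r] + 1L]] <- idx[!left]
    }
  }
  scores
}

#' Random-forest Gini feature importance
#'
#' Trains a random forest of CART-style trees on the given features and binary
#' labels and scores each feature. The default `"node_gini"` method credits,
#' for each tree, the Gini index \eqn{1 - \sum_k p_k^2} of every node that
#' splits on the feature (class proportions taken over the node's bootstrap
#' sample), sums the credits over the forest and normalizes the result to sum
#' to 1. `"impurity"` switches to the conventional mean decrease in impurity.
#' Deterministic given `seed` (forests are fit single-threaded).
#'
#' @param X numeric matrix, features x samples (typically the rows of an omics
#'   block restricted to a candidate support).
#' @param labels 0/1 vector per sample; both classes must be present.
#' @param nTrees number of trees.
#' @param seed RNG seed for the forest.
#' @param method `"node_gini"` (default) or `"impurity"`.
#' @return An [ImportanceScores-class]; `oobAccuracy` carries the forest's
#'   out-of-bag accuracy.
#' @export
rfFeatureImportance <- function(X, labels, nTrees = 200L, seed = 1L,
                                method = c("node_gini", "impurity")) {
  method <- match.arg(method)
  if (is(X, "OmicsMatrix")) X <- X@values
  stopifnot(is.matrix(X), nrow(X) >= 1L, nTrees >= 1L)
  labels <- as.integer(labels)
  if (length(labels) != ncol(X)) stop("labels must match the number of samples")
  if (length(unique(labels)) < 2L) stop("labels contain a single class")
  xdf <- as.data.frame(t(X))
  colnames(xdf) <- paste0("f", seq_len(nrow(X)))  # safe names for ranger
  y <- factor(labels, levels = c(0L, 1L))
  rf <- ranger::ranger(x = xdf, y = y, num.trees = nTrees, seed = seed,
    num.threads = 1L, keep.inbag = TRUE,
    importance = if (method == "impurity") "impurity" else "none")
  raw <- if (method == "node_gini") {
    .nodeGiniScores(rf, xdf, labels, nrow(X))
  } else {
    pmax(as.numeric(rf$variable.importance), 0)
  }
  tot <- sum(raw)
  if (tot <= 0) {
    warning("all importance scores are zero; returning a uniform vector")
    scores <- rep(1 / length(raw), length(raw))
  } else {
    scores <- raw / tot
  }
  names(scores) <- rownames(X)
  oob <- 1 - rf$prediction.error
  if (!is.finite(oob)) oob <- 0.5
  new("ImportanceScores", scores = scores, normalized = TRUE,
      oobAccuracy = oob, method = method)
}
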