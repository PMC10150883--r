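# Evaluation panel: sensitivity, specificity, per-class precision, overall
# (macro) precision, accuracy, per-class and macro F1. Class 1 = sensitive.

#' Confusion counts for binary predictions
#'
#' @param labelsTrue,labelsPred 0/1 vectors of equal length; class 1 is the
#'   positive (sensitive) class.
#' @return A list of class `ConfusionCounts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusionCounts <- function(labelsTrue, labelsPred) {
  labelsTrue <- as.integer(labelsTrue)
  labelsPred <- as.integer(labelsPred)
  if (length(labelsTrue) != length(labelsPred))
    stop("label vectors differ in length")
  if (length(labelsTrue) < 1L) stop("need at least one sample")
  if (!all(c(labelsTrue, labelsPred) %in% c(0L, 1L)))
    stop("labels must be 0 or 1")
  structure(list(
    tp = sum(labelsTrue == 1L & labelsPred == 1L),
    fp = sum(labelsTrue == 0L & labelsPred == 1L),
    tn = sum(labelsTrue == 0L & labelsPred == 0L),
    fn = sum(labelsTrue == 1L & labelsPred == 0L)),
    class = "ConfusionCounts")
}

.safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning("0/0 in ", what, "; reporting 0")
    return(0)
  }
  num / den
}

#' Compute the evaluation panel from confusion counts
#'
#' Sensitivity (recall of class 1), specificity (recall of class 0),
#' per-class precision `p0`/`p1`, overall precision (the unweighted macro
#' average of `p0` and `p1`), accuracy, per-class F1 and their macro average.
#' Degenerate 0/0 ratios are reported as 0 with a warning.
#'
#' @param counts a `ConfusionCounts` object (or list with tp/fp/tn/fn).
#' @param drugID optional drug identifier carried into the report.
#' @return A list of class `MetricsReport`.
#' @examples
#' m <- computeMetrics(confusionCounts(c(1,1,0,0), c(1,0,0,0)))
#' m$sensitivity  # 0.5
#' @export
computeMetrics <- function(counts, drugID = NA_character_) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  k <- tp + fp + tn + fn
  if (k == 0) stop("empty confusion counts")
  sens <- .safeRatio(tp, tp + fn, "sensitivity")
  spec <- .safeRatio(tn, tn + fp, "specificity")
  p1 <- .safeRatio(tp, tp + fp, "p1")
  p0 <- .safeRatio(tn, tn + fn, "p0")
  acc <- (tp + tn) / k
  f1 <- function(prec, rec, what) {
    if (prec + rec == 0) {
      warning("0/0 in ", what, "; reporting 0")
      return(0)
    }
    2 * prec * rec / (prec + rec)
  }
  f1_1 <- f1(p1, sens, "f1_1")
  f1_0 <- f1(p0, spec, "f1_0")
  structure(list(
    drugID = drugID,
    sensitivity = sens, specificity = spec,
    p0 = p0, p1 = p1,
    precision = (p0 + p1) / 2,
    accuracy = acc,
    f1_0 = f1_0, f1_1 = f1_1,
    f1_macro = (f1_0 + f1_1) / 2,
    counts = counts),
    class = "MetricsReport")
}

.metricCols <- c("sensitivity", "specificity", "p0", "p1", "precision",
                 "accuracy", "f1_0", "f1_1", "f1_macro")

#' @export
print.MetricsReport <- function(x, ...) {
  cat("MetricsReport", if (!is.na(x$drugID)) paste0("[", x$drugID, "]"), "\n")
  vals <- vapply(.metricCols, function(nm) x[[nm]], numeric(1))
  print(round(vals, 4))
  invisible(x)
}

#' Write a metrics report as TSV and JSON
#'
#' One row per drug, columns in the order sensitivity, specificity, p-0,
#' p-1, precision, accuracy, F1-0, F1-1, F1-macro; a `.json` twin carries
#' the same numbers plus the precision-interpretation note.
#'
#' @param report a `MetricsReport` or list of them.
#' @param path output TSV path (JSON written next to it).
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(report, path) {
  if (inherits(report, "MetricsReport")) report <- list(report)
  rows <- lapply(report, function(r) {
    data.frame(drug_id = r$drugID,
      as.list(vapply(.metricCols, function(nm) r[[nm]], numeric(1))),
      check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  js <- lapply(report, function(r) {
    out <- as.list(vapply(.metricCols, function(nm) r[[nm]], numeric(1)))
    out$drug_id <- r$drugID
    out$counts <- r$counts[c("tp", "fp", "tn", "fn")]
    out
  })
  jsPath <- if (grepl("\\.tsv$", path)) sub("\\.tsv$", ".json", path)
            else paste0(path, ".json")
  jsonlite::write_json(
    list(reports = js,
         notes = "precision = unweighted macro average of p0 and p1"),
    jsPath, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
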