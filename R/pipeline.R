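# End-to-end orchestration: align -> binarize -> per-omics feature selection
# -> per-omics similarity -> fusion -> split -> CNN -> metrics.

#' Pipeline configuration
#'
#' @param s per-omics sparsity budgets (features retained per block).
#' @param mode `"transductive"` (one similarity network over all samples,
#'   then split — faithful to a single n x 3n matrix) or `"inductive"`
#'   (feature selection and similarity columns use training samples only;
#'   leakage-safe).
#' @param testFraction held-out fraction for the stratified split.
#' @param blockOrder concatenation order of the omics blocks.
#' @param similarityMethods per-omics similarity: `"pearson"` for the
#'   continuous blocks, `"kendall"` (tau-a) for copy number.
#' @param loop list of [spcaFiLoop()] controls
#'   (`maxOuter`, `tol`, `maxIter`, `nTrees`, `damping`, `importanceMethod`).
#' @param cnn a [cnnConfig()]; its seed is overridden by the pipeline seed.
#' @param seed master seed propagated to every stochastic stage.
#' @param outdir if non-NULL, artifacts (metrics, feature exports,
#'   predictions, model checkpoint, manifest) are written there.
#' @return A list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(s = c(rnaseq = 50L, cna = 50L, methylation = 50L),
                           mode = c("transductive", "inductive"),
                           testFraction = 0.2,
                           blockOrder = c("rnaseq", "cna", "methylation"),
                           similarityMethods = c(rnaseq = "pearson",
                             cna = "kendall", methylation = "pearson"),
                           loop = list(), cnn = cnnConfig(), seed = 1L,
                           outdir = NULL) {
  mode <- match.arg(mode)
  loopDefaults <- list(maxOuter = 20L, tol = 1e-6, maxIter = 500L,
    nTrees = 200L, damping = 0.5, importanceMethod = "node_gini")
  loop <- utils::modifyList(loopDefaults, loop)
  stopifnot(inherits(cnn, "CnnConfig"), testFraction > 0, testFraction < 1)
  structure(list(s = s, mode = mode, testFraction = testFraction,
    blockOrder = blockOrder, similarityMethods = similarityMethods,
    loop = loop, cnn = cnn, seed = as.integer(seed), outdir = outdir),
    class = "PipelineConfig")
}

.simFor <- function(kind, F, method) {
  if (method == "pearson") pearsonSimilarity(F, omicsKind = kind)
  else kendallSimilarity(F, omicsKind = kind)
}

#' Run the full classification pipeline
#'
#' Executes feature selection ([spcaFiLoop()]) per omics block, builds the
#' per-omics sample similarity networks over the selected features, fuses
#' them horizontally, splits samples stratified by class, trains the CNN on
#' the training rows and evaluates on the held-out rows. In inductive mode,
#' feature selection uses training labels only and similarity columns are
#' computed against training samples only.
#'
#' @param data an [AlignedDataset-class] or [SimDataset-class].
#' @param config a [pipelineConfig()].
#' @return List with `metrics` (a `MetricsReport`), `selection` (per-omics
#'   [SpcaFiResult-class]), `fused`, `model`, `predictions` (data.frame for
#'   the held-out samples), `split`, and `manifest`. If `config$outdir` is
#'   set the artifacts are also written to disk.
#' @export
runPipeline <- function(data, config = pipelineConfig()) {
  if (is(data, "SimDataset")) data <- data@dataset
  stopifnot(is(data, "AlignedDataset"), inherits(config, "PipelineConfig"))
  labels <- data@labels
  n <- length(labels)
  seed <- config$seed

  split <- .stratifiedSplit(labels, config$testFraction, seed = seed + 1000L)
  selLabels <- labels
  selSamples <- seq_len(n)
  if (config$mode == "inductive") {
    selSamples <- split$train
    selLabels <- labels[split$train]
  }

  kinds <- config$blockOrder
  missing <- setdiff(kinds, names(data@blocks))
  if (length(missing))
    stop("blockOrder names blocks absent from the dataset: ",
         paste(missing, collapse = ", "))

  stageShapes <- list()
  selection <- list()
  simBlocks <- list()
  crossCols <- list()  # inductive-mode rectangular similarities
  for (bi in seq_along(kinds)) {
    kind <- kinds[bi]
    blk <- data@blocks[[kind]]
    sBudget <- if (kind %in% names(config$s)) config$s[[kind]] else NULL
    if (is.null(sBudget) || is.na(sBudget))
      stop("no sparsity budget configured for block '", kind, "'")
    if (sBudget > nrow(blk@values)) {
      message("sparsity budget for '", kind, "' (", sBudget,
              ") exceeds its ", nrow(blk@values), " features; clamping")
      sBudget <- nrow(blk@values)
    }
    message("feature selection [", kind, "]: m = ", nrow(blk@values),
            ", s = ", sBudget)
    res <- spcaFiLoop(blk@values[, selSamples, drop = FALSE], selLabels,
      s = sBudget, maxOuter = config$loop$maxOuter, tol = config$loop$tol,
      maxIter = config$loop$maxIter, nTrees = config$loop$nTrees,
      seed = seed + 11L * bi, damping = config$loop$damping,
      importanceMethod = config$loop$importanceMethod)
    selection[[kind]] <- res
    F <- blk@values[res@selectedFeatureIDs, , drop = FALSE]
    method <- config$similarityMethods[[kind]]
    if (config$mode == "transductive") {
      simBlocks[[kind]] <- .simFor(kind, F, method)
      stageShapes[[kind]] <- list(selected = nrow(F), similarity = dim(as.matrix(simBlocks[[kind]])))
    } else {
      crossCols[[kind]] <- .crossSimilarity(F, split$train, method = method)
      stageShapes[[kind]] <- list(selected = nrow(F), similarity = dim(crossCols[[kind]]))
    }
  }

  if (config$mode == "transductive") {
    fused <- fuseNetworks(simBlocks[kinds])
    rows <- fused@values
  } else {
    fused <- NULL
    rows <- do.call(cbind, crossCols[kinds])
    rownames(rows) <- data@sampleIDs
  }
  inputWidth <- ncol(rows)
  message("fused classifier input: ", nrow(rows), " x ", inputWidth)

  cnnCfg <- config$cnn
  cnnCfg$seed <- seed + 2000L
  model <- buildCnnModel(cnnCfg, inputWidth)
  model <- trainCnn(model, rows[split$train, , drop = FALSE], labels[split$train])
  pred <- predictCnn(model, rows[split$test, , drop = FALSE])
  metrics <- computeMetrics(
    confusionCounts(labels[split$test], pred$label), drugID = data@drugID)

  predictions <- data.frame(
    sample_id = data@sampleIDs[split$test],
    p0 = pred$prob[, "p0"], p1 = pred$prob[, "p1"],
    label = pred$label, true_label = labels[split$test],
    stringsAsFactors = FALSE)

  manifest <- list(
    package = "DrugSensFusion",
    version = as.character(utils::packageVersion("DrugSensFusion")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    drug_id = data@drugID,
    seed = seed,
    mode = config$mode,
    n_samples = n,
    n_train = length(split$train), n_test = length(split$test),
    input_width = inputWidth,
    sparsity = as.list(config$s),
    loop = config$loop,
    cnn = unclass(cnnCfg),
    block_order = kinds,
    similarity_methods = as.list(config$similarityMethods),
    stage_shapes = stageShapes,
    selection = lapply(selection, function(r) list(
      n_selected = length(r@selectedFeatureIDs),
      outer_iterations = r@nOuterIterations,
      support_stable = r@converged,
      oob_accuracy = r@importance@oobAccuracy)))

  out <- list(metrics = metrics, selection = selection, fused = fused,
              model = model, predictions = predictions, split = split,
              manifest = manifest)

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    writeMetricsReport(metrics, file.path(config$outdir, "metrics.tsv"))
    for (kind in kinds)
      exportSelectedFeatures(selection[[kind]], kind, config$outdir)
    utils::write.table(
      within(predictions, { p0 <- .fmtNum(p0); p1 <- .fmtNum(p1) }),
      file.path(config$outdir, "predictions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    saveCnnModel(model, file.path(config$outdir, "model.rds"))
    if (!is.null(fused))
      writeSimilarity(fused, file.path(config$outdir, "fused.tsv"))
    jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
      auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Simulate a dataset and write it to disk
#'
#' Convenience wrapper around [simulateMultiOmics()] and [writeSimDataset()].
#'
#' @param config a [simConfig()].
#' @param outdir output directory.
#' @return The [SimDataset-class], invisibly; files are written to `outdir`.
#' @export
runSimulate <- function(config, outdir) {
  sim <- simulateMultiOmics(config)
  writeSimDataset(sim, outdir)
  invisible(sim)
}
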