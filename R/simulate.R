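# Synthetic multi-omics generator with planted class-informative features.
# Emulates the shapes and value domains of the three real blocks (continuous
# expression, integer copy number in {-2..2}, bounded methylation in [0,1])
# at desk scale, with a known ground truth for every stage of the pipeline.

#' Simulation configuration
#'
#' Defaults describe the desk-scale study conditions: 200 samples and blocks
#' of 2000 / 1500 / 3000 features standing in for genome-scale expression,
#' copy-number and methylation panels.
#'
#' @param nSamples number of samples (>= 10).
#' @param blockSizes features per block, in the order rnaseq, cna,
#'   methylation.
#' @param nInformative planted class-informative features per block.
#' @param effectSize standardized between-class mean shift delta for the
#'   continuous blocks; also scales the class-dependence of the CNA
#'   categorical (delta = 0 gives a pure null dataset).
#' @param classBalance fraction of sensitive (label 1) samples, in (0, 1).
#' @param noiseSD residual standard deviation of the continuous blocks.
#' @param seed RNG seed; identical configs give byte-identical datasets.
#' @param drugID drug identifier attached to the labels.
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(nSamples = 200L,
                      blockSizes = c(rnaseq = 2000L, cna = 1500L, methylation = 3000L),
                      nInformative = c(rnaseq = 50L, cna = 50L, methylation = 50L),
                      effectSize = 2, classBalance = 0.5, noiseSD = 1,
                      seed = 1L, drugID = "synthetic_drug") {
  stopifnot(nSamples >= 10L, length(blockSizes) == 3L,
    length(nInformative) == 3L, all(nInformative <= blockSizes),
    all(nInformative >= 0L), effectSize >= 0,
    classBalance > 0, classBalance < 1, noiseSD > 0)
  structure(list(
    nSamples = as.integer(nSamples),
    blockSizes = stats::setNames(as.integer(blockSizes), .OMICS_KINDS),
    nInformative = stats::setNames(as.integer(nInformative), .OMICS_KINDS),
    effectSize = effectSize, classBalance = classBalance,
    noiseSD = noiseSD, seed = as.integer(seed), drugID = drugID),
    class = "SimConfig")
}

# Class-conditional CNA category probabilities over {-2,...,2}: a fraction
# alpha (proportional to effectSize) of the neutral-centred baseline mass is
# shifted towards gains for the sensitive class and losses otherwise.
.cnaProbs <- function(effectSize) {
  base <- c(0.02, 0.08, 0.80, 0.08, 0.02)
  gain <- c(0.00, 0.05, 0.25, 0.45, 0.25)
  loss <- rev(gain)
  alpha <- min(1, effectSize / 4)
  list(class0 = (1 - alpha) * base + alpha * loss,
       class1 = (1 - alpha) * base + alpha * gain,
       base = base)
}

#' Simulate a planted multi-omics dataset
#'
#' Labels are drawn at the configured class balance (to within one sample).
#' The expression block is Gaussian around per-feature baselines; planted
#' features receive a between-class mean shift of `effectSize * noiseSD`
#' (split symmetrically across the two classes). The methylation block is a
#' logistic squash of shifted Gaussians, so values stay strictly inside
#' \[0, 1\]. The CNA block draws integers in \{-2..2\} from a class-dependent
#' categorical for planted features and a class-independent one otherwise.
#' Fully deterministic given the config seed.
#'
#' @param config a [simConfig()] object.
#' @return A [SimDataset-class]: the aligned dataset plus the planted truth
#'   (per-block informative feature IDs).
#' @export
simulateMultiOmics <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  n <- config$nSamples
  delta <- config$effectSize
  sdN <- config$noiseSD
  .withSeed(config$seed, {
    sids <- sprintf("S%04d", seq_len(n))
    labels <- integer(n)
    labels[sample(n, round(n * config$classBalance))] <- 1L
    shift <- ifelse(labels == 1L, delta * sdN / 2, -delta * sdN / 2)

    truth <- list()
    blocks <- list()

    # rnaseq: continuous expression-like values
    m <- config$blockSizes["rnaseq"]
    fids <- sprintf("rna_%05d", seq_len(m))
    inf <- sort(sample(m, config$nInformative["rnaseq"]))
    vals <- matrix(stats::rnorm(m * n, 0, sdN), m, n) + stats::runif(m, 2, 12)
    vals[inf, ] <- vals[inf, ] + rep(shift, each = length(inf))
    dimnames(vals) <- list(fids, sids)
    blocks$rnaseq <- OmicsMatrix(vals, "rnaseq")
    truth$rnaseq <- fids[inf]

    # cna: integer categories in {-2..2}
    m <- config$blockSizes["cna"]
    fids <- sprintf("cna_%05d", seq_len(m))
    inf <- sort(sample(m, config$nInformative["cna"]))
    pr <- .cnaProbs(delta)
    vals <- matrix(sample(-2:2, m * n, replace = TRUE, prob = pr$base), m, n)
    if (length(inf)) {
      n1 <- sum(labels == 1L)
      vals[inf, labels == 1L] <- sample(-2:2, length(inf) * n1,
        replace = TRUE, prob = pr$class1)
      vals[inf, labels == 0L] <- sample(-2:2, length(inf) * (n - n1),
        replace = TRUE, prob = pr$class0)
    }
    storage.mode(vals) <- "double"
    dimnames(vals) <- list(fids, sids)
    blocks$cna <- OmicsMatrix(vals, "cna")
    truth$cna <- fids[inf]

    # methylation: logistic squash of shifted Gaussians -> (0, 1)
    m <- config$blockSizes["methylation"]
    fids <- sprintf("meth_%06d", seq_len(m))
    inf <- sort(sample(m, config$nInformative["methylation"]))
    latent <- matrix(stats::rnorm(m * n, 0, sdN), m, n) + stats::rnorm(m, 0, 1.5)
    latent[inf, ] <- latent[inf, ] + rep(shift, each = length(inf))
    vals <- stats::plogis(latent)
    dimnames(vals) <- list(fids, sids)
    blocks$methylation <- OmicsMatrix(vals, "methylation")
    truth$methylation <- fids[inf]

    ds <- new("AlignedDataset", blocks = blocks, labels = labels,
              drugID = config$drugID, sampleIDs = sids)
    new("SimDataset", dataset = ds, truth = truth,
        trapFeatures = character(0), config = unclass(config))
  })
}

#' Named study fixtures
#'
#' Three canned datasets used throughout the test suite and the worked
#' examples:
#' \describe{
#'   \item{`separable`}{strong planted signal (delta = 3, n = 200, blocks
#'     300/200/400 with 30/20/30 informative features): every pipeline stage
#'     should succeed and held-out accuracy should be high.}
#'   \item{`null`}{delta = 0, same shapes: no feature separates the classes;
#'     held-out accuracy should hover at chance in inductive mode.}
#'   \item{`variance_trap`}{a minimal block of 6 strongly correlated
#'     (pairwise ~0.95) but class-independent expression features forms the
#'     dominant variance direction — the direction rank-1 PCA chases —
#'     alongside 8 modest (delta = 2) informative features. Plain sparse PCA
#'     selects the trap; the importance-feedback loop must displace it.}
#' }
#'
#' @param name `"separable"`, `"null"` or `"variance_trap"`.
#' @param seed RNG seed.
#' @return A [SimDataset-class]; for `variance_trap` the `trapFeatures` slot
#'   names the trap features.
#' @export
simulateFixture <- function(name = c("separable", "null", "variance_trap"),
                            seed = 1L) {
  name <- match.arg(name)
  if (name %in% c("separable", "null")) {
    cfg <- simConfig(nSamples = 200L,
      blockSizes = c(rnaseq = 300L, cna = 200L, methylation = 400L),
      nInformative = c(rnaseq = 30L, cna = 20L, methylation = 30L),
      effectSize = if (name == "separable") 3 else 0,
      classBalance = 0.5, noiseSD = 1, seed = seed,
      drugID = paste0("fixture_", name))
    return(simulateMultiOmics(cfg))
  }
  # variance_trap: built on a small simulated base, then a minimal set of
  # uninformative rnaseq features is replaced by a correlated factor block
  # whose leading eigenvalue (1 + 5 * 0.95 ~ 5.75) dominates the informative
  # block (1 + 7 * 0.5 ~ 4.5) after per-feature standardization.
  cfg <- simConfig(nSamples = 160L,
    blockSizes = c(rnaseq = 60L, cna = 40L, methylation = 40L),
    nInformative = c(rnaseq = 8L, cna = 6L, methylation = 6L),
    effectSize = 2, classBalance = 0.5, noiseSD = 1, seed = seed,
    drugID = "fixture_variance_trap")
  sim <- simulateMultiOmics(cfg)
  .withSeed(seed + 104729L, {
    blk <- sim@dataset@blocks$rnaseq
    vals <- blk@values
    n <- ncol(vals)
    nonInf <- setdiff(rownames(vals), sim@truth$rnaseq)
    nTrap <- 6L
    trapIdx <- sort(sample(nonInf, nTrap))
    loading <- sqrt(0.95)  # pairwise correlation ~0.95 within the trap block
    f <- stats::rnorm(n)  # shared latent factor, independent of the labels
    trapVals <- loading * matrix(f, nTrap, n, byrow = TRUE) +
      sqrt(1 - loading^2) * matrix(stats::rnorm(nTrap * n), nTrap, n)
    vals[trapIdx, ] <- trapVals
    blocks <- sim@dataset@blocks
    blocks$rnaseq <- OmicsMatrix(vals, "rnaseq")
    ds <- new("AlignedDataset", blocks = blocks, labels = sim@dataset@labels,
              drugID = sim@dataset@drugID, sampleIDs = sim@dataset@sampleIDs)
    new("SimDataset", dataset = ds, truth = sim@truth,
        trapFeatures = trapIdx, config = sim@config)
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the same TSV formats [readOmicsMatrix()] and [readDrugResponse()]
#' consume (one file per omics block plus a response table with labels), and
#' a `truth.json` with the planted feature IDs.
#'
#' @param sim a [SimDataset-class].
#' @param outdir output directory (created if needed).
#' @return Character vector of written paths, invisibly.
#' @export
writeSimDataset <- function(sim, outdir) {
  stopifnot(is(sim, "SimDataset"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  paths <- character(0)
  for (b in sim@dataset@blocks) {
    p <- file.path(outdir, paste0(b@omicsKind, ".tsv"))
    writeOmicsMatrix(b, p)
    paths <- c(paths, p)
  }
  resp <- DrugResponse(sim@dataset@sampleIDs, labels = sim@dataset@labels,
    drugID = sim@dataset@drugID)
  p <- file.path(outdir, "response.tsv")
  writeDrugResponse(resp, p)
  paths <- c(paths, p)
  p <- file.path(outdir, "truth.json")
  jsonlite::write_json(
    c(sim@truth, list(trap_features = sim@trapFeatures)),
    p, auto_unbox = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}
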