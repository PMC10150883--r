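# Internal helpers shared across modules.

# Evaluate expr under a given RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv()),
        add = TRUE)
    }
    set.seed(seed)
  }
  expr
}

# Row-wise standardization (features in rows). Constant rows get unit scale
# so they survive as zeros rather than NaN.
.standardizeRows <- function(X, center = TRUE, scale = TRUE) {
  if (center) X <- X - rowMeans(X)
  if (scale) {
    sds <- sqrt(rowSums(X^2) / max(1L, ncol(X) - 1L))
    sds[sds < 1e-12] <- 1
    X <- X / sds
  }
  X
}

# Stratified train/test split on 0/1 labels. Deterministic given seed.
.stratifiedSplit <- function(labels, testFraction = 0.2, seed = 1L) {
  stopifnot(testFraction > 0, testFraction < 1)
  .withSeed(seed, {
    test <- integer(0)
    for (cl in c(0L, 1L)) {
      idx <- which(labels == cl)
      nTest <- max(1L, round(length(idx) * testFraction))
      if (length(idx) - nTest < 2L)
        stop("too few samples in class ", cl, " for a stratified split")
      test <- c(test, sample(idx, nTest))
    }
    test <- sort(test)
    list(train = setdiff(seq_along(labels), test), test = test)
  })
}

# Text connection honouring .gz extensions.
.openRead <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

.openWrite <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
}

# Full-precision number formatting so write -> read round-trips bit-exactly.
.fmtNum <- function(x) {
  out <- sprintf("%.17g", x)
  whole <- x == round(x) & abs(x) < 1e15
  out[whole] <- sprintf("%.0f", x[whole])
  out
}
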