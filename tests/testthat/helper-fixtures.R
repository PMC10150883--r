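# Shared fixture builders; everything is generated in code at test time.

tinyOmics <- function(kind = "rnaseq", m = 4, n = 5, seed = 1) {
  set.seed(seed)
  vals <- switch(kind,
    rnaseq = matrix(rnorm(m * n, 6, 2), m, n),
    cna = matrix(sample(-2:2, m * n, replace = TRUE), m, n),
    methylation = matrix(runif(m * n), m, n))
  storage.mode(vals) <- "double"
  dimnames(vals) <- list(sprintf("%s_f%02d", kind, seq_len(m)),
                         sprintf("S%02d", seq_len(n)))
  OmicsMatrix(vals, kind)
}

# Planted sparse rank-1 matrix: loadings bounded away from zero so every
# support coordinate carries signal; A is the planted singular value.
plantedRank1 <- function(m = 200, n = 60, k = 5, snr = 10, seed = 1) {
  set.seed(seed)
  supp <- sort(sample(m, k))
  u <- numeric(m)
  u[supp] <- sample(c(-1, 1), k, replace = TRUE) * runif(k, 0.5, 1)
  u <- u / sqrt(sum(u^2))
  v <- rnorm(n); v <- v / sqrt(sum(v^2))
  A <- snr * sqrt(m + n)
  list(X = A * u %*% t(v) + matrix(rnorm(m * n), m, n),
       support = as.integer(supp), u = u, v = v)
}

# Brute-force s-sparse projection: enumerate all supports, keep the one
# maximizing retained energy (ties broken towards lower indices).
bruteSparseProject <- function(z, s) {
  p <- length(z)
  best <- NULL; bestE <- -Inf
  for (comb in utils::combn(p, s, simplify = FALSE)) {
    e <- sum(z[comb]^2)
    if (e > bestE + 1e-15) { bestE <- e; best <- comb }
  }
  out <- numeric(p)
  out[best] <- z[best]
  out
}

# O(c^2) pair-enumeration Kendall tau-a between two sample vectors.
bruteTauA <- function(x, y) {
  cFeat <- length(x)
  conc <- disc <- 0
  for (i in seq_len(cFeat - 1)) for (j in (i + 1):cFeat) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  (conc - disc) / choose(cFeat, 2)
}

# Small separable rows for quick CNN tests.
toyCnnData <- function(n = 40, W = 48, shift = 2, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- matrix(rnorm(n * W), n, W)
  X[y == 1, seq_len(W %/% 4)] <- X[y == 1, seq_len(W %/% 4)] + shift
  list(X = X, y = y)
}
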