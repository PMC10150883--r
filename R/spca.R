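# L0-constrained rank-1 sparse PCA by alternating s-sparse projection.

#' s-sparse projection operator
#'
#' Keeps the entries of `z` at the `s` indices of largest absolute value and
#' zeroes the rest. Ties in |z| are broken in favour of the lower index, so
#' the operator is deterministic. This support maximizes the Euclidean norm
#' of the kept entries over all supports of size `s`.
#'
#' @param z numeric vector.
#' @param s number of entries to keep, `1 <= s <= length(z)`.
#' @return A vector of the same length with at most `s` nonzeros.
#' @examples
#' sparseProject(c(0.5, -3, 2, -2.5), 2)  # 0 -3 0 -2.5
#' @export
sparseProject <- function(z, s) {
  p <- length(z)
  if (!is.numeric(z) || p == 0L) stop("z must be a non-empty numeric vector")
  if (s < 1L || s > p) stop("s must satisfy 1 <= s <= length(z); got s = ", s,
    ", length(z) = ", p)
  ord <- order(-abs(z), seq_len(p))
  out <- numeric(p)
  keep <- ord[seq_len(s)]
  out[keep] <- z[keep]
  out
}

#' Rank-1 sparse PCA with an L0 sparsity budget
#'
#' Solves \eqn{\max u^\top X v} subject to \eqn{\|u\|_2 = \|v\|_2 = 1} and
#' \eqn{\|u\|_0 \le s} by alternating the s-sparse projection of `X v` with
#' the exact `v` update `X^T u`:
#' \deqn{\hat u = P(Xv, s),\; u = \hat u / \|\hat u\|,\;
#'       \hat v = X^\top u,\; v = \hat v / \|\hat v\|.}
#' Each half-step maximizes the objective given the other vector, so the
#' objective sequence is non-decreasing. Iteration stops when
#' \eqn{\|u_{new} - u_{old}\|_\infty < tol} or after `maxIter` iterations.
#' The sign is fixed so the largest-magnitude loading is positive.
#'
#' With `s = m` this is plain power iteration and recovers the leading
#' singular pair of `X`.
#'
#' @param X numeric matrix (features x samples) or [OmicsMatrix-class].
#' @param s sparsity budget on the loading `u`.
#' @param vInit `"svd"` (default: leading right singular vector, fully
#'   deterministic), `"random"` (seeded random unit vector), or a numeric
#'   start vector of length `ncol(X)`.
#' @param tol convergence tolerance on the max-norm change of `u`.
#' @param maxIter iteration cap.
#' @param seed RNG seed, used only when `vInit = "random"`.
#' @return A [SparseComponent-class].
#' @examples
#' X <- matrix(0, 3, 4); X[1, 1] <- 5
#' dimnames(X) <- list(paste0("f", 1:3), paste0("s", 1:4))
#' spcaRank1(X, s = 1)
#' @export
spcaRank1 <- function(X, s, vInit = "svd", tol = 1e-6, maxIter = 500L,
                      seed = NULL) {
  if (is(X, "OmicsMatrix")) X <- X@values
  stopifnot(is.matrix(X), is.numeric(X))
  if (anyNA(X) || any(!is.finite(X))) stop("X must be finite")
  m <- nrow(X); n <- ncol(X)
  if (s < 1L || s > m) stop("s must satisfy 1 <= s <= nrow(X)")
  v <- if (is.numeric(vInit)) {
    stopifnot(length(vInit) == n)
    vInit / sqrt(sum(vInit^2))
  } else if (identical(vInit, "svd")) {
    svd(X, nu = 0L, nv = 1L)$v[, 1L]
  } else if (identical(vInit, "random")) {
    .withSeed(seed, { r <- stats::rnorm(n); r / sqrt(sum(r^2)) })
  } else stop("vInit must be 'svd', 'random' or a numeric vector")

  uOld <- rep(NA_real_, m)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    z <- as.vector(X %*% v)
    uh <- sparseProject(z, s)
    nu <- sqrt(sum(uh^2))
    if (nu == 0) stop("degenerate matrix: X v vanished at iteration ", iter)
    u <- uh / nu
    vh <- as.vector(crossprod(X, u))
    nv <- sqrt(sum(vh^2))
    if (nv == 0) stop("degenerate matrix: X^T u vanished at iteration ", iter)
    v <- vh / nv
    trace <- c(trace, nv)  # u^T X v with the freshly updated v
    if (!anyNA(uOld) && max(abs(u - uOld)) < tol) { converged <- TRUE; break }
    uOld <- u
  }
  imax <- which.max(abs(u))
  if (u[imax] < 0) { u <- -u; v <- -v }
  support <- which(u != 0)
  new("SparseComponent", u = u, v = v, support = as.integer(support),
      s = as.integer(s), objective = trace[length(trace)],
      objectiveTrace = trace, iterations = iter, converged = converged)
}

#' Successive sparse components by deflation
#'
#' Extracts `k` rank-1 sparse components, deflating the matrix after each:
#' \eqn{X \leftarrow X - (u^\top X v)\, u v^\top}. One component per omics
#' block is the pipeline default; additional components are occasionally
#' useful for exploring secondary structure.
#'
#' @inheritParams spcaRank1
#' @param k number of components to extract.
#' @return A list of [SparseComponent-class] objects of length `k`.
#' @export
spcaComponents <- function(X, s, k = 2L, vInit = "svd", tol = 1e-6,
                           maxIter = 500L, seed = NULL) {
  if (is(X, "OmicsMatrix")) X <- X@values
  stopifnot(k >= 1L)
  out <- vector("list", k)
  for (i in seq_len(k)) {
    sc <- spcaRank1(X, s, vInit = vInit, tol = tol, maxIter = maxIter,
                    seed = if (is.null(seed)) NULL else seed + i)
    out[[i]] <- sc
    X <- X - sc@objective * sc@u %*% t(sc@v)
  }
  out
}
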