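# A compact, fully seeded 1-D convolutional network for classifying fused
# similarity rows. Three same-padded conv(+relu)+maxpool stages, batch
# normalization after the last stage, two relu dense layers and a softmax
# head, trained with Adam on the cross-entropy loss. All layers are written
# as vectorized matrix algebra so training stays fast on one CPU.

#' CNN configuration
#'
#' @param convChannels output channels of the three conv stages.
#' @param kernelSize convolution kernel width (same padding).
#' @param poolSize max-pool window; widths shrink by floor division.
#' @param fcSizes sizes of the two hidden dense layers.
#' @param nClasses number of classes (fixed at 2).
#' @param learningRate Adam step size.
#' @param epochs training epochs.
#' @param batchSize minibatch size.
#' @param seed seed controlling initialization and shuffling.
#' @return A list of class `CnnConfig`.
#' @export
cnnConfig <- function(convChannels = c(8L, 16L, 32L), kernelSize = 5L,
                      poolSize = 2L, fcSizes = c(64L, 32L), nClasses = 2L,
                      learningRate = 1e-3, epochs = 60L, batchSize = 16L,
                      seed = 1L) {
  stopifnot(length(convChannels) == 3L, all(convChannels >= 1L),
    kernelSize >= 1L, poolSize >= 1L, length(fcSizes) == 2L,
    all(fcSizes >= 1L), nClasses == 2L, learningRate > 0,
    epochs >= 1L, batchSize >= 1L)
  structure(list(
    convChannels = as.integer(convChannels), kernelSize = as.integer(kernelSize),
    poolSize = as.integer(poolSize), fcSizes = as.integer(fcSizes),
    nClasses = 2L, learningRate = learningRate, epochs = as.integer(epochs),
    batchSize = as.integer(batchSize), seed = as.integer(seed)),
    class = "CnnConfig")
}

## ---- layer primitives (internal; compiled kernels in src/) ----

# A: (B, W, Cin); W3: (k, Cin, Cout); same padding
.convForward <- function(A, W3, b) .conv1dForwardC(A, W3, b)

.convBackward <- function(A, W3, dOut) .conv1dBackwardC(A, W3, dOut)

.poolForward <- function(A, p) {
  res <- .poolForwardC(A, as.integer(p))
  list(out = res$out, arg = res$arg, inWidth = dim(A)[2])
}

.poolBackward <- function(cacheP, dOut, p) {
  .poolBackwardC(cacheP$arg, dOut, as.integer(cacheP$inWidth), as.integer(p))
}

.bnForward <- function(A, gamma, beta, running, train, momentum = 0.1, eps = 1e-5) {
  dA <- dim(A); B <- dA[1]; Wd <- dA[2]; C <- dA[3]
  M <- A; dim(M) <- c(B * Wd, C)
  if (train) {
    mu <- colMeans(M)
    vr <- pmax(colMeans(M^2) - mu^2, 0)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * vr
  } else {
    mu <- running$mean
    vr <- running$var
  }
  istd <- 1 / sqrt(vr + eps)
  xhat <- (M - rep(mu, each = B * Wd)) * rep(istd, each = B * Wd)
  out <- xhat * rep(gamma, each = B * Wd) + rep(beta, each = B * Wd)
  dim(out) <- c(B, Wd, C)
  list(out = out, xhat = xhat, istd = istd, running = running, dims = c(B, Wd, C))
}

.bnBackward <- function(cacheB, gamma, dOut) {
  dms <- cacheB$dims; B <- dms[1]; Wd <- dms[2]; C <- dms[3]
  dY <- dOut; dim(dY) <- c(B * Wd, C)
  xhat <- cacheB$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  Nc <- B * Wd
  gi <- rep(gamma * cacheB$istd, each = Nc)
  dX <- gi * (dY -
    rep(colMeans(dY), each = Nc) -
    xhat * rep(colMeans(dY * xhat), each = Nc))
  dim(dX) <- c(B, Wd, C)
  list(dA = dX, dgamma = dgamma, dbeta = dbeta)
}

.softmax <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

## ---- model ----

.pooledWidths <- function(inputWidth, poolSize) {
  w <- as.integer(inputWidth)
  ws <- integer(3)
  for (l in 1:3) { w <- w %/% as.integer(poolSize); ws[l] <- w }
  ws
}

#' Build an untrained CNN
#'
#' Architecture: `[conv1d(same) -> relu -> maxpool] x3 -> batchnorm ->
#' flatten -> dense(relu) -> dense(relu) -> dense(softmax, 2)`. Parameters
#' are He-initialized under the config seed, so two models built from the
#' same config and width are identical.
#'
#' @param config a [cnnConfig()] object.
#' @param inputWidth number of input columns (3n for a fused matrix over n
#'   samples); must survive three pool operations.
#' @return A list of class `CnnModel`.
#' @export
buildCnnModel <- function(config, inputWidth) {
  stopifnot(inherits(config, "CnnConfig"), inputWidth >= 1L)
  ws <- .pooledWidths(inputWidth, config$poolSize)
  if (ws[3] < 1L)
    stop("input width ", inputWidth, " underflows after three pools; ",
         "minimum width is ", config$poolSize^3)
  k <- config$kernelSize
  ch <- c(1L, config$convChannels)
  params <- .withSeed(config$seed, {
    p <- list()
    for (l in 1:3) {
      fanIn <- k * ch[l]
      p[[paste0("Wc", l)]] <- array(
        stats::rnorm(k * ch[l] * ch[l + 1L], 0, sqrt(2 / fanIn)),
        c(k, ch[l], ch[l + 1L]))
      p[[paste0("bc", l)]] <- numeric(ch[l + 1L])
    }
    p$gamma <- rep(1, ch[4L])
    p$beta <- numeric(ch[4L])
    flat <- ws[3] * ch[4L]
    sizes <- c(flat, config$fcSizes, 2L)
    for (l in 1:3) {
      p[[paste0("Wf", l)]] <- matrix(
        stats::rnorm(sizes[l] * sizes[l + 1L], 0, sqrt(2 / sizes[l])),
        sizes[l], sizes[l + 1L])
      p[[paste0("bf", l)]] <- numeric(sizes[l + 1L])
    }
    p
  })
  structure(list(
    config = config, inputWidth = as.integer(inputWidth),
    pooledWidths = ws, params = params,
    bnRunning = list(mean = numeric(ch[4L]), var = rep(1, ch[4L])),
    trained = FALSE, history = numeric(0)), class = "CnnModel")
}

# Forward pass; returns probabilities plus caches when training.
.cnnForward <- function(model, X, train = FALSE) {
  p <- model$params; cfg <- model$config
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  for (l in 1:3) {
    Z <- .convForward(A, p[[paste0("Wc", l)]], p[[paste0("bc", l)]])
    R <- Z; R[R < 0] <- 0
    pl <- .poolForward(R, cfg$poolSize)
    caches[[l]] <- list(Ain = A, Z = Z, pool = pl)
    A <- pl$out
  }
  bn <- .bnForward(A, p$gamma, p$beta, model$bnRunning, train = train)
  M <- bn$out; dim(M) <- c(B, prod(dim(bn$out)[2:3]))
  H1 <- M %*% p$Wf1; H1 <- sweep(H1, 2L, p$bf1, "+"); H1[H1 < 0] <- 0
  H2 <- H1 %*% p$Wf2; H2 <- sweep(H2, 2L, p$bf2, "+"); H2[H2 < 0] <- 0
  Z3 <- H2 %*% p$Wf3; Z3 <- sweep(Z3, 2L, p$bf3, "+")
  probs <- .softmax(Z3)
  list(probs = probs, caches = caches, bn = bn, M = M, H1 = H1, H2 = H2)
}

.cnnBackward <- function(model, fw, X, y01) {
  p <- model$params; cfg <- model$config
  B <- nrow(X)
  Y <- cbind(1 - y01, y01)
  g <- list()
  dZ3 <- (fw$probs - Y) / B
  g$Wf3 <- crossprod(fw$H2, dZ3); g$bf3 <- colSums(dZ3)
  dH2 <- dZ3 %*% t(p$Wf3); dH2[fw$H2 <= 0] <- 0
  g$Wf2 <- crossprod(fw$H1, dH2); g$bf2 <- colSums(dH2)
  dH1 <- dH2 %*% t(p$Wf2); dH1[fw$H1 <= 0] <- 0
  g$Wf1 <- crossprod(fw$M, dH1); g$bf1 <- colSums(dH1)
  dM <- dH1 %*% t(p$Wf1)
  dim(dM) <- dim(fw$bn$out)
  bnb <- .bnBackward(fw$bn, p$gamma, dM)
  g$gamma <- bnb$dgamma; g$beta <- bnb$dbeta
  dA <- bnb$dA
  for (l in 3:1) {
    cc <- fw$caches[[l]]
    dR <- .poolBackward(cc$pool, dA, cfg$poolSize)
    dR[cc$Z <= 0] <- 0
    cb <- .convBackward(cc$Ain, p[[paste0("Wc", l)]], dR)
    g[[paste0("Wc", l)]] <- cb$dW
    g[[paste0("bc", l)]] <- cb$db
    dA <- cb$dA
  }
  g
}

#' Train the CNN on fused similarity rows
#'
#' Minimizes the cross-entropy with Adam; the per-epoch mean training loss is
#' recorded in `$history`. Deterministic given the config seed and a fixed
#' thread count.
#'
#' @param model an untrained `CnnModel` from [buildCnnModel()].
#' @param X numeric matrix of training rows (samples x `inputWidth`) or a
#'   [FusedMatrix-class].
#' @param labels 0/1 vector; both classes must be present with at least two
#'   samples each.
#' @return The trained `CnnModel` (with `$trained = TRUE` and `$history`).
#' @export
trainCnn <- function(model, X, labels) {
  stopifnot(inherits(model, "CnnModel"))
  if (is(X, "FusedMatrix")) X <- X@values
  X <- as.matrix(X)
  labels <- as.integer(labels)
  if (ncol(X) != model$inputWidth)
    stop("training rows have width ", ncol(X), "; model expects ", model$inputWidth)
  if (anyNA(X) || any(!is.finite(X))) stop("training rows must be finite")
  if (length(labels) != nrow(X)) stop("labels must match the training rows")
  if (min(table(factor(labels, levels = c(0L, 1L)))) < 2L)
    stop("need at least 2 training samples in each class")
  cfg <- model$config
  params <- model$params
  mAdam <- lapply(params, function(x) x * 0)
  vAdam <- lapply(params, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; epsA <- 1e-8
  tA <- 0L
  history <- numeric(cfg$epochs)
  n <- nrow(X)
  .withSeed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      idx <- sample(n)
      lossSum <- 0; lossN <- 0L
      for (start in seq(1L, n, by = cfg$batchSize)) {
        bi <- idx[start:min(start + cfg$batchSize - 1L, n)]
        Xb <- X[bi, , drop = FALSE]
        yb <- labels[bi]
        model$params <- params
        fw <- .cnnForward(model, Xb, train = TRUE)
        model$bnRunning <- fw$bn$running
        pTrue <- fw$probs[cbind(seq_along(bi), yb + 1L)]
        loss <- -mean(log(pmax(pTrue, 1e-12)))
        if (!is.finite(loss))
          stop("non-finite training loss at epoch ", ep)
        lossSum <- lossSum + loss * length(bi); lossN <- lossN + length(bi)
        g <- .cnnBackward(model, fw, Xb, yb)
        tA <- tA + 1L
        corr1 <- 1 - b1^tA; corr2 <- 1 - b2^tA
        for (nm in names(params)) {
          mAdam[[nm]] <- b1 * mAdam[[nm]] + (1 - b1) * g[[nm]]
          vAdam[[nm]] <- b2 * vAdam[[nm]] + (1 - b2) * g[[nm]]^2
          params[[nm]] <- params[[nm]] - cfg$learningRate *
            (mAdam[[nm]] / corr1) / (sqrt(vAdam[[nm]] / corr2) + epsA)
        }
      }
      history[ep] <- lossSum / lossN
    }
  })
  model$params <- params
  model$history <- history
  model$trained <- TRUE
  model
}

#' Predict class probabilities and labels
#'
#' Softmax probabilities per row (batch-norm uses running statistics) and
#' hard labels by argmax; ties go to class 0. Zero rows yield empty output.
#'
#' @param model a trained `CnnModel`.
#' @param X matrix of rows to classify (samples x `inputWidth`) or a
#'   [FusedMatrix-class].
#' @return List with `prob` (k x 2 matrix, columns `p0`, `p1`) and `label`
#'   (integer 0/1 vector).
#' @export
predictCnn <- function(model, X) {
  stopifnot(inherits(model, "CnnModel"))
  if (is(X, "FusedMatrix")) X <- X@values
  X <- as.matrix(X)
  if (nrow(X) == 0L) {
    return(list(prob = matrix(numeric(0), 0L, 2L,
      dimnames = list(NULL, c("p0", "p1"))), label = integer(0)))
  }
  if (ncol(X) != model$inputWidth)
    stop("rows have width ", ncol(X), "; model expects ", model$inputWidth)
  fw <- .cnnForward(model, X, train = FALSE)
  prob <- fw$probs
  colnames(prob) <- c("p0", "p1")
  rownames(prob) <- rownames(X)
  list(prob = prob, label = as.integer(prob[, 2L] > prob[, 1L]))
}

#' Save / load a CNN checkpoint
#'
#' The checkpoint embeds the config, input width, weights and batch-norm
#' running statistics.
#'
#' @param model a `CnnModel`.
#' @param path checkpoint path.
#' @return `saveCnnModel`: `path` invisibly; `loadCnnModel`: the model.
#' @export
saveCnnModel <- function(model, path) {
  stopifnot(inherits(model, "CnnModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCnnModel
#' @export
loadCnnModel <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "CnnModel"))
  model
}
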