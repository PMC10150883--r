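test_that("pooled widths follow floor division and underflow is rejected", {
  cfg <- cnnConfig()
  m <- buildCnnModel(cfg, 300)
  expect_identical(m$pooledWidths, c(150L, 75L, 37L))
  expect_error(buildCnnModel(cfg, 4), "underflow.*minimum width is 8")
})

test_that("model construction is deterministic under the config seed", {
  cfg <- cnnConfig(seed = 11)
  a <- buildCnnModel(cfg, 96)
  b <- buildCnnModel(cfg, 96)
  expect_identical(a$params, b$params)
  c2 <- buildCnnModel(cnnConfig(seed = 12), 96)
  expect_false(identical(a$params, c2$params))
})

test_that("analytic gradients match numerical differentiation", {
  cfg <- cnnConfig(convChannels = c(2, 2, 3), kernelSize = 3, poolSize = 2,
                   fcSizes = c(5, 4), epochs = 1, batchSize = 4, seed = 3)
  mod <- buildCnnModel(cfg, 24)
  # move biases off zero so no relu unit sits exactly at its kink, where
  # the subgradient and a central difference legitimately disagree
  for (nm in c("bc1", "bc2", "bc3", "bf1", "bf2", "bf3", "beta"))
    mod$params[[nm]] <- mod$params[[nm]] + 0.1
  set.seed(9)
  X <- matrix(rnorm(4 * 24), 4, 24)
  y <- c(0L, 1L, 1L, 0L)
  fw <- DrugSensFusion:::.cnnForward(mod, X, train = TRUE)
  g <- DrugSensFusion:::.cnnBackward(mod, fw, X, y)
  lossAt <- function(m) {
    f <- DrugSensFusion:::.cnnForward(m, X, train = TRUE)
    -mean(log(f$probs[cbind(1:4, y + 1)]))
  }
  eps <- 1e-5
  set.seed(11)
  for (nm in names(mod$params)) {
    for (rep in 1:3) {
      i <- sample(length(mod$params[[nm]]), 1)
      m2 <- mod
      m2$params[[nm]][i] <- mod$params[[nm]][i] + eps
      lp <- lossAt(m2)
      m2$params[[nm]][i] <- mod$params[[nm]][i] - eps
      lm <- lossAt(m2)
      num <- (lp - lm) / (2 * eps)
      expect_equal(unname(g[[nm]][i]), num, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and fits separable toy data", {
  toy <- toyCnnData(n = 40, W = 48, shift = 2, seed = 2)
  cfg <- cnnConfig(convChannels = c(4, 6, 8), fcSizes = c(16, 8),
                   epochs = 30, batchSize = 8, seed = 5)
  m <- trainCnn(buildCnnModel(cfg, 48), toy$X, toy$y)
  expect_length(m$history, 30)
  expect_lt(m$history[30], m$history[1])
  pred <- predictCnn(m, toy$X)
  expect_gte(mean(pred$label == toy$y), 0.95)
})

test_that("training is deterministic given seed", {
  toy <- toyCnnData(seed = 4)
  cfg <- cnnConfig(convChannels = c(2, 3, 4), fcSizes = c(8, 6),
                   epochs = 5, batchSize = 8, seed = 21)
  a <- trainCnn(buildCnnModel(cfg, 48), toy$X, toy$y)
  b <- trainCnn(buildCnnModel(cfg, 48), toy$X, toy$y)
  expect_identical(a$params, b$params)
  expect_identical(a$history, b$history)
})

test_that("probabilities are a distribution and edge cases are handled", {
  toy <- toyCnnData(seed = 6)
  cfg <- cnnConfig(convChannels = c(2, 3, 4), fcSizes = c(8, 6),
                   epochs = 3, batchSize = 8, seed = 2)
  m <- trainCnn(buildCnnModel(cfg, 48), toy$X, toy$y)
  pred <- predictCnn(m, toy$X)
  expect_equal(unname(rowSums(pred$prob)), rep(1, nrow(toy$X)), tolerance = 1e-6)
  expect_true(all(pred$prob >= 0))
  # zero rows: empty output, no error
  empty <- predictCnn(m, toy$X[0, , drop = FALSE])
  expect_identical(dim(empty$prob), c(0L, 2L))
  expect_identical(empty$label, integer(0))
  # width mismatch
  expect_error(predictCnn(m, toy$X[, 1:20]), "width")
  # single-class training set
  expect_error(trainCnn(buildCnnModel(cfg, 48), toy$X, rep(1L, 40)),
               "each class")
})

test_that("checkpoints restore an identical model", {
  toy <- toyCnnData(seed = 8)
  cfg <- cnnConfig(convChannels = c(2, 3, 4), fcSizes = c(8, 6),
                   epochs = 3, batchSize = 8, seed = 13)
  m <- trainCnn(buildCnnModel(cfg, 48), toy$X, toy$y)
  path <- withr::local_tempfile(fileext = ".rds")
  saveCnnModel(m, path)
  m2 <- loadCnnModel(path)
  expect_identical(predictCnn(m, toy$X), predictCnn(m2, toy$X))
})
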