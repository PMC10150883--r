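test_that("sparse projection keeps the largest magnitudes with stable ties", {
  expect_equal(sparseProject(c(0.5, -3, 2, -2.5), 2), c(0, -3, 0, -2.5))
  # tie at |1|: lower index wins
  expect_equal(sparseProject(c(1, 1, 2), 2), c(1, 0, 2))
  z <- rnorm(7)
  expect_equal(sparseProject(z, 7), z)
  expect_error(sparseProject(z, 0), "s must satisfy")
  expect_error(sparseProject(z, 8), "s must satisfy")
})

test_that("sparse projection maximizes kept energy against brute-force enumeration", {
  set.seed(101)
  for (rep in 1:200) {
    p <- sample(3:12, 1)
    s <- sample(seq_len(p), 1)
    z <- round(rnorm(p), 3)
    fast <- sparseProject(z, s)
    slow <- bruteSparseProject(z, s)
    expect_equal(sum(fast^2), sum(slow^2))
  }
})

test_that("rank-1 SPCA solves trivial and planted problems", {
  # single nonzero entry
  X <- matrix(0, 3, 4, dimnames = list(paste0("f", 1:3), paste0("s", 1:4)))
  X[1, 1] <- 5
  sc <- spcaRank1(X, 1)
  expect_identical(sc@support, 1L)
  expect_equal(sc@objective, 5)
  expect_equal(abs(sc@v), c(1, 0, 0, 0))
  # planted two-feature loading, noiseless
  set.seed(5)
  u <- numeric(6); u[c(1, 3)] <- 1 / sqrt(2)
  v <- rnorm(8); v <- v / sqrt(sum(v^2))
  sc2 <- spcaRank1(u %*% t(v), 2)
  expect_identical(sc2@support, c(1L, 3L))
  expect_equal(sc2@objective, 1, tolerance = 1e-9)
  # all-zero matrix is degenerate
  expect_error(spcaRank1(matrix(0, 4, 4), 2), "degenerate")
})

test_that("with s = m the solution matches the dense leading singular pair", {
  set.seed(7)
  for (rep in 1:10) {
    X <- matrix(rnorm(20 * 10), 20, 10)
    sc <- spcaRank1(X, 20)
    u1 <- svd(X, nu = 1, nv = 0)$u[, 1]
    expect_gt(abs(sum(sc@u * u1)), 0.999)
  }
})

test_that("objective trace is monotonically non-decreasing", {
  set.seed(11)
  for (rep in 1:20) {
    X <- matrix(rnorm(30 * 15), 30, 15)
    s <- sample(1:30, 1)
    sc <- spcaRank1(X, s, vInit = "random", seed = rep)
    expect_true(all(diff(sc@objectiveTrace) >= -1e-10))
    expect_lte(length(sc@support), s)
  }
})

test_that("planted sparse supports are recovered under noise", {
  hits <- 0L
  for (sd in 1:20) {
    pl <- plantedRank1(m = 200, n = 60, k = 5, snr = 10, seed = sd)
    sc <- spcaRank1(pl$X, 5)
    if (identical(sc@support, pl$support)) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("deflation extracts orthogonal planted components in order", {
  set.seed(19)
  m <- 40; n <- 25
  u1 <- numeric(m); u1[1:3] <- 1 / sqrt(3)
  u2 <- numeric(m); u2[10:12] <- 1 / sqrt(3)
  v1 <- rnorm(n); v1 <- v1 / sqrt(sum(v1^2))
  v2 <- rnorm(n); v2 <- v2 - sum(v2 * v1) * v1; v2 <- v2 / sqrt(sum(v2^2))
  X <- 8 * u1 %*% t(v1) + 4 * u2 %*% t(v2)
  comps <- spcaComponents(X, s = 3, k = 2)
  expect_identical(comps[[1]]@support, 1:3)
  expect_identical(comps[[2]]@support, 10:12)
  expect_equal(comps[[1]]@objective, 8, tolerance = 1e-6)
  expect_equal(comps[[2]]@objective, 4, tolerance = 1e-6)
})

test_that("the sign convention makes the largest loading positive", {
  set.seed(13)
  X <- matrix(rnorm(12 * 6), 12, 6)
  sc <- spcaRank1(X, 4)
  expect_gt(sc@u[which.max(abs(sc@u))], 0)
})
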