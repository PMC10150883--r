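test_that("Pearson similarity reproduces hand-computed values", {
  F <- cbind(a = c(1, 2, 3), b = c(1, 2, 4))
  s <- pearsonSimilarity(F)
  expect_equal(as.matrix(s)[1, 2], 9 / (2 * sqrt(21)), tolerance = 1e-12)
  # perfect anti-correlation
  F2 <- cbind(a = c(1, 2, 3), b = c(6, 4, 2))
  expect_equal(as.matrix(pearsonSimilarity(F2))[1, 2], -1, tolerance = 1e-12)
  # identical vectors
  F3 <- cbind(a = c(1, 5, 2), b = c(1, 5, 2))
  expect_equal(as.matrix(pearsonSimilarity(F3))[1, 2], 1, tolerance = 1e-12)
})

test_that("Pearson similarity is invariant to shifting and positive rescaling", {
  set.seed(17)
  F <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, paste0("s", 1:6)))
  base <- as.matrix(pearsonSimilarity(F))
  expect_equal(as.matrix(pearsonSimilarity(F + 3)), base, tolerance = 1e-12)
  expect_equal(as.matrix(pearsonSimilarity(F * 2.5)), base, tolerance = 1e-12)
})

test_that("zero-variance samples are rejected by name", {
  F <- cbind(good = c(1, 2, 3), flat = c(2, 2, 2))
  expect_error(pearsonSimilarity(F), "flat")
})

test_that("Kendall tau-a reproduces enumerated pair counts", {
  F <- cbind(a = c(1, 2, 3), b = c(2, 1, 3))
  expect_equal(as.matrix(kendallSimilarity(F))[1, 2], 1 / 3)
  F2 <- cbind(a = c(1, 2, 3), b = c(3, 2, 1))
  expect_equal(as.matrix(kendallSimilarity(F2))[1, 2], -1)
  F3 <- cbind(a = c(1, 2, 3), b = c(1, 2, 3))
  expect_equal(as.matrix(kendallSimilarity(F3))[1, 2], 1)
})

test_that("Kendall tau-a agrees exactly with the O(c^2) oracle, including ties", {
  set.seed(23)
  for (cFeat in c(5, 17, 50)) {
    F <- matrix(sample(-2:2, cFeat * 4, replace = TRUE), cFeat, 4,
                dimnames = list(NULL, paste0("s", 1:4)))
    got <- as.matrix(kendallSimilarity(F))
    for (i in 1:3) for (j in (i + 1):4) {
      expect_identical(got[i, j], bruteTauA(F[, i], F[, j]))
    }
  }
})

test_that("similarity matrices are symmetric with unit diagonal", {
  set.seed(29)
  F <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("s", 1:8)))
  Fc <- matrix(sample(-2:2, 30 * 8, TRUE), 30, 8,
               dimnames = list(NULL, paste0("s", 1:8)))
  for (s in list(pearsonSimilarity(F), kendallSimilarity(Fc))) {
    v <- as.matrix(s)
    expect_lt(max(abs(v - t(v))), 1e-9)
    expect_equal(unname(diag(v)), rep(1, 8))
    expect_true(all(v >= -1 - 1e-9 & v <= 1 + 1e-9))
  }
})

test_that("similarity is invariant to feature ordering", {
  set.seed(31)
  F <- matrix(rnorm(25 * 5), 25, 5, dimnames = list(NULL, paste0("s", 1:5)))
  perm <- sample(25)
  expect_equal(as.matrix(pearsonSimilarity(F)),
               as.matrix(pearsonSimilarity(F[perm, ])), tolerance = 1e-12)
  Fc <- matrix(sample(-2:2, 25 * 5, TRUE), 25, 5,
               dimnames = list(NULL, paste0("s", 1:5)))
  expect_identical(as.matrix(kendallSimilarity(Fc)),
                   as.matrix(kendallSimilarity(Fc[perm, ])))
})

test_that("fusion concatenates losslessly and checks sample order", {
  set.seed(37)
  sids <- paste0("s", 1:4)
  mk <- function(kind, seed) {
    F <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(NULL, sids))
    pearsonSimilarity(F, omicsKind = kind)
  }
  blocks <- list(mk("rnaseq", 1), mk("cna", 2), mk("methylation", 3))
  fused <- fuseNetworks(blocks)
  expect_equal(dim(as.matrix(fused)), c(4L, 12L))
  expect_identical(blockOrder(fused), c("rnaseq", "cna", "methylation"))
  for (b in 1:3) {
    expect_identical(unname(extractBlock(fused, b)),
                     unname(as.matrix(blocks[[b]])))
  }
  expect_identical(unname(extractBlock(fused, "cna")),
                   unname(as.matrix(blocks[[2]])))
  # single block: fusion is the identity
  f1 <- fuseNetworks(blocks[1])
  expect_identical(unname(as.matrix(f1)), unname(as.matrix(blocks[[1]])))
  # mismatched sample order is rejected
  bad <- blocks[[2]]
  bad@values <- bad@values[4:1, 4:1]
  bad@sampleIDs <- rev(bad@sampleIDs)
  expect_error(fuseNetworks(list(blocks[[1]], bad)), "sample order")
})

test_that("similarity TSV serialization carries IDs and sidecar metadata", {
  set.seed(41)
  F <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("s", 1:5)))
  sim <- pearsonSimilarity(F)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSimilarity(sim, path)
  back <- read.delim(path, check.names = FALSE)
  expect_identical(colnames(back)[-1], sampleIDs(sim))
  expect_equal(unname(as.matrix(back[, -1])), unname(as.matrix(sim)),
               tolerance = 0)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"))
  expect_identical(meta$method, "pearson")
})
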