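test_that("simulation respects value domains and class balance", {
  cfg <- simConfig(nSamples = 60, blockSizes = c(80, 60, 90),
                   nInformative = c(10, 8, 12), effectSize = 2, seed = 5)
  sim <- simulateMultiOmics(cfg)
  ds <- sim@dataset
  expect_identical(names(ds@blocks), c("rnaseq", "cna", "methylation"))
  cna <- as.matrix(ds@blocks$cna)
  expect_true(all(cna == round(cna)))
  expect_true(all(cna >= -2 & cna <= 2))
  meth <- as.matrix(ds@blocks$methylation)
  expect_true(all(meth >= 0 & meth <= 1))
  expect_equal(sum(ds@labels), 30)
  # truth indices are valid per block
  for (k in names(sim@truth))
    expect_true(all(sim@truth[[k]] %in% featureIDs(ds@blocks[[k]])))
})

test_that("identical configs give identical datasets; seeds differ", {
  cfg <- simConfig(nSamples = 40, blockSizes = c(50, 40, 60),
                   nInformative = c(5, 5, 5), seed = 9)
  a <- simulateMultiOmics(cfg)
  b <- simulateMultiOmics(cfg)
  expect_identical(lapply(a@dataset@blocks, as.matrix),
                   lapply(b@dataset@blocks, as.matrix))
  expect_identical(a@dataset@labels, b@dataset@labels)
  cfg2 <- simConfig(nSamples = 40, blockSizes = c(50, 40, 60),
                    nInformative = c(5, 5, 5), seed = 10)
  expect_false(identical(as.matrix(a@dataset@blocks$rnaseq),
                         as.matrix(simulateMultiOmics(cfg2)@dataset@blocks$rnaseq)))
})

test_that("planted expression features show the configured standardized shift", {
  cfg <- simConfig(nSamples = 200, blockSizes = c(300, 100, 100),
                   nInformative = c(30, 5, 5), effectSize = 3, seed = 11)
  sim <- simulateMultiOmics(cfg)
  vals <- as.matrix(sim@dataset@blocks$rnaseq)
  labs <- sim@dataset@labels
  for (fid in sim@truth$rnaseq) {
    x1 <- vals[fid, labs == 1L]; x0 <- vals[fid, labs == 0L]
    pooled <- sqrt((var(x1) * (length(x1) - 1) + var(x0) * (length(x0) - 1)) /
                   (length(x1) + length(x0) - 2))
    smd <- (mean(x1) - mean(x0)) / pooled
    expect_gte(smd, 2); expect_lte(smd, 4)
  }
})

test_that("a zero effect size yields a pure null dataset", {
  cfg <- simConfig(nSamples = 120, blockSizes = c(200, 100, 150),
                   nInformative = c(20, 10, 15), effectSize = 0, seed = 13)
  sim <- simulateMultiOmics(cfg)
  labs <- sim@dataset@labels
  maxT <- 0
  for (k in c("rnaseq", "methylation")) {
    vals <- as.matrix(sim@dataset@blocks[[k]])
    for (i in seq_len(nrow(vals))) {
      tt <- abs(t.test(vals[i, labs == 1L], vals[i, labs == 0L])$statistic)
      maxT <- max(maxT, tt)
    }
  }
  expect_lt(maxT, 4)
  # CNA class-conditional distributions coincide at delta = 0
  pr <- DrugSensFusion:::.cnaProbs(0)
  expect_identical(pr$class0, pr$class1)
})

test_that("named fixtures exist and unknown names are rejected", {
  sep <- simulateFixture("separable", seed = 1)
  expect_equal(sep@config$effectSize, 3)
  nul <- simulateFixture("null", seed = 1)
  expect_equal(nul@config$effectSize, 0)
  trap <- simulateFixture("variance_trap", seed = 1)
  expect_length(trap@trapFeatures, 6)
  expect_false(any(trap@trapFeatures %in% trap@truth$rnaseq))
  expect_error(simulateFixture("nope"), "arg")
})

test_that("datasets write to disk reproducibly and read back", {
  cfg <- simConfig(nSamples = 30, blockSizes = c(20, 15, 25),
                   nInformative = c(3, 3, 3), seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  runSimulate(cfg, d1)
  runSimulate(cfg, d2)
  for (f in c("rnaseq.tsv", "cna.tsv", "methylation.tsv", "response.tsv",
              "truth.json")) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7))
  }
  back <- readOmicsMatrix(file.path(d1, "cna.tsv"), "cna")
  sim <- simulateMultiOmics(cfg)
  expect_identical(as.matrix(back), as.matrix(sim@dataset@blocks$cna))
  resp <- readDrugResponse(file.path(d1, "response.tsv"))
  expect_identical(responseLabels(resp), sim@dataset@labels)
})

test_that("configs below the minimum sample size are rejected", {
  expect_error(simConfig(nSamples = 5), "nSamples")
})
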