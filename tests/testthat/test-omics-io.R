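test_that("omics matrices round-trip bit-exactly through TSV, plain and gzipped", {
  for (kind in c("rnaseq", "cna", "methylation")) {
    x <- tinyOmics(kind, m = 6, n = 4, seed = 42)
    for (ext in c(".tsv", ".tsv.gz")) {
      path <- withr::local_tempfile(fileext = ext)
      writeOmicsMatrix(x, path)
      y <- readOmicsMatrix(path, kind)
      expect_identical(as.matrix(y), as.matrix(x))
      expect_identical(featureIDs(y), featureIDs(x))
      expect_identical(sampleIDs(y), sampleIDs(x))
    }
  }
})

test_that("features with missing values are dropped and counted", {
  x <- tinyOmics("rnaseq", m = 4, n = 4)
  v <- as.matrix(x)
  v[2, 3] <- NA
  path <- withr::local_tempfile(fileext = ".tsv")
  lines <- c(paste(c("feature_id", colnames(v)), collapse = "\t"),
    vapply(seq_len(nrow(v)), function(i)
      paste(c(rownames(v)[i], v[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  expect_message(y <- readOmicsMatrix(path, "rnaseq"), "1 feature")
  expect_equal(nrow(as.matrix(y)), 3L)
  expect_false("rnaseq_f02" %in% featureIDs(y))
  expect_equal(y@droppedFeatures, 1L)
})

test_that("invalid omics files are rejected with informative errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  # duplicate feature IDs
  writeLines(c("feature_id\tS1\tS2\tS3", "g1\t1\t2\t3", "g1\t4\t5\t6",
               "g2\t1\t1\t1"), path)
  expect_error(readOmicsMatrix(path, "rnaseq"), "duplicate feature IDs.*g1")
  # non-integer copy number value, named cell
  writeLines(c("feature_id\tS1\tS2\tS3", "g1\t1\t1.5\t0", "g2\t0\t2\t-1"), path)
  expect_error(readOmicsMatrix(path, "cna"), "g1.*S2")
  # methylation out of range
  writeLines(c("feature_id\tS1\tS2\tS3", "g1\t0.2\t0.4\t1.2", "g2\t0\t1\t0.5"),
             path)
  expect_error(readOmicsMatrix(path, "methylation"), "g1.*S3")
})

test_that("IC50 binarization follows the strict-less-than and median rules", {
  tab <- DrugResponse(paste0("s", 1:4), ic50 = c(1, 2, 3, 4), drugID = "d1")
  expect_identical(responseLabels(binarizeIC50(tab, 2.5)), c(1L, 1L, 0L, 0L))
  med <- binarizeIC50(tab, "median")
  expect_identical(responseLabels(med), c(1L, 1L, 0L, 0L))
  expect_equal(med@threshold, 2.5)
  # a value exactly at the threshold lands in class 0
  tab2 <- DrugResponse(paste0("s", 1:3), ic50 = c(1, 2, 3))
  expect_identical(responseLabels(binarizeIC50(tab2, 2)), c(1L, 0L, 0L))
  # degenerate: single class
  tab3 <- DrugResponse(paste0("s", 1:3), ic50 = c(5, 5, 5))
  expect_error(binarizeIC50(tab3, 1), "one class")
  expect_error(binarizeIC50(tab3, "median"), "one class")
})

test_that("binarization depends only on values and threshold, not sample order", {
  set.seed(3)
  ic <- rnorm(20)
  ord <- sample(20)
  a <- binarizeIC50(DrugResponse(paste0("s", 1:20), ic50 = ic), 0)
  b <- binarizeIC50(DrugResponse(paste0("s", 1:20)[ord], ic50 = ic[ord]), 0)
  expect_identical(responseLabels(a)[ord], responseLabels(b))
})

test_that("alignment intersects and lexicographically orders samples", {
  mk <- function(sids, kind = "rnaseq", seed = 1) {
    x <- tinyOmics(kind, m = 4, n = length(sids), seed = seed)
    v <- as.matrix(x); colnames(v) <- sids
    OmicsMatrix(v, kind)
  }
  b1 <- mk(c("C", "A", "B", "D"))
  b2 <- mk(c("B", "C", "D", "E"), "cna", seed = 2)
  tab <- DrugResponse(c("B", "C", "D", "F"), labels = c(1L, 0L, 1L, 0L))
  expect_message(ds <- alignSamples(list(b1, b2), tab), "dropped")
  expect_identical(sampleIDs(ds), c("B", "C", "D"))
  expect_identical(responseLabels(ds), c(1L, 0L, 1L))
  expect_identical(as.matrix(ds@blocks[[1]]), as.matrix(b1)[, c("B", "C", "D")])
  # idempotence: aligning an already-aligned dataset changes nothing
  tab2 <- DrugResponse(sampleIDs(ds), labels = responseLabels(ds))
  ds2 <- alignSamples(ds@blocks, tab2)
  expect_identical(sampleIDs(ds2), sampleIDs(ds))
  expect_identical(lapply(ds2@blocks, as.matrix), lapply(ds@blocks, as.matrix))
  # disjoint sample sets are a hard error
  b3 <- mk(c("X", "Y", "Z"))
  expect_error(alignSamples(list(b1, b3), tab), "no sample IDs")
})

test_that("drug-response tables read back from disk", {
  tab <- binarizeIC50(
    DrugResponse(paste0("s", 1:6), ic50 = c(1, 5, 2, 6, 3, 7), drugID = "dx"),
    "median")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeDrugResponse(tab, path)
  back <- readDrugResponse(path)
  expect_identical(responseLabels(back), responseLabels(tab))
  expect_identical(drugID(back), "dx")
  expect_equal(back@ic50, tab@ic50)
})
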