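test_that("control profile takes the max proportion across positive controls", {
  x <- tinyExperiment()
  prof <- maxControlProportion(x)
  expect_equal(unname(prof["A1"]), 0.03)  # 10/1000 and 30/1000
  expect_equal(unname(prof["A2"]), 0)
  expect_equal(unname(prof["ACTL"]), 0.99)  # max(990/1000, 970/1000)
})

test_that("zero-read controls are excluded; all-zero controls are an error", {
  x <- tinyExperiment()
  m <- counts(x)
  m[, "POS_run1_2"] <- 0
  assay(x, "counts") <- m
  prof <- maxControlProportion(x)
  expect_equal(unname(prof["A1"]), 0.01)  # only the 10/1000 control remains
  m[, "POS_run1_1"] <- 0
  assay(x, "counts") <- m
  expect_error(maxControlProportion(x), "zero reads")

  noctl <- x[, sampleClass(x) == "environmental"]
  expect_error(maxControlProportion(noctl), "no positive-control")
})

test_that("subtraction reduces proportions, floors at zero and keeps depth", {
  env <- matrix(c(50, 30, 920), 3, 1)
  env <- cbind(env, c(60, 10, 930), c(40, 20, 940))
  envCounts <- rbind(env, 0)  # 4th row: control taxon, absent in field
  x <- tinyExperiment(envCounts)
  prof <- setNames(c(0.03, 0.1, 0, 0), rownames(x))
  y <- subtractContamination(x, prof, removeControlTaxa = TRUE)
  # replicate 1: total 1000; A1 50/1000 - 0.03 -> 0.02 -> 20 counts
  expect_equal(unname(counts(y)["A1", 1]), 20)
  # A2 at 30/1000 < 0.1 floors to zero
  expect_equal(unname(counts(y)["A2", 1]), 0)
  expect_false("ACTL" %in% rownames(y))
  expect_true(all(counts(y) >= 0))
  expect_true("decontaminated" %in% provenance(y))
})

test_that("a zero profile is the identity on field samples", {
  x <- tinyExperiment()
  prof <- setNames(numeric(4), rownames(x))
  y <- subtractContamination(x, prof, removeControlTaxa = FALSE)
  expect_equal(counts(y), counts(x))
})

test_that("ASVs absent from controls are numerically unchanged", {
  x <- tinyExperiment()
  y <- subtractContamination(x)
  env <- sampleClass(x) == "environmental"
  expect_equal(counts(y)["A2", colnames(x)[env]],
               counts(x)["A2", env])
})

test_that("decontamination removes all control-taxon reads from field samples", {
  sim <- simulateStudy(surveyDesign(seed = 21))
  x <- sim$experiment
  ctl_ids <- rownames(x)[rowData(x)$control]
  env <- sampleClass(x) == "environmental"
  expect_gt(sum(counts(x)[ctl_ids, env]), 0)  # leakage was injected
  y <- subtractContamination(x)
  expect_false(any(ctl_ids %in% rownames(y)))
  # even without removing the rows, the profile zeroes them out
  y2 <- subtractContamination(x, removeControlTaxa = FALSE)
  expect_equal(sum(counts(y2)[ctl_ids, sampleClass(y2) == "environmental"]), 0)
})

test_that("low-read replicates are dropped by threshold", {
  fill <- function(s, mo, p, r) {
    tot <- c(12, 50000, 48000)[r]
    setNames(round(tot * c(0.1, 0.4, 0.5)), c("A1", "A2", "A3"))
  }
  x <- designedExperiment(fill, positions = "1", nrep = 3)
  expect_message(y <- dropLowReadReplicates(x, 1000), "low-read")
  expect_equal(ncol(y), 2)
  expect_equal(nrow(metadata(y)$low_read_removed), 1)

  expect_equal(ncol(dropLowReadReplicates(x, 0)), 3)
  expect_warning(z <- dropLowReadReplicates(x, 1e6), "no environmental")
  expect_equal(ncol(z), 0)
})
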