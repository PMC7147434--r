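test_that("detection histories count detections per bottle", {
  fill <- function(s, mo, p, r) {
    c(A1 = if (r <= 2) 5 else 0,  # detected in 2 of 3 replicates
      A2 = 0,                      # never detected
      A3 = 3)
  }
  x <- designedExperiment(fill, positions = "1", nrep = 3)
  h <- buildDetectionHistories(x)
  expect_equal(h$y[h$asv_id == "A1"], 2L)
  expect_equal(h$K[h$asv_id == "A1"], 3L)
  expect_equal(h$y[h$asv_id == "A2"], 0L)  # zero history retained
  expect_equal(nrow(h), 3)

  # replicate attrition: a bottle reduced to 2 replicates has K = 2
  x2 <- x[, 1:2]
  h2 <- buildDetectionHistories(x2)
  expect_true(all(h2$K == 2L))
  expect_equal(h2$y[h2$asv_id == "A1"], 2L)
})

test_that("the conditional presence probability matches the closed form", {
  expect_equal(presenceProb(0.5, 0.8, 0.1, y = 0, K = 3),
               0.5 * 0.008 / (0.5 * 0.008 + 0.5 * 0.729))
  # false positives impossible: any detection implies presence
  expect_equal(presenceProb(0.3, 0.8, 0, y = 1, K = 3), 1)
  expect_equal(presenceProb(1, 0.8, 0.1, y = 0, K = 3), 1)
  # monotone nondecreasing in y when p11 > p10
  p <- presenceProb(0.4, 0.85, 0.05, y = 0:3, K = 3)
  expect_true(all(diff(p) > 0))
})

test_that("posterior extremes behave: saturated and empty detection sets", {
  # all bottles saturated: detection is near-certain and occupancy high,
  # though a high-false-positive explanation keeps some mass off psi = 1
  fit_hi <- fitOccupancyModel(y = rep(3, 50), K = 3, draws = 4000,
                              burnIn = 2000, seed = 1)
  s <- fit_hi@summary
  expect_gt(s$mean[s$parameter == "psi"], 0.75)
  expect_gt(s$mean[s$parameter == "p11"], 0.9)
  pp_hi <- presenceProbability(fit_hi, y = 3, K = 3)
  expect_gt(pp_hi$overall, 0.75)

  fit_lo <- fitOccupancyModel(y = rep(0, 50), K = 3, draws = 2000,
                              burnIn = 1000, seed = 1)
  pp <- presenceProbability(fit_lo, y = rep(0, 50), K = 3)
  expect_lt(pp$overall, 0.2)
})

test_that("MCMC posterior means agree with grid integration on small cases", {
  set.seed(14)
  for (i in 1:4) {
    nb <- sample(10:30, 1)
    y <- rbinom(nb, 3, runif(1, 0.1, 0.9))
    fit <- fitOccupancyModel(y, K = 3, draws = 5000, burnIn = 2000, seed = i)
    oracle <- gridOccupancyOracle(y, rep(3, nb))
    got <- setNames(fit@summary$mean, fit@summary$parameter)
    expect_lt(max(abs(got[names(oracle)] - oracle)), 0.02)
  }
})

test_that("fitOccupancyAll reuses fits across identical detection patterns", {
  fill <- function(s, mo, p, r) c(A1 = 5, A2 = 5, A3 = if (r == 1) 4 else 0)
  x <- designedExperiment(fill, positions = c("1", "3", "6"), nrep = 3)
  occ <- fitOccupancyAll(x, draws = 800, burnIn = 300, seed = 2)
  expect_equal(nrow(occ), 3)
  # A1 and A2 share a pattern, hence an identical posterior
  expect_equal(occ[occ$asv_id == "A1", -1], occ[occ$asv_id == "A2", -1],
               ignore_attr = TRUE)
  occ2 <- fitOccupancyAll(x, draws = 800, burnIn = 300, seed = 2,
                          collapsePatterns = FALSE)
  expect_equal(occ$presence_prob, occ2$presence_prob, tolerance = 1e-9)
})

test_that("the cull removes ASVs strictly below the threshold", {
  m <- matrix(5L, 4, 2, dimnames = list(
    paste0("A", 1:4), c("CI_Eg_0_May_1_run1", "CI_Eg_0_May_2_run1")))
  x <- EdnaExperiment(m)
  probs <- setNames(c(0.05, 0.19, 0.20, 0.9), rownames(x))
  y <- cullAsvs(x, probs, threshold = 0.2)
  expect_equal(rownames(y), c("A3", "A4"))
  expect_true("occupancy-filtered" %in% provenance(y))
  expect_equal(nrow(cullAsvs(x, probs, threshold = 0)), 4)
  expect_equal(rownames(cullAsvs(x, probs, threshold = 1)), character(0))
  probs1 <- setNames(c(0.05, 0.19, 0.20, 1), rownames(x))
  expect_equal(rownames(cullAsvs(x, probs1, threshold = 1)), "A4")
})

test_that("histories must be consistent", {
  expect_error(fitOccupancyModel(y = 4, K = 3), "0 <= y <= K")
  expect_error(fitOccupancyModel(numeric(0), K = 3), "at least one")
  expect_error(buildDetectionHistories(tinyExperiment(), detectThreshold = 0),
               ">= 1")
})
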