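test_that("the 1-D two-cluster split is exact and deterministic", {
  sp <- splitHighLow(c(0.01, 0.02, 0.90))
  expect_equal(as.character(sp$class), c("low", "low", "high"))

  sp2 <- splitHighLow(c(0, 1))
  expect_equal(as.character(sp2$class), c("low", "high"))
  expect_equal(sp2$varianceExplained, 1)

  expect_error(splitHighLow(rep(0.4, 5)), "distinct")

  set.seed(12)
  for (i in 1:30) {
    v <- round(runif(sample(3:12, 1)), 3)
    if (length(unique(v)) < 2) next
    sp <- splitHighLow(v)
    wss <- sum(tapply(v, sp$class, function(g) sum((g - mean(g))^2)))
    oracle <- bruteForceSplit(v)
    expect_equal(wss, oracle$wss, tolerance = 1e-12)
  }
})

test_that("rank-sum p-values are exact for small untied groups", {
  expect_equal(rankSumTest(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rankSumTest(1, 2), 1)
  x <- c(1.2, 3.4, 0.1); y <- c(2.2, 5.1, 0.7, 4.4)
  expect_equal(rankSumTest(x, y), enumRankSumP(x, y), tolerance = 1e-12)
  # identical groups (fully tied): approximate path, p = 1
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_error(rankSumTest(numeric(0), 1), "nonempty")
})

test_that("transect events average a taxon's index over the transect", {
  fill <- function(s, mo, p, r) c(D1 = if (p == "Ba") 300 else 100, O1 = 100)
  x <- designedExperiment(fill, positions = c("Eg", "1", "Ba"), nrep = 2,
                          phyla = c("Dinoflagellata", "Chlorophyta"))
  ev <- transectEvents(x, phylum = "Dinoflagellata")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$taxon_unit, "D1")
  # proportions 0.5 alongshore vs 0.75 at Ba; index 2/3 vs 1
  expect_equal(ev$mean_index, mean(c(2 / 3, 2 / 3, 2 / 3, 2 / 3, 1, 1)))
  expect_warning(transectEvents(x, taxa = "nope"), "no requested taxa")
})

test_that("the Gaussian mixture isolates a separated bare-substrate group", {
  set.seed(4)
  pos <- rep(c("Eg", "1", "3", "6", "10", "15", "Ba"), each = 8)
  val <- ifelse(pos == "Ba", rnorm(56, 0.9, 0.03), rnorm(56, 0.08, 0.03))
  hr <- gmmTwoGroup(data.frame(position = pos, value = val), seed = 1)
  expect_equal(unname(hr@positionGroups[c("Eg", "1", "3", "6", "10", "15")]),
               rep("A", 6))
  expect_equal(unname(hr@positionGroups["Ba"]), "B")
  expect_lt(hr@rankSumP, 0.05)
  expect_gt(hr@varianceExplained, 0.8)
  # component means sit on the cloud means
  expect_lt(abs(hr@componentMeans["A"] - mean(val[pos != "Ba"])), 1e-3)
  expect_lt(abs(hr@componentMeans["B"] - mean(val[pos == "Ba"])), 1e-3)
})

test_that("degenerate mixture inputs are handled", {
  df <- data.frame(position = c("Eg", "1", "3", "Ba"), value = rep(0.5, 4))
  expect_warning(hr <- gmmTwoGroup(df), "identical")
  expect_true(hr@degenerate)
  expect_error(gmmTwoGroup(data.frame(position = c("Eg", "Ba"),
                                      value = c(0.1, 0.9))), "at least 4")
})

test_that("adjacent-point dissimilarity is grouped by spacing and tested", {
  # identical community at all positions: all dissimilarities equal, p = 1
  fill <- function(s, mo, p, r) c(A1 = 10, A2 = 30, A3 = 60)
  x <- designedExperiment(fill, nrep = 2,
                          sites = c("CI", "NR"), months = "May")
  ac <- adjacentDissimilarityCheck(x)
  expect_equal(ac$p, 1)
  expect_equal(sort(unique(ac$pairs$spacing_m)), c(2, 3, 4, 5))
  expect_true(all(ac$pairs$dissimilarity == 0))

  # Eg and Ba never enter the spacing pairs
  expect_false(any(is.na(ac$pairs$spacing_m)))

  fill2 <- function(s, mo, p, r)
    c(A1 = 10 + 5 * match(p, c("Eg", "1", "3", "6", "10", "15", "Ba")),
      A2 = 30, A3 = 60)
  x2 <- designedExperiment(fill2, nrep = 2, sites = c("CI", "NR", "PG"),
                           months = c("May", "July"))
  ac2 <- adjacentDissimilarityCheck(x2)
  expect_true(ac2$p >= 0 && ac2$p <= 1)
  expect_error(adjacentDissimilarityCheck(
    designedExperiment(fill, positions = c("Eg", "1", "Ba"), nrep = 2)),
    "alongshore")
})
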