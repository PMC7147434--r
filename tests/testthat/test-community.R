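test_that("the eDNA index matches the two-step hand computation", {
  m <- matrix(c(10, 30, 90, 70), 2, 2,
              dimnames = list(c("t1", "t2"), c("r1", "r2")))
  idx <- ednaIndex(m)
  # proportions: (0.25, 0.5625) / (0.75, 0.4375); row maxima 0.5625, 0.75
  expect_equal(idx, matrix(c(4 / 9, 1, 1, 7 / 12), 2, 2,
                           dimnames = dimnames(m)))
})

test_that("eDNA index invariants: row maxima, depth invariance, edge cases", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(rpois(60, 40), 6, 10,
                dimnames = list(paste0("t", 1:6), paste0("r", 1:10)))
    idx <- ednaIndex(m)
    expect_equal(unname(apply(idx, 1, max)), rep(1, 6))
    expect_true(all(idx >= 0 & idx <= 1))
    # rescaling one replicate's depth leaves the index unchanged
    m2 <- m; m2[, 3] <- m2[, 3] * 17
    expect_equal(ednaIndex(m2), idx)
  }
  # single replicate: every non-zero taxon scores 1
  one <- matrix(c(3, 9, 0), 3, 1, dimnames = list(letters[1:3], "r1"))
  expect_warning(idx1 <- ednaIndex(one), "all-zero")
  expect_equal(unname(idx1[, 1]), c(1, 1, 0))
  expect_error(ednaIndex(matrix(-1, 1, 1, dimnames = list("a", "b"))),
               "non-negative")
})

test_that("phylum aggregation sums counts before indexing", {
  fill <- function(s, mo, p, r) c(A1 = 10, A2 = 20, A3 = 40)
  x <- designedExperiment(fill, positions = c("1", "3"), nrep = 1,
                          phyla = c("P1", "P1", "P2"))
  idx <- ednaIndex(x, grouping = "phylum")
  expect_equal(sort(rownames(idx)), c("P1", "P2"))
  expect_equal(unname(idx["P1", ]), c(1, 1))  # 30/70 in both replicates
})

test_that("Bray-Curtis follows its formula and metric axioms", {
  m <- cbind(a = c(1, 0), b = c(0, 1), c = c(1, 1))
  d <- as.matrix(brayCurtis(m))
  expect_equal(unname(d["a", "b"]), 1)        # disjoint support
  expect_equal(unname(d["c", "b"]), 1 / 3)    # (1+0)/(1+2)
  expect_equal(unname(diag(d)), rep(0, 3))
  set.seed(3)
  r <- matrix(rpois(40, 5), 4, 10)
  colnames(r) <- paste0("s", 1:10)
  rownames(r) <- paste0("t", 1:4)
  dr <- as.matrix(brayCurtis(r))
  expect_equal(dr, t(dr))
  expect_true(all(dr >= 0 & dr <= 1))
  expect_error(brayCurtis(matrix(-1, 1, 1)), "non-negative")
  z <- cbind(a = c(0, 0), b = c(0, 0), c = c(1, 1))
  expect_warning(dz <- as.matrix(brayCurtis(z)), "all-zero")
  expect_equal(unname(dz["a", "b"]), 0)
})

test_that("nMDS recovers configurations that embed exactly", {
  set.seed(5)
  pts <- matrix(rnorm(24), 12, 2)
  d <- dist(pts)
  fit <- runNmds(d, dims = 2, maxStarts = 40, seed = 2)
  expect_lt(fit$stress, 0.01)

  # two points embed with zero stress
  d2 <- dist(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE))
  expect_lt(runNmds(d2, dims = 1, maxStarts = 5, seed = 1)$stress, 1e-6)
  expect_error(runNmds(d2, dims = 2), "dims \\+ 1")
})

test_that("PERMANOVA partitions variance and its p has the permutation floor", {
  # two tight, hugely separated groups: minimum attainable p = 1/(99+1)
  set.seed(9)
  m <- cbind(matrix(rpois(40, 5), 4, 10), matrix(rpois(40, 5) + 200, 4, 10))
  colnames(m) <- paste0("s", 1:20)
  rownames(m) <- paste0("t", 1:4)
  d <- brayCurtis(m)
  meta <- data.frame(grp = rep(c("a", "b"), each = 10))
  res <- runPermanova(d, meta, terms = "grp", nPerm = 99, seed = 4)
  expect_equal(res$p[res$term == "grp"], 0.01)
  expect_equal(sum(res$R2), 1, tolerance = 1e-9)

  # reproducible under a fixed seed
  res2 <- runPermanova(d, meta, terms = "grp", nPerm = 99, seed = 4)
  expect_identical(res$p, res2$p)

  # single-level terms are dropped with R2 = 0, p = 1
  meta$solo <- "only"
  expect_warning(
    res3 <- runPermanova(d, meta, terms = c("grp", "solo"), nPerm = 99,
                         seed = 4), "single-level")
  expect_equal(res3$R2[res3$term == "solo"], 0)
  expect_equal(res3$p[res3$term == "solo"], 1)
  expect_equal(sum(res3$R2), 1, tolerance = 1e-9)

  expect_error(runPermanova(dist(matrix(0, 4, 2)), meta[1:4, , drop = FALSE],
                            "grp"), "no variance")
})
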