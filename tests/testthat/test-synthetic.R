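test_that("the default design yields 105 bottles and 315 replicates", {
  p <- surveyDesign()
  expect_equal(unname(designSize(p)), c(105, 315))
  expect_equal(unname(designSize(surveyDesign(nReplicates = 1))[2]), 105)
  expect_equal(unname(designSize(surveyDesign(positions = c("Eg", "Ba")))[1]), 30)

  sim <- simulateStudy(surveyDesign(seed = 11))
  env <- environmentalSamples(sim$experiment)
  expect_equal(ncol(env), 315)
  expect_equal(length(unique(bottleId(env))), 105)
})

test_that("a fixed seed reproduces the simulation exactly", {
  a <- simulateStudy(surveyDesign(seed = 42))
  b <- simulateStudy(surveyDesign(seed = 42))
  expect_identical(counts(a$experiment), counts(b$experiment))
  expect_identical(a$truth$z, b$truth$z)
  c <- simulateStudy(surveyDesign(seed = 43))
  expect_false(identical(counts(a$experiment), counts(c$experiment)))
})

test_that("degenerate parameters are rejected", {
  expect_error(surveyDesign(nReplicates = 0))
  expect_error(surveyDesign(phyla = character()))
  expect_error(surveyDesign(p10True = 0.9))   # must stay below p11
  expect_error(surveyDesign(haloFactor = 0.5))
})

test_that("occupancy states follow psi and gate all reads when p10 = 0", {
  # no blooms, so occupancy is pure background Bernoulli(psi):
  # 105 bottles x 72 ASVs of draws, binomial CI around 0.5
  sim <- simulateStudy(surveyDesign(psiTrue = 0.5, bloomProb = 0, seed = 5))
  expect_lt(abs(mean(sim$truth$z) - 0.5), 0.02)

  sim0 <- simulateStudy(surveyDesign(p10True = 0, controlLeakRate = 0, seed = 6))
  env <- environmentalSamples(sim0$experiment)
  bt <- bottleId(env)
  cnt <- counts(env)[rownames(sim0$truth$z), ]
  for (b in sample(colnames(sim0$truth$z), 20)) {
    absent <- sim0$truth$z[, b] == 0
    expect_equal(sum(cnt[absent, bt == b]), 0)
  }
})

test_that("the degenerate no-effect design detects everything everywhere", {
  p <- surveyDesign(haloFactor = 1, p10True = 0, p11True = 1, psiTrue = 1,
                   siteCodes = c("CI", "NR"), months = "May", seed = 2)
  sim <- simulateStudy(p)
  expect_true(all(sim$truth$z == 1))
  # no Eg/Ba difference in latent composition beyond sampling noise
  tp <- sim$truth$trueProportions
  cd <- parseSampleName(colnames(environmentalSamples(sim$experiment)))
  dino <- grepl("Dinoflagellata", rownames(tp))
  eg <- colnames(tp)[grepl("_Eg_", colnames(tp))]
  ba <- colnames(tp)[grepl("_Ba_", colnames(tp))]
  expect_equal(mean(colSums(tp[dino, ba, drop = FALSE])),
               mean(colSums(tp[dino, eg, drop = FALSE])), tolerance = 1e-9)
})

test_that("the injected halo is recovered from realized proportions", {
  # many phyla so the focal phylum is a small share and closure effects
  # stay inside the 10% check
  p <- surveyDesign(phyla = c("Dinoflagellata", paste0("Phylum", 1:11)),
                   haloFactor = 2, psiTrue = 1, p11True = 1, p10True = 1e-6,
                   bloomProb = 0, readDepthMean = 1e5,
                   contaminationRate = 1e-9, controlLeakRate = 0, seed = 8)
  sim <- simulateStudy(p)
  env <- environmentalSamples(sim$experiment)
  cnt <- counts(env)
  prop <- sweep(cnt, 2, colSums(cnt), "/")
  dino <- rowData(env)$phylum == "Dinoflagellata"
  pos <- colData(env)$position
  ratio <- mean(colSums(prop[dino, pos == "Ba", drop = FALSE])) /
    mean(colSums(prop[dino, pos == "Eg", drop = FALSE]))
  expect_lt(abs(ratio - 2) / 2, 0.10)
})

test_that("positive controls are dominated by control tissue with leakage", {
  sim <- simulateStudy(surveyDesign(seed = 9))
  x <- sim$experiment
  pc <- counts(x)[, sampleClass(x) == "positive_control", drop = FALSE]
  ctl <- rowData(x)$control
  frac_ctl <- colSums(pc[ctl, ]) / colSums(pc)
  expect_true(all(frac_ctl > 0.99))
  expect_gt(sum(pc[!ctl, ]), 0)  # environmental leakage present
})

test_that("simulated studies write counts, taxonomy, truth and manifest", {
  sim <- simulateStudy(surveyDesign(siteCodes = "CI", months = "May", seed = 1))
  out <- tempfile()
  writeSimulatedStudy(sim, out)
  expect_true(all(file.exists(file.path(
    out, c("counts.tsv", "taxonomy.tsv", "ground_truth.tsv", "manifest.json")))))
  x <- readCountTable(file.path(out, "counts.tsv"),
                      taxonomyPath = file.path(out, "taxonomy.tsv"))
  common <- intersect(rownames(x), rownames(sim$experiment))
  expect_equal(counts(x)[common, colnames(x)],
               counts(sim$experiment)[common, colnames(x)])
})
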