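#' Parameters of the synthetic eDNA study generator
#'
#' Describes a replicated transect survey: sites x months x transect
#' positions, up to three PCR replicates per water bottle, multinomial read
#' sampling at negative-binomial depth, Bernoulli detection with
#' true-positive rate `p11True` and false-positive rate `p10True` over latent
#' per-bottle occupancy `psiTrue`, episodic bloom boosts, an optional
#' multiplicative depletion ("halo") of one phylum at all positions except
#' distant bare substrate, and sequencing controls with cross-contamination.
#'
#' @slot siteCodes character site codes (default the five study sites).
#' @slot months character sampling months.
#' @slot positions ordered transect positions; default Eg,1,3,6,10,15,Ba.
#' @slot nReplicates integer PCR replicates per bottle (1-3).
#' @slot phyla character phylum names.
#' @slot nTaxonUnitsPerPhylum,nAsvsPerTaxonUnit integers controlling richness.
#' @slot baseConcentration gamma shape of the Dirichlet-like base composition
#'   (smaller = more uneven).
#' @slot siteEffectSd,monthEffectSd log-scale SD of site/month abundance shifts.
#' @slot haloPhylum phylum receiving the depletion.
#' @slot haloFactor multiplicative depletion (>= 1; 1 = no halo) applied at
#'   `haloPositions` relative to Ba.
#' @slot haloPositions positions depleted; default Eg through 15 m (not Ba).
#' @slot bloomProb probability a (taxon unit, site-month) is in a
#'   high-abundance bloom state.
#' @slot bloomFactor multiplicative boost in the bloom state.
#' @slot readDepthMean,readDepthDispersion negative-binomial depth (mu, size).
#' @slot psiTrue,p11True,p10True occupancy, detection and false-positive
#'   probabilities in (0,1) with `p10True < p11True`.
#' @slot contaminationRate expected proportional leakage of environmental
#'   reads into positive controls.
#' @slot controlLeakRate expected proportional leakage of control-tissue reads
#'   into environmental samples (tag jumping).
#' @slot nPositiveControls,nNegativeControls numbers of control samples
#'   (sequenced in triplicate / singly per run respectively).
#' @slot seed integer RNG seed; a fixed seed gives byte-identical output.
#' @seealso [surveyDesign()], [simulateStudy()]
#' @export
setClass("SimulationParams", representation(
  siteCodes = "character", months = "character", positions = "character",
  nReplicates = "integer", phyla = "character",
  nTaxonUnitsPerPhylum = "integer", nAsvsPerTaxonUnit = "integer",
  baseConcentration = "numeric", siteEffectSd = "numeric",
  monthEffectSd = "numeric", haloPhylum = "character", haloFactor = "numeric",
  haloPositions = "character", bloomProb = "numeric", bloomFactor = "numeric",
  readDepthMean = "numeric", readDepthDispersion = "numeric",
  psiTrue = "numeric", p11True = "numeric", p10True = "numeric",
  contaminationRate = "numeric", controlLeakRate = "numeric",
  nPositiveControls = "integer", nNegativeControls = "integer",
  seed = "integer"))

setValidity("SimulationParams", function(object) {
  msg <- character()
  pr <- c(psi = object@psiTrue, p11 = object@p11True, p10 = object@p10True,
          bloom = object@bloomProb)
  if (any(pr < 0 | pr > 1))
    msg <- c(msg, "psiTrue, p11True, p10True, bloomProb must lie in [0,1]")
  if (object@p10True >= object@p11True)
    msg <- c(msg, "p10True must be < p11True")
  if (object@haloFactor < 1) msg <- c(msg, "haloFactor must be >= 1")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@nTaxonUnitsPerPhylum < 1L || object@nAsvsPerTaxonUnit < 1L ||
      !length(object@phyla))
    msg <- c(msg, "need >= 1 phylum, taxon unit and ASV")
  if (!length(object@siteCodes) || !length(object@months) ||
      !length(object@positions))
    msg <- c(msg, "need >= 1 site, month and position")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams:", length(object@siteCodes), "sites x",
      length(object@months), "months x", length(object@positions),
      "positions x", object@nReplicates, "replicates\n")
  cat("  ", length(object@phyla), " phyla, ",
      length(object@phyla) * object@nTaxonUnitsPerPhylum *
        object@nAsvsPerTaxonUnit, " ASVs; halo ", object@haloPhylum,
      " x1/", object@haloFactor, "\n", sep = "")
  cat(sprintf("  psi=%.2f p11=%.2f p10=%.2f depth~NB(%g,%g) seed=%d\n",
              object@psiTrue, object@p11True, object@p10True,
              object@readDepthMean, object@readDepthDispersion, object@seed))
})

#' Study-design defaults for the synthetic generator
#'
#' Returns a [SimulationParams-class] describing the survey layout: 5 Puget
#' Sound sites x 3 months x 7 transect positions (Eg, 1, 3, 6, 10, 15 m,
#' Ba) x 3 PCR replicates = 105 bottles / 315 environmental replicates (the
#' realized field study collected a subset of 84 bottles). Any slot can be
#' overridden by name.
#'
#' @param ... named overrides of [SimulationParams-class] slots.
#' @return a validated `SimulationParams`.
#' @examples
#' p <- surveyDesign(haloFactor = 10, seed = 7)
#' designSize(p)
#' @export
surveyDesign <- function(...) {
  p <- new("SimulationParams",
    siteCodes = c("CI", "NR", "PG", "SK", "WB"),
    months = c("May", "July", "August"),
    positions = .POSITIONS, nReplicates = 3L,
    phyla = c("Dinoflagellata", "Bacillariophyta", "Chlorophyta",
              "Annelida", "Arthropoda", "Mollusca"),
    nTaxonUnitsPerPhylum = 4L, nAsvsPerTaxonUnit = 3L,
    baseConcentration = 0.3, siteEffectSd = 0.5, monthEffectSd = 0.5,
    haloPhylum = "Dinoflagellata", haloFactor = 1,
    haloPositions = c("Eg", "1", "3", "6", "10", "15"),
    bloomProb = 0.13, bloomFactor = 25,
    readDepthMean = 2e4, readDepthDispersion = 5,
    psiTrue = 0.6, p11True = 0.85, p10True = 0.05,
    contaminationRate = 1e-3, controlLeakRate = 5e-4,
    nPositiveControls = 4L, nNegativeControls = 2L, seed = 1L)
  ov <- list(...)
  for (k in names(ov)) {
    if (!k %in% slotNames(p)) stop("unknown SimulationParams slot: ", k)
    cur <- slot(p, k)
    v <- ov[[k]]
    if (is.integer(cur)) v <- as.integer(v)
    slot(p, k) <- v
  }
  validObject(p)
  p
}

#' @describeIn surveyDesign numbers of bottles and environmental replicates
#'   implied by a design.
#' @param params a `SimulationParams`.
#' @export
designSize <- function(params) {
  b <- length(params@siteCodes) * length(params@months) *
    length(params@positions)
  c(bottles = b, replicates = b * params@nReplicates)
}

.kindForPosition <- function(pos)
  ifelse(pos == "Eg", "Eg", ifelse(pos == "Ba", "Ba", "Al"))

.posField <- function(pos) ifelse(pos == "Eg", "0", ifelse(pos == "Ba", "50", pos))

#' Simulate a replicated eDNA metabarcoding study
#'
#' Generates an ASV count table with the statistical structure the analysis
#' pipeline assumes, plus the latent ground truth, so each downstream stage
#' can be validated. Per bottle, log-normal site/month/taxon effects (plus
#' bloom boosts and the halo depletion) define true relative abundances; each
#' (ASV, bottle) is truly present with probability `psiTrue`, except that a
#' blooming taxon is forced present throughout its site-month (a bloom is in
#' the water column by construction; `psiTrue` governs background occupancy);
#' each PCR
#' replicate detects present ASVs with probability `p11True` and absent ones
#' with `p10True`; detected ASVs receive multinomial reads at a
#' negative-binomial depth. Positive controls are dominated by two control
#' tissues (kangaroo / ostrich) with proportional leakage of environmental
#' ASVs at `contaminationRate`, and control tissue leaks into environmental
#' samples at `controlLeakRate`.
#'
#' @param params a [SimulationParams-class], e.g. from [surveyDesign()].
#' @return list with elements `experiment` (an [EdnaExperiment-class]) and
#'   `truth` (list: `trueProportions` ASV x bottle matrix, `z` occupancy
#'   matrix, `blooms` data.frame, `haloPositions`, `params`).
#' @examples
#' sim <- simulateStudy(surveyDesign(seed = 1))
#' sim$experiment
#' @export
simulateStudy <- function(params = surveyDesign()) {
  validObject(params)
  set.seed(params@seed)
  units <- unlist(lapply(params@phyla, function(ph)
    paste0(ph, "_u", seq_len(params@nTaxonUnitsPerPhylum))))
  tax <- data.frame(
    asv_id = sprintf("ASV%04d", seq_len(length(units) * params@nAsvsPerTaxonUnit)),
    phylum = rep(rep(params@phyla, each = params@nTaxonUnitsPerPhylum),
                 each = params@nAsvsPerTaxonUnit),
    family = rep(units, each = params@nAsvsPerTaxonUnit),
    genus = NA_character_, control = FALSE, stringsAsFactors = FALSE)
  tax$taxon_unit <- tax$family
  ctrl <- data.frame(asv_id = c("ASV_CTRL_KANGAROO", "ASV_CTRL_OSTRICH"),
                     phylum = "Chordata", family = c("Macropodidae", "Struthionidae"),
                     genus = c("Macropus", "Struthio"), control = TRUE,
                     taxon_unit = c("Macropodidae Macropus",
                                    "Struthionidae Struthio"),
                     stringsAsFactors = FALSE)
  tax <- rbind(tax, ctrl)
  nEnvAsv <- sum(!tax$control)
  envIds <- tax$asv_id[!tax$control]

  # Dirichlet-like base composition and log-normal site/month effects
  base <- rgamma(nEnvAsv, shape = params@baseConcentration, rate = 1) + 1e-10
  siteEff <- matrix(rlnorm(nEnvAsv * length(params@siteCodes),
                           sdlog = params@siteEffectSd),
                    nEnvAsv, dimnames = list(envIds, params@siteCodes))
  monthEff <- matrix(rlnorm(nEnvAsv * length(params@months),
                            sdlog = params@monthEffectSd),
                     nEnvAsv, dimnames = list(envIds, params@months))

  # bloom states per (taxon unit, site, month)
  bl <- expand.grid(taxon_unit = units, site = params@siteCodes,
                    month = params@months, stringsAsFactors = FALSE)
  bl$bloom <- rbinom(nrow(bl), 1, params@bloomProb) == 1

  design <- expand.grid(position = params@positions, month = params@months,
                        site = params@siteCodes, stringsAsFactors = FALSE)
  design$bottle_id <- paste(design$site, design$position, design$month, sep = "_")
  nBottle <- nrow(design)

  trueProp <- matrix(0, nEnvAsv, nBottle, dimnames = list(envIds, design$bottle_id))
  haloAsv <- tax$phylum[!tax$control] == params@haloPhylum
  unitOf <- tax$taxon_unit[!tax$control]
  for (b in seq_len(nBottle)) {
    st <- design$site[b]; mo <- design$month[b]; po <- design$position[b]
    boom <- bl$bloom[bl$site == st & bl$month == mo]
    names(boom) <- bl$taxon_unit[bl$site == st & bl$month == mo]
    lam <- base * siteEff[, st] * monthEff[, mo] *
      ifelse(boom[unitOf], params@bloomFactor, 1)
    if (po %in% params@haloPositions)
      lam[haloAsv] <- lam[haloAsv] / params@haloFactor
    trueProp[, b] <- lam / sum(lam)
  }

  z <- matrix(rbinom(nEnvAsv * nBottle, 1, params@psiTrue), nEnvAsv, nBottle,
              dimnames = dimnames(trueProp))
  # a blooming taxon is present in the water column by construction: force
  # occupancy for member ASVs across that site-month's bottles (psi governs
  # background occupancy of non-blooming taxa)
  for (i in which(bl$bloom)) {
    asvs <- unitOf == bl$taxon_unit[i]
    bots <- design$site == bl$site[i] & design$month == bl$month[i]
    z[asvs, bots] <- 1L
  }

  runs <- paste0("run", 1 + (match(design$site, params@siteCodes) - 1) %% 4)
  allIds <- tax$asv_id
  cols <- list(); names_out <- character()
  for (b in seq_len(nBottle)) {
    for (r in seq_len(params@nReplicates)) {
      det <- rbinom(nEnvAsv, 1, ifelse(z[, b] == 1, params@p11True,
                                       params@p10True))
      w <- trueProp[, b] * det
      # control tissue leaks into field samples at a small fixed proportion
      wc <- rep(params@controlLeakRate * max(sum(w), 1e-12), 2)
      depth <- rnbinom(1, mu = params@readDepthMean,
                       size = params@readDepthDispersion)
      cnt <- if (sum(w) + sum(wc) > 0 && depth > 0)
        as.numeric(rmultinom(1, depth, c(w, wc))) else numeric(nEnvAsv + 2)
      nm <- paste(design$site[b], .kindForPosition(design$position[b]),
                  .posField(design$position[b]), design$month[b], r, runs[b],
                  sep = "_")
      cols[[length(cols) + 1L]] <- cnt
      names_out <- c(names_out, nm)
    }
  }

  # positive controls: alternately kangaroo / ostrich tissue, in triplicate,
  # with proportional leakage of environmental ASVs
  meanEnv <- rowMeans(trueProp)
  for (pc in seq_len(params@nPositiveControls)) {
    tissue <- if (pc %% 2 == 1) 1 else 2  # 1 kangaroo, 2 ostrich
    for (r in 1:3) {
      w <- params@contaminationRate * meanEnv / sum(meanEnv)
      wc <- c(0, 0); wc[tissue] <- 1 - params@contaminationRate
      depth <- rnbinom(1, mu = params@readDepthMean,
                       size = params@readDepthDispersion)
      cnt <- if (depth > 0) as.numeric(rmultinom(1, depth, c(w, wc)))
             else numeric(nEnvAsv + 2)
      cols[[length(cols) + 1L]] <- cnt
      names_out <- c(names_out, paste("POS", paste0("run", 1 + (pc - 1) %% 4),
                                      r, sep = "_"))
    }
  }
  for (nc in seq_len(params@nNegativeControls)) {
    depth <- rnbinom(1, mu = 20, size = 1)
    w <- c(params@contaminationRate * meanEnv / sum(meanEnv),
           rep(params@contaminationRate / 2, 2))
    cnt <- if (depth > 0) as.numeric(rmultinom(1, depth, w))
           else numeric(nEnvAsv + 2)
    cols[[length(cols) + 1L]] <- cnt
    names_out <- c(names_out, paste("NEG", paste0("run", 1 + (nc - 1) %% 4),
                                    1, sep = "_"))
  }

  m <- do.call(cbind, cols)
  dimnames(m) <- list(allIds, names_out)
  ee <- EdnaExperiment(m, taxonomy = tax)
  list(experiment = ee,
       truth = list(trueProportions = trueProp, z = z, blooms = bl,
                    haloPositions = params@haloPositions, params = params))
}

#' Write a simulated study to disk
#'
#' Writes counts (long TSV), taxonomy (TSV), ground-truth occupancy and
#' proportions (TSV) and a JSON manifest of the generator parameters.
#'
#' @param sim result of [simulateStudy()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
writeSimulatedStudy <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeCountTable(sim$experiment, file.path(outdir, "counts.tsv"))
  tx <- as.data.frame(rowData(sim$experiment))
  tx <- data.frame(asv_id = rownames(tx), tx, row.names = NULL)
  write.table(tx, file.path(outdir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  zt <- data.frame(asv_id = rep(rownames(sim$truth$z), ncol(sim$truth$z)),
                   bottle_id = rep(colnames(sim$truth$z),
                                   each = nrow(sim$truth$z)),
                   z = as.integer(sim$truth$z),
                   true_proportion = as.numeric(sim$truth$trueProportions))
  write.table(zt, file.path(outdir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  p <- sim$truth$params
  pl <- lapply(setNames(slotNames(p), slotNames(p)), function(s) slot(p, s))
  jsonlite::write_json(list(generator = "simulateStudy", params = pl,
                            note = paste("contaminationRate and controlLeakRate",
                                         "are order-of-magnitude defaults")),
                       file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
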