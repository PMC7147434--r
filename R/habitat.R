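#' Relative eDNA abundance between eelgrass and bare substrate
#'
#' For each phylum and each site-month with samples at both transect extremes,
#' computes the mean phylum-level eDNA index over eelgrass (Eg) replicates
#' minus the mean over bare-substrate (Ba) replicates. Positive values denote
#' higher abundance in eelgrass, negative values higher abundance over bare
#' substrate. Site-months missing either extreme are skipped.
#'
#' @param x an [EdnaExperiment-class].
#' @param grouping taxon level of the index (default `"phylum"`).
#' @return data.frame: `taxon`, `site`, `month`, `eg_mean`, `ba_mean`,
#'   `value` (in `[-1, 1]`).
#' @export
relativeAbundance <- function(x, grouping = "phylum") {
  env <- environmentalSamples(x)
  idx <- ednaIndex(env, grouping = grouping)
  cd <- colData(env)
  key <- paste(cd$site, cd$month, sep = "_")
  out <- list()
  for (sm in unique(key)) {
    eg <- key == sm & cd$position == "Eg"
    ba <- key == sm & cd$position == "Ba"
    if (!any(eg) || !any(ba)) next
    egm <- rowMeans(idx[, eg, drop = FALSE])
    bam <- rowMeans(idx[, ba, drop = FALSE])
    parts <- strsplit(sm, "_", fixed = TRUE)[[1]]
    out[[sm]] <- data.frame(taxon = rownames(idx), site = parts[1],
                            month = parts[2], eg_mean = egm, ba_mean = bam,
                            value = egm - bam, row.names = NULL,
                            stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no site-month has both Eg and Ba samples")
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Two-sided Wilcoxon signed-rank test of paired differences
#'
#' Exact null enumeration when the differences are few and untied (the
#' `wilcox.test` exact path); tie-corrected normal approximation otherwise.
#' All-zero differences give p = 1.
#'
#' @param diffs numeric vector of paired differences.
#' @return two-sided p-value.
#' @examples
#' signedRankTest(rep(0.1, 8) + (1:8) / 100)  # all positive, n = 8: p = 2/256
#' @export
signedRankTest <- function(diffs) {
  d <- diffs[!is.na(diffs)]
  if (!length(d) || all(d == 0)) return(1)
  suppressWarnings(wilcox.test(d, mu = 0, correct = FALSE)$p.value)
}

.signedRankP <- signedRankTest

#' Phylum habitat-association tests
#'
#' Paired Wilcoxon signed-rank test per taxon of the eelgrass-vs-bare measure
#' from [relativeAbundance()] (pairing on site-month), with Bonferroni
#' correction over the number of taxa actually tested. Taxa with fewer than
#' two site-month pairs are not testable and raise an error if none remain.
#'
#' @param measures data.frame from [relativeAbundance()].
#' @param minPairs minimum site-month pairs per taxon (default 2).
#' @return data.frame: `taxon`, `n_pairs`, `mean_measure`, `p_raw`, `p_adj`
#'   (`= min(1, m * p_raw)`), ordered by `p_adj`.
#' @export
habitatAssociation <- function(measures, minPairs = 2) {
  sp <- split(measures$value, measures$taxon)
  sp <- sp[vapply(sp, length, 0L) >= minPairs]
  if (!length(sp))
    stop("no taxon has >= ", minPairs, " site-month pairs")
  out <- data.frame(
    taxon = names(sp),
    n_pairs = vapply(sp, length, 0L),
    mean_measure = vapply(sp, mean, 0),
    p_raw = vapply(sp, .signedRankP, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  out$p_adj <- p.adjust(out$p_raw, method = "bonferroni")
  out[order(out$p_adj, out$p_raw), ]
}
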