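# Bray-Curtis dissimilarity between two non-negative vectors.
.bc2 <- function(a, b) {
  s <- sum(a) + sum(b)
  if (s == 0) return(NA_real_)
  sum(abs(a - b)) / s
}

#' Bray-Curtis distance of each PCR replicate to its bottle centroid
#'
#' Computes eDNA abundance indices per replicate ([ednaIndex()] at ASV level),
#' then for every bottle the centroid (arithmetic mean of its replicates'
#' index vectors) and each replicate's Bray-Curtis dissimilarity to it.
#' Singleton bottles get distance 0 by convention; replicates with zero total
#' reads have undefined distance (`NA`) and are treated as outliers
#' downstream.
#'
#' @param x an [EdnaExperiment-class].
#' @return data.frame with `sample_name`, `bottle_id`, `distance`.
#' @export
replicateDistances <- function(x) {
  env <- environmentalSamples(x)
  idx <- ednaIndex(env, grouping = "asv")
  bt <- bottleId(env)
  out <- data.frame(sample_name = colnames(env), bottle_id = bt,
                    distance = NA_real_, stringsAsFactors = FALSE)
  zero_total <- colSums(counts(env)) == 0
  for (b in unique(bt)) {
    j <- which(bt == b)
    if (length(j) == 1) { out$distance[j] <- 0; next }
    centroid <- rowMeans(idx[, j, drop = FALSE])
    out$distance[j] <- vapply(j, function(k) .bc2(idx[, k], centroid), 0)
  }
  out$distance[zero_total] <- NA_real_
  out
}

#' Flag outlier replicates by pooled distance quantile
#'
#' The 95% rule is implemented as a one-sided empirical cutoff: the pooled
#' `1 - alpha` quantile of centroid distances across the whole dataset
#' (pooling borrows strength across bottles that have only 3 replicates
#' each). Replicates strictly above the cutoff, or with undefined distance,
#' are flagged. With fewer than 10 finite distances a normal approximation
#' (`mean + z[1-alpha] * sd`) is used, with a warning.
#'
#' @param distances data.frame from [replicateDistances()].
#' @param alpha tail probability (default 0.05).
#' @return the input data.frame with logical `flagged` and an attribute
#'   `cutoff`.
#' @export
flagOutlierReplicates <- function(distances, alpha = 0.05) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0,1]")
  d <- distances$distance
  fin <- d[!is.na(d)]
  if (length(fin) >= 10) {
    cutoff <- as.numeric(quantile(fin, 1 - alpha, type = 7))
  } else {
    warning("fewer than 10 distances; using normal-approximation cutoff")
    cutoff <- mean(fin) + qnorm(1 - alpha) * (if (length(fin) > 1) sd(fin) else 0)
  }
  distances$flagged <- is.na(d) | d > cutoff
  attr(distances, "cutoff") <- cutoff
  distances
}

#' Apply replicate quality control
#'
#' Flags and removes outlier technical replicates in a single pass (bottle
#' centroids are not recomputed after discards). Bottles may drop to zero
#' surviving replicates. The per-bottle survivor distribution is recorded in
#' `metadata(x)$qc_survivors`.
#'
#' @param x an [EdnaExperiment-class].
#' @param alpha tail probability for [flagOutlierReplicates()].
#' @return filtered `EdnaExperiment` (provenance gains `"qc-filtered"`).
#' @export
applyReplicateQc <- function(x, alpha = 0.05) {
  dist <- replicateDistances(x)
  dist <- flagOutlierReplicates(dist, alpha)
  drop <- colnames(x) %in% dist$sample_name[dist$flagged]
  surv <- table(factor(
    vapply(split(!dist$flagged, dist$bottle_id), sum, 0L),
    levels = 0:max(table(dist$bottle_id))))
  x <- x[, !drop]
  provenance(x) <- c(provenance(x), "qc-filtered")
  metadata(x)$qc_survivors <- surv
  metadata(x)$qc_distances <- dist
  x
}
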