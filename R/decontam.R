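#' Maximum proportional representation in positive controls
#'
#' For every ASV, computes its proportional representation within each
#' positive-control replicate and takes the maximum across controls. This
#' profile estimates the fraction of a sample's reads that can be attributed
#' to cross-sample contamination (tag jumping / index hopping) and is
#' subtracted from field samples by [subtractContamination()].
#'
#' Control replicates with zero total reads are excluded; if none have reads
#' an error asks the caller to skip the stage explicitly.
#'
#' @param x an [EdnaExperiment-class] containing positive-control samples.
#' @return named numeric vector over all ASVs, values in `[0, 1]` (0 for ASVs
#'   absent from every control).
#' @export
maxControlProportion <- function(x) {
  pc <- counts(x)[, sampleClass(x) == "positive_control", drop = FALSE]
  if (ncol(pc) == 0)
    stop("no positive-control samples present; skip the decontamination ",
         "stage explicitly if none were sequenced")
  tot <- colSums(pc)
  pc <- pc[, tot > 0, drop = FALSE]
  if (ncol(pc) == 0)
    stop("all positive controls have zero reads; skip the decontamination ",
         "stage explicitly")
  prop <- sweep(pc, 2, colSums(pc), "/")
  apply(prop, 1, max)
}

#' Subtract contamination from field samples
#'
#' In each environmental replicate, every ASV's within-replicate proportion is
#' reduced by its control profile value, floored at zero, and mapped back to
#' counts at the replicate's original read total (so the low-read filter stays
#' meaningful; counts may become fractional). Remaining proportions are not
#' renormalized here — the eDNA index renormalizes later. ASVs assigned to the
#' positive-control tissues themselves (`rowData(x)$control`) are removed
#' entirely.
#'
#' @param x an [EdnaExperiment-class].
#' @param profile named numeric from [maxControlProportion()].
#' @param removeControlTaxa drop control-tissue ASVs (default `TRUE`).
#' @return the decontaminated `EdnaExperiment` (provenance gains
#'   `"decontaminated"`).
#' @export
subtractContamination <- function(x, profile = maxControlProportion(x),
                                  removeControlTaxa = TRUE) {
  m <- counts(x)
  prof <- setNames(numeric(nrow(m)), rownames(m))
  prof[intersect(names(profile), rownames(m))] <-
    profile[intersect(names(profile), rownames(m))]
  env <- sampleClass(x) == "environmental"
  for (j in which(env)) {
    tot <- sum(m[, j])
    if (tot <= 0) next
    adj <- pmax(m[, j] / tot - prof, 0)
    m[, j] <- adj * tot
  }
  assay(x, "counts") <- m
  if (removeControlTaxa && any(rowData(x)$control))
    x <- x[!rowData(x)$control, ]
  provenance(x) <- c(provenance(x), "decontaminated")
  validObject(x)
  x
}

#' Drop PCR replicates with extremely low read counts
#'
#' @param x an [EdnaExperiment-class].
#' @param minReads environmental replicates with total reads below this are
#'   removed (default 1000; the threshold is a config parameter because
#'   "extremely low" depends on the run).
#' @return filtered `EdnaExperiment`; removals are reported via `message()`
#'   and recorded in `metadata(x)$low_read_removed`.
#' @export
dropLowReadReplicates <- function(x, minReads = 1000) {
  if (minReads < 0) stop("minReads must be >= 0")
  tot <- colSums(counts(x))
  drop <- sampleClass(x) == "environmental" & tot < minReads
  if (any(drop)) {
    message("dropping ", sum(drop), " low-read replicate(s): ",
            paste(sprintf("%s (%.0f reads)", colnames(x)[drop], tot[drop]),
                  collapse = ", "))
    removed <- data.frame(sample_name = colnames(x)[drop],
                          total_reads = unname(tot[drop]))
  } else removed <- data.frame(sample_name = character(),
                               total_reads = numeric())
  x <- x[, !drop]
  if (!any(sampleClass(x) == "environmental"))
    warning("no environmental replicates survive the low-read filter")
  metadata(x)$low_read_removed <- removed
  x
}
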