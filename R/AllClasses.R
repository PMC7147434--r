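#' @import methods
#' @import SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom stats dbinom kruskal.test p.adjust quantile rbinom rgamma
#'   rlnorm rmultinom rnbinom runif sd setNames var wilcox.test qnorm rnorm
#' @importFrom utils read.delim write.table packageVersion head
#' @importFrom mclust Mclust mclustBIC
NULL

# Required per-sample metadata columns for an EdnaExperiment.
.META_COLS <- c("site", "transect_kind", "position", "distance_m", "month",
                "bottle_id", "replicate_index", "run_id", "sample_class")

.SAMPLE_CLASSES <- c("environmental", "positive_control", "negative_control")

#' Container for a replicated eDNA metabarcoding count table
#'
#' `EdnaExperiment` extends [SummarizedExperiment::SummarizedExperiment] with
#' the structure of a replicated eDNA metabarcoding survey: the `"counts"`
#' assay holds ASV-by-PCR-replicate read counts, `colData` carries the sample
#' design (site, month, transect position, bottle, replicate index, run, and
#' whether a sample is environmental or a sequencing control), and `rowData`
#' carries the taxonomy assigned to each ASV. A provenance vector in
#' `metadata()` records which processing stages (decontamination, occupancy
#' filtering, replicate QC) have been applied.
#'
#' Counts must be non-negative; they are integer-valued in a raw table but may
#' become fractional after proportional decontamination.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [EdnaExperiment()], [readCountTable()], [simulateStudy()]
#' @export
setClass("EdnaExperiment", contains = "SummarizedExperiment")

setValidity("EdnaExperiment", function(object) {
  msg <- character()
  if (!"counts" %in% assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- assay(object, "counts")
    if (anyNA(m)) msg <- c(msg, "counts must not contain NA")
    else if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    else if (identical(provenance(object), "raw") &&
             any(abs(m - round(m)) > 1e-8))
      msg <- c(msg, "raw counts must be integer-valued")
  }
  missing_cols <- setdiff(.META_COLS, colnames(colData(object)))
  if (length(missing_cols))
    msg <- c(msg, paste("missing colData columns:",
                        paste(missing_cols, collapse = ", ")))
  else {
    cls <- as.character(colData(object)$sample_class)
    if (!all(cls %in% .SAMPLE_CLASSES))
      msg <- c(msg, "sample_class must be environmental/positive_control/negative_control")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicated sample names")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicated ASV ids")
  if (length(msg)) msg else TRUE
})

#' Construct an EdnaExperiment
#'
#' @param counts numeric matrix, ASVs in rows, PCR replicates in columns.
#'   Column names are sample names; row names are ASV ids.
#' @param sampleData `DataFrame`/`data.frame` of per-sample metadata with the
#'   columns produced by [parseSampleName()]. If `NULL`, metadata is parsed
#'   from the column names using `dialect`.
#' @param taxonomy optional `data.frame` keyed by `asv_id` (see
#'   [readTaxonomy()]); stored in `rowData`.
#' @param provenance character vector of processing stages applied so far.
#' @param dialect sample-name dialect, see [defaultDialect()].
#' @return an [EdnaExperiment-class] object.
#' @examples
#' m <- matrix(c(5L, 5L, 5L, 5L), 2, 2,
#'             dimnames = list(c("ASV1", "ASV2"),
#'                             c("CI_Eg_0_May_1_run1", "CI_Eg_0_May_2_run1")))
#' ee <- EdnaExperiment(m)
#' @export
EdnaExperiment <- function(counts, sampleData = NULL, taxonomy = NULL,
                           provenance = "raw", dialect = defaultDialect()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have ASV row names and sample column names")
  if (is.null(sampleData))
    sampleData <- parseSampleName(colnames(counts), dialect)
  sampleData <- DataFrame(sampleData)
  rownames(sampleData) <- colnames(counts)
  rd <- DataFrame(row.names = rownames(counts))
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    idx <- match(rownames(counts), taxonomy$asv_id)
    if (anyNA(idx))
      stop("taxonomy is missing ASVs: ",
           paste(head(rownames(counts)[is.na(idx)]), collapse = ", "))
    rd <- DataFrame(taxonomy[idx, setdiff(colnames(taxonomy), "asv_id"),
                             drop = FALSE], row.names = rownames(counts))
  }
  if (!"control" %in% colnames(rd)) rd$control <- FALSE
  se <- SummarizedExperiment(assays = list(counts = counts),
                             colData = sampleData, rowData = rd)
  out <- new("EdnaExperiment", se)
  metadata(out)$provenance <- provenance
  out
}

#' @describeIn EdnaExperiment processing stages applied so far.
#' @param x,object an `EdnaExperiment`.
#' @export
provenance <- function(x) {
  p <- metadata(x)$provenance
  if (is.null(p)) "raw" else p
}

#' @describeIn EdnaExperiment append a stage to the provenance record.
#' @param value character stage label.
#' @export
`provenance<-` <- function(x, value) {
  metadata(x)$provenance <- value
  x
}

#' @describeIn EdnaExperiment the count matrix.
#' @export
setGeneric("counts", function(object, ...) standardGeneric("counts"))

#' @rdname EdnaExperiment
#' @param ... unused.
#' @export
setMethod("counts", "EdnaExperiment", function(object, ...)
  assay(object, "counts"))

#' @describeIn EdnaExperiment sample class (environmental / controls) per column.
#' @export
sampleClass <- function(x) as.character(colData(x)$sample_class)

#' @describeIn EdnaExperiment bottle identifier per column.
#' @export
bottleId <- function(x) as.character(colData(x)$bottle_id)

#' @describeIn EdnaExperiment subset to environmental replicates.
#' @export
environmentalSamples <- function(x) x[, sampleClass(x) == "environmental"]

setMethod("show", "EdnaExperiment", function(object) {
  cls <- table(factor(sampleClass(object), levels = .SAMPLE_CLASSES))
  cat("EdnaExperiment:", nrow(object), "ASVs x", ncol(object), "replicates\n")
  cat("  environmental:", cls[["environmental"]],
      "| positive controls:", cls[["positive_control"]],
      "| negative controls:", cls[["negative_control"]], "\n")
  env <- colData(object)[sampleClass(object) == "environmental", , drop = FALSE]
  if (nrow(env))
    cat("  bottles:", length(unique(env$bottle_id)),
        "| sites:", paste(sort(unique(as.character(env$site))), collapse = ","),
        "| months:", paste(unique(as.character(env$month)), collapse = ","), "\n")
  cat("  provenance:", paste(provenance(object), collapse = " -> "), "\n")
})

#' Posterior of the Bayesian occupancy model for one ASV
#'
#' Holds Markov-chain draws of the commonness `psi`, the per-replicate
#' true-positive detection rate `p11` and the false-positive rate `p10`
#' (constrained `p10 < p11`), together with posterior summaries and split-R̂
#' convergence diagnostics.
#'
#' @slot asv character ASV id (may be `NA` for ad hoc fits).
#' @slot draws numeric matrix of post-burn-in draws, columns `psi, p11, p10`.
#' @slot summary data.frame of posterior mean and 95% credible bounds per
#'   parameter, plus split-R̂.
#' @slot nChains integer number of chains concatenated in `draws`.
#' @slot converged logical, `TRUE` when all split-R̂ < 1.05.
#' @export
setClass("OccupancyPosterior",
         representation(asv = "character", draws = "matrix",
                        summary = "data.frame", nChains = "integer",
                        converged = "logical"))

setValidity("OccupancyPosterior", function(object) {
  d <- object@draws
  if (!all(colnames(d) == c("psi", "p11", "p10")))
    return("draws must have columns psi, p11, p10")
  if (any(d <= 0 | d >= 1)) return("draws must lie in (0,1)")
  if (any(d[, "p10"] >= d[, "p11"])) return("constraint p10 < p11 violated")
  TRUE
})

setMethod("show", "OccupancyPosterior", function(object) {
  cat("OccupancyPosterior", if (!is.na(object@asv)) paste0("[", object@asv, "]"),
      "-", nrow(object@draws), "draws,", object@nChains, "chains",
      if (!object@converged) "(NOT converged)" else "(converged)", "\n")
  print(object@summary, digits = 3)
})

#' Result of the two-group halo analysis
#'
#' Classification of transect positions into two groups from a univariate
#' Gaussian mixture over high-abundance eDNA index values, with the rank-sum
#' test of group separation and the between/total sum-of-squares ratio.
#'
#' @slot positionGroups named character; `"A"`/`"B"` label per transect
#'   position (A is the group containing the most shoreward position present).
#' @slot values data.frame with columns `position`, `value`, `group`.
#' @slot modelName mclust covariance model chosen by BIC (`"E"` or `"V"`), or
#'   `"degenerate"` when all values coincide.
#' @slot componentMeans numeric means of the two mixture components (A, B).
#' @slot varianceExplained between-group SS / total SS of the values.
#' @slot rankSumP two-sided Wilcoxon rank-sum p-value comparing group values.
#' @slot degenerate logical, `TRUE` if a single effective component was found.
#' @export
setClass("HaloResult",
         representation(positionGroups = "character", values = "data.frame",
                        modelName = "character", componentMeans = "numeric",
                        varianceExplained = "numeric", rankSumP = "numeric",
                        degenerate = "logical"))

setValidity("HaloResult", function(object) {
  if (!object@degenerate && !all(object@positionGroups %in% c("A", "B")))
    return("position groups must be labelled A/B")
  ve <- object@varianceExplained
  if (!object@degenerate && !is.na(ve) && (ve < -1e-9 || ve > 1 + 1e-9))
    return("varianceExplained must lie in [0,1]")
  TRUE
})

setMethod("show", "HaloResult", function(object) {
  if (object@degenerate) {
    cat("HaloResult: degenerate (single effective component)\n")
    return(invisible(NULL))
  }
  a <- names(object@positionGroups)[object@positionGroups == "A"]
  b <- names(object@positionGroups)[object@positionGroups == "B"]
  cat("HaloResult (model ", object@modelName, "):\n", sep = "")
  cat("  group A:", paste(a, collapse = ", "), "\n")
  cat("  group B:", paste(b, collapse = ", "), "\n")
  cat(sprintf("  between/total SS = %.3f, rank-sum p = %.4g\n",
              object@varianceExplained, object@rankSumP))
})
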