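#' eDNA abundance index (Wisconsin double standardization)
#'
#' Two-step transform: counts are first normalized to proportions within each
#' technical replicate, then each taxon's proportions are divided by that
#' taxon's maximum across all replicates, so every non-zero taxon reaches 1
#' somewhere. The index corrects both for read-depth differences among
#' replicates and amplification-efficiency differences among sequences, and
#' equals the Wisconsin double standardization of community ecology.
#'
#' For an `EdnaExperiment`, counts can be aggregated (summed) to `taxon_unit`
#' or `phylum` before indexing, and only environmental replicates are used.
#'
#' @param x a non-negative taxa-by-replicates matrix, or an
#'   [EdnaExperiment-class].
#' @param grouping for the `EdnaExperiment` method: `"asv"`, `"taxon_unit"`,
#'   or `"phylum"`.
#' @param ... passed between methods.
#' @return matrix of indices in `[0, 1]`, same orientation as the input
#'   (rows = taxa at the requested grouping).
#' @examples
#' m <- matrix(c(10, 30, 90, 70), 2, 2,
#'             dimnames = list(c("t1", "t2"), c("r1", "r2")))
#' ednaIndex(m)
#' @export
setGeneric("ednaIndex", function(x, ...) standardGeneric("ednaIndex"))

#' @rdname ednaIndex
#' @export
setMethod("ednaIndex", "matrix", function(x, ...) {
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- colSums(x)
  if (any(tot == 0))
    warning(sum(tot == 0), " replicate(s) with zero total reads; ",
            "their proportions are set to 0")
  prop <- sweep(x, 2, ifelse(tot > 0, tot, 1), "/")
  mx <- apply(prop, 1, max)
  if (any(mx == 0))
    warning(sum(mx == 0), " all-zero taxa left at index 0")
  sweep(prop, 1, ifelse(mx > 0, mx, 1), "/")
})

#' @rdname ednaIndex
#' @export
setMethod("ednaIndex", "EdnaExperiment", function(
    x, grouping = c("asv", "taxon_unit", "phylum"), ...) {
  grouping <- match.arg(grouping)
  env <- environmentalSamples(x)
  m <- counts(env)
  if (grouping != "asv") {
    g <- as.character(rowData(env)[[grouping]])
    if (is.null(g) || all(is.na(g)))
      stop("rowData lacks a usable '", grouping, "' column")
    g[is.na(g)] <- "unassigned"
    m <- rowsum(m, g)
  }
  ednaIndex(m)
})

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` between all pairs of columns
#' (replicates/samples). Pairs in which both vectors are all zero get
#' distance 0, with a warning.
#'
#' @param m non-negative taxa-by-samples matrix (e.g. an eDNA index matrix).
#' @return a `dist` object over columns, with `attr(, "metric") = "bray"`.
#' @export
brayCurtis <- function(m) {
  if (any(m < 0)) stop("Bray-Curtis requires non-negative entries")
  d <- suppressWarnings(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s); their distance is set to 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- "bray"
  d
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Thin wrapper over [vegan::metaMDS()] (Kruskal stress-1, monotone
#' regression, best of up to `maxStarts` random starts) with deterministic
#' seeding.
#'
#' @param d a `dist` object.
#' @param dims embedding dimension (default 2).
#' @param maxStarts maximum random starts (default 100).
#' @param seed RNG seed.
#' @return list: `points` (coordinates), `stress` (Kruskal stress-1, in
#'   [0,1]), `converged`.
#' @export
runNmds <- function(d, dims = 2, maxStarts = 100, seed = 1) {
  n <- attr(d, "Size")
  if (is.null(n) || n < dims + 1) stop("need at least dims + 1 points")
  set.seed(seed)
  fit <- suppressWarnings(suppressMessages(
    vegan::metaMDS(d, k = dims, trymax = maxStarts, trace = 0,
                   autotransform = FALSE, wascores = FALSE)))
  list(points = fit$points, stress = fit$stress,
       converged = isTRUE(fit$converged) || fit$stress < 1e-6)
}

#' PERMANOVA variance partitioning of a distance matrix
#'
#' Sequential (Type-I) sums of squares from the Gower-centered distance
#' matrix, pseudo-F per term, and permutation p-values
#' `(#{F* >= F} + 1) / (nPerm + 1)` under free row permutation, via
#' [vegan::adonis2()]. Factors with a single level are dropped from the model
#' and reported with `R2 = 0`, `p = 1` and a warning. Term order matters and
#' is taken as given.
#'
#' @param d a `dist` object.
#' @param data data.frame of factors aligned with the rows of `d`.
#' @param terms character vector of column names of `data`, in model order.
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return data.frame: one row per term plus `Residual`, with `df`, `SumOfSqs`,
#'   `R2`, `F`, `p`. Term plus residual R2 sum to 1.
#' @export
runPermanova <- function(d, data, terms, nPerm = 999, seed = 1) {
  if (max(d) == 0) stop("distance matrix has no variance")
  if (nPerm < 1) stop("nPerm must be >= 1")
  data <- as.data.frame(data)[, terms, drop = FALSE]
  for (t in terms) data[[t]] <- factor(as.character(data[[t]]))
  degenerate <- vapply(terms, function(t) nlevels(data[[t]]) < 2, TRUE)
  if (any(degenerate))
    warning("single-level term(s) dropped: ",
            paste(terms[degenerate], collapse = ", "))
  kept <- terms[!degenerate]
  if (!length(kept)) stop("no term has more than one level")
  form <- stats::as.formula(paste("d ~", paste(kept, collapse = " + ")))
  set.seed(seed)
  fit <- vegan::adonis2(form, data = data, permutations = nPerm, by = "terms")
  res <- data.frame(term = rownames(fit), df = fit$Df, SumOfSqs = fit$SumOfSqs,
                    R2 = fit$R2, F = fit$F, p = fit$`Pr(>F)`,
                    row.names = NULL)
  res <- res[res$term != "Total", ]
  if (any(degenerate)) {
    deg <- data.frame(term = terms[degenerate], df = 0, SumOfSqs = 0, R2 = 0,
                      F = NA_real_, p = 1)
    res <- rbind(res[res$term != "Residual", ], deg,
                 res[res$term == "Residual", ])
  }
  res
}
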