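#' Per-transect abundance events for a set of taxa
#'
#' One event per (taxon unit, site-month) in which the taxon occurs: the
#' grand mean of its eDNA indices over all of that transect's technical
#' replicates. Events feed the high/low-abundance split ([splitHighLow()]).
#'
#' @param x an [EdnaExperiment-class].
#' @param phylum restrict to taxon units of this phylum (default
#'   `"Dinoflagellata"`); ignored when `taxa` is given.
#' @param taxa explicit taxon units to use.
#' @param grouping index grouping (default `"taxon_unit"`).
#' @return data.frame: `taxon_unit`, `site`, `month`, `mean_index`.
#' @export
transectEvents <- function(x, phylum = "Dinoflagellata", taxa = NULL,
                           grouping = "taxon_unit") {
  env <- environmentalSamples(x)
  idx <- ednaIndex(env, grouping = grouping)
  if (is.null(taxa)) {
    rd <- rowData(env)
    taxa <- unique(as.character(rd[[grouping]][rd$phylum %in% phylum]))
  }
  taxa <- intersect(taxa, rownames(idx))
  if (!length(taxa)) {
    warning("no requested taxa present in the index")
    return(data.frame(taxon_unit = character(), site = character(),
                      month = character(), mean_index = numeric()))
  }
  cd <- colData(env)
  key <- paste(cd$site, cd$month, sep = "_")
  out <- list()
  for (sm in unique(key)) {
    j <- key == sm
    mi <- rowMeans(idx[taxa, j, drop = FALSE])
    parts <- strsplit(sm, "_", fixed = TRUE)[[1]]
    keep <- mi > 0
    if (!any(keep)) next
    out[[sm]] <- data.frame(taxon_unit = taxa[keep], site = parts[1],
                            month = parts[2], mean_index = mi[keep],
                            row.names = NULL, stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Exact two-cluster split of one-dimensional values
#'
#' Globally optimal two-cluster k-means of a numeric vector: because the
#' optimal 1-D two-cluster partition is contiguous in sorted order, all n-1
#' cut points of the sorted values are scored by within-cluster sum of
#' squares and the minimum taken. Deterministic — no random initialization.
#'
#' @param values numeric vector (>= 2 distinct values required).
#' @return list: `class` (factor `"high"`/`"low"` aligned with `values`;
#'   high is the cluster with the larger center), `centers`,
#'   `varianceExplained` (between-cluster SS / total SS).
#' @examples
#' splitHighLow(c(0.01, 0.02, 0.90))$class
#' @export
splitHighLow <- function(values) {
  if (is.data.frame(values)) values <- values$mean_index
  n <- length(values)
  if (n < 2 || length(unique(values)) < 2)
    stop("need >= 2 distinct values to split")
  o <- order(values)
  s <- values[o]
  wss_best <- Inf; cut_best <- 1L
  for (cut in seq_len(n - 1)) {
    lo <- s[seq_len(cut)]; hi <- s[(cut + 1):n]
    wss <- sum((lo - mean(lo))^2) + sum((hi - mean(hi))^2)
    if (wss < wss_best) { wss_best <- wss; cut_best <- cut }
  }
  cls <- rep("low", n)
  cls[o[(cut_best + 1):n]] <- "high"
  tss <- sum((values - mean(values))^2)
  list(class = factor(cls, levels = c("low", "high")),
       centers = c(low = mean(s[seq_len(cut_best)]),
                   high = mean(s[(cut_best + 1):n])),
       varianceExplained = 1 - wss_best / tss)
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact null distribution when both groups are small and untied; otherwise
#' a tie-corrected normal approximation (no continuity correction, so
#' identical groups give p = 1).
#'
#' @param a,b numeric value vectors for the two groups.
#' @return two-sided p-value.
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.1
#' @export
rankSumTest <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  ties <- anyDuplicated(c(a, b)) > 0
  ex <- !ties && min(length(a), length(b)) <= 10 && max(length(a), length(b)) <= 50
  suppressWarnings(
    wilcox.test(a, b, exact = ex, correct = FALSE)$p.value)
}

#' Two-group Gaussian mixture classification of transect positions
#'
#' Pools high-abundance eDNA index values across transects, fits univariate
#' two-component Gaussian mixtures (equal- and unequal-variance models, the
#' better chosen by BIC, via [mclust::Mclust()]), assigns each transect
#' position to the component holding the majority of its values' posterior
#' memberships, and tests group separation with a Wilcoxon rank-sum test.
#' Group `"A"` is the component assigned to the most shoreward position
#' present (the eelgrass side); `"B"` the other.
#'
#' @param values data.frame with columns `position` (in Eg,1,3,6,10,15,Ba)
#'   and `value` (eDNA index), typically from [haloPositionValues()].
#' @param seed RNG seed (the fit itself is deterministic; the seed guards
#'   mclust internals).
#' @return a [HaloResult-class].
#' @export
gmmTwoGroup <- function(values, seed = 1) {
  stopifnot(all(c("position", "value") %in% colnames(values)))
  v <- values$value
  if (length(v) < 4) stop("need at least 4 values for a two-group mixture")
  pos <- as.character(values$position)
  if (length(unique(pos)) < 2) stop("need values from >= 2 positions")
  if (length(unique(v)) == 1) {
    warning("all values identical: single effective component")
    return(new("HaloResult",
               positionGroups = setNames(rep("A", length(unique(pos))),
                                         unique(pos)),
               values = data.frame(position = pos, value = v, group = "A"),
               modelName = "degenerate", componentMeans = c(A = v[1], B = NA),
               varianceExplained = NA_real_, rankSumP = NA_real_,
               degenerate = TRUE))
  }
  set.seed(seed)
  # BIC chooses between equal- and unequal-variance models. The conjugate
  # variance prior regularizes the classic 1-D degeneracy where the
  # unequal-variance model collapses one component onto a spike of
  # near-identical values; the joint call can still fail on a singularity,
  # in which case each model is fit separately and the better BIC kept.
  fit <- tryCatch(Mclust(v, G = 2, modelNames = c("E", "V"),
                         prior = mclust::priorControl(), verbose = FALSE),
                  error = function(e) NULL)
  if (is.null(fit)) {
    fits <- lapply(c("E", "V"), function(mn)
      tryCatch(Mclust(v, G = 2, modelNames = mn,
                      prior = mclust::priorControl(), verbose = FALSE),
               error = function(e) NULL))
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) stop("mixture fit failed")
    fit <- fits[[which.max(vapply(fits, function(f) f$bic, 0))]]
  }
  post <- fit$z
  ord <- .positionFactor(pos)
  posLevels <- unique(pos[order(ord)])
  compOf <- vapply(posLevels, function(p) {
    which.max(colSums(post[pos == p, , drop = FALSE]))
  }, 0L)
  compA <- compOf[[1]]  # component of the most shoreward position
  groups <- setNames(ifelse(compOf == compA, "A", "B"), posLevels)
  valueGroup <- ifelse(fit$classification == compA, "A", "B")
  mA <- fit$parameters$mean[compA]
  mB <- if (any(compOf != compA)) fit$parameters$mean[-compA][1] else
    fit$parameters$mean[-compA][1]
  grpA <- v[groups[pos] == "A"]; grpB <- v[groups[pos] == "B"]
  p <- if (length(grpA) && length(grpB)) rankSumTest(grpA, grpB) else NA_real_
  gm <- groups[pos]
  bss <- sum(tapply(v, gm, function(g) length(g) * (mean(g) - mean(v))^2))
  new("HaloResult", positionGroups = groups,
      values = data.frame(position = pos, value = v, group = unname(gm)),
      modelName = fit$modelName,
      componentMeans = c(A = unname(mA), B = unname(mB)),
      varianceExplained = if (length(unique(gm)) > 1)
        bss / sum((v - mean(v))^2) else NA_real_,
      rankSumP = p, degenerate = FALSE)
}

#' Per-position index values for selected transect events
#'
#' For each high-abundance (taxon, site-month) event, the mean eDNA index of
#' that taxon at each transect position (over the position's technical
#' replicates). This is the long-format input to [gmmTwoGroup()].
#'
#' @param x an [EdnaExperiment-class].
#' @param events data.frame of events (e.g. the `"high"` rows after
#'   [splitHighLow()]), with columns `taxon_unit`, `site`, `month`.
#' @param grouping index grouping (default `"taxon_unit"`).
#' @return data.frame: `taxon_unit`, `site`, `month`, `position`, `value`.
#' @export
haloPositionValues <- function(x, events, grouping = "taxon_unit") {
  env <- environmentalSamples(x)
  idx <- ednaIndex(env, grouping = grouping)
  cd <- colData(env)
  out <- list()
  for (i in seq_len(nrow(events))) {
    tu <- events$taxon_unit[i]
    j <- cd$site == events$site[i] & cd$month == events$month[i]
    for (p in unique(as.character(cd$position[j]))) {
      k <- j & cd$position == p
      out[[length(out) + 1L]] <- data.frame(
        taxon_unit = tu, site = events$site[i], month = events$month[i],
        position = p, value = mean(idx[tu, k]), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Spatial-autocorrelation check on adjacent transect points
#'
#' Computes the all-ASV Bray-Curtis dissimilarity between adjacent alongshore
#' positions of each full transect (Eg and Ba are excluded: their metric
#' distance to the transect varies by site), groups the pairs by their
#' spacing in meters, and runs a Kruskal-Wallis rank test of the null that
#' spacing does not influence dissimilarity.
#'
#' @param x an [EdnaExperiment-class].
#' @param minPositions minimum alongshore positions per transect (default 3).
#' @return list: `pairs` (data.frame `site`, `month`, `spacing_m`,
#'   `dissimilarity`), `statistic` (tie-corrected H), `p`.
#' @export
adjacentDissimilarityCheck <- function(x, minPositions = 3) {
  env <- environmentalSamples(x)
  idx <- ednaIndex(env, grouping = "asv")
  cd <- colData(env)
  key <- paste(cd$site, cd$month, sep = "_")
  rows <- list()
  for (sm in unique(key)) {
    j <- which(key == sm & !is.na(cd$distance_m))
    dists <- sort(unique(cd$distance_m[j]))
    if (length(dists) < minPositions) next
    prof <- vapply(dists, function(dm)
      rowMeans(idx[, j[cd$distance_m[j] == dm], drop = FALSE]),
      numeric(nrow(idx)))
    for (i in seq_len(length(dists) - 1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        site = cd$site[j][1], month = cd$month[j][1],
        spacing_m = dists[i + 1] - dists[i],
        dissimilarity = .bc2(prof[, i], prof[, i + 1]))
    }
  }
  if (!length(rows)) stop("no transect has >= ", minPositions,
                          " alongshore positions")
  pairs <- do.call(rbind, rows)
  if (length(unique(pairs$spacing_m)) < 2)
    stop("need >= 2 spacing groups for the Kruskal-Wallis test")
  if (length(unique(pairs$dissimilarity)) == 1)
    return(list(pairs = pairs, statistic = 0, p = 1))
  kt <- kruskal.test(pairs$dissimilarity, factor(pairs$spacing_m))
  list(pairs = pairs, statistic = unname(kt$statistic), p = kt$p.value)
}
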