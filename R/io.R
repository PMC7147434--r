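# Transect positions in shore-to-sea order. "Eg" is the eelgrass bed interior
# (tens of meters inside the bed edge), 1-15 are alongshore meters outside the
# edge, "Ba" is distant bare substrate; Eg and Ba have no fixed metric
# distance, so distance_m is NA there.
.POSITIONS <- c("Eg", "1", "3", "6", "10", "15", "Ba")

#' Default sample-name dialect
#'
#' Sample names encode the study design as underscore-delimited fields, e.g.
#' `"WB_Al_1_July_2_run1"` = site Willapa Bay, alongshore transect, 1 m from
#' the bed edge, July, PCR replicate 2, sequencing run 1. Position `"0"`
#' denotes the eelgrass-bed interior (`Eg`) and `"50"` the distant bare
#' position (`Ba`). Control samples are recognised by prefix (`POS_`/`NEG_`).
#' All vocabularies may be extended for other studies.
#'
#' @return a list with components `field_order`, `sites`, `kinds`, `months`,
#'   `position_map`, `positions`, `max_replicates`, `control_patterns`.
#' @export
defaultDialect <- function() {
  list(
    field_order = c("site", "transect_kind", "position", "month",
                    "replicate", "run"),
    sites = c(CI = "Case Inlet", NR = "Nisqually Reach", PG = "Port Gamble",
              SK = "Skokomish", WB = "Willapa Bay"),
    kinds = c(Eg = "eelgrass", Al = "alongshore", Ac = "across", Ba = "bare"),
    months = c("May", "July", "August"),
    position_map = c("0" = "Eg", "50" = "Ba"),
    positions = .POSITIONS,
    max_replicates = 3L,
    control_patterns = list(positive = "^(POS|KANGAROO|OSTRICH)",
                            negative = "^NEG")
  )
}

.positionFactor <- function(x, levels = .POSITIONS)
  factor(x, levels = levels, ordered = TRUE)

#' Parse sample names into design metadata
#'
#' @param name character vector of sample names.
#' @param dialect naming dialect, see [defaultDialect()].
#' @return a `DataFrame` with one row per name: `site`, `transect_kind`,
#'   `position` (ordered factor Eg < 1 < ... < 15 < Ba), `distance_m`
#'   (numeric alongshore meters, `NA` for Eg/Ba), `month`, `bottle_id`,
#'   `replicate_index`, `run_id`, `sample_class`.
#' @examples
#' parseSampleName("WB_Al_1_July_2_run1")
#' parseSampleName("CI_Eg_0_May_1_run1")$position
#' @export
parseSampleName <- function(name, dialect = defaultDialect()) {
  one <- function(nm) {
    up <- toupper(nm)
    if (grepl(dialect$control_patterns$positive, up) ||
        grepl(dialect$control_patterns$negative, up)) {
      cls <- if (grepl(dialect$control_patterns$positive, up))
        "positive_control" else "negative_control"
      parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
      rep_idx <- suppressWarnings(as.integer(parts[length(parts)]))
      run <- if (length(parts) >= 2) parts[length(parts) - 1] else NA_character_
      return(data.frame(
        site = NA_character_, transect_kind = NA_character_,
        position = .positionFactor(NA, dialect$positions),
        distance_m = NA_real_, month = NA_character_,
        bottle_id = paste(parts[-length(parts)], collapse = "_"),
        replicate_index = if (is.na(rep_idx)) 1L else rep_idx,
        run_id = run, sample_class = cls, stringsAsFactors = FALSE))
    }
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(parts) < length(dialect$field_order))
      stop("malformed sample name '", nm, "': expected ",
           length(dialect$field_order), " underscore-delimited fields (",
           paste(dialect$field_order, collapse = ", "), "), got ",
           length(parts))
    f <- setNames(parts[seq_along(dialect$field_order)], dialect$field_order)
    if (!f[["site"]] %in% names(dialect$sites))
      stop("unknown site code '", f[["site"]], "' in '", nm,
           "'; allowed: ", paste(names(dialect$sites), collapse = ", "))
    if (!f[["transect_kind"]] %in% names(dialect$kinds))
      stop("unknown transect kind '", f[["transect_kind"]], "' in '", nm,
           "'; allowed: ", paste(names(dialect$kinds), collapse = ", "))
    pos_raw <- f[["position"]]
    pos <- if (pos_raw %in% names(dialect$position_map))
      dialect$position_map[[pos_raw]] else pos_raw
    if (!pos %in% dialect$positions)
      stop("unknown position '", pos_raw, "' in '", nm, "'; allowed: ",
           paste(c(names(dialect$position_map), dialect$positions),
                 collapse = ", "))
    if (!f[["month"]] %in% dialect$months)
      stop("unknown month '", f[["month"]], "' in '", nm, "'; allowed: ",
           paste(dialect$months, collapse = ", "))
    rep_idx <- suppressWarnings(as.integer(f[["replicate"]]))
    if (is.na(rep_idx) || rep_idx < 1L || rep_idx > dialect$max_replicates)
      stop("bad replicate index '", f[["replicate"]], "' in '", nm,
           "': must be an integer in 1..", dialect$max_replicates)
    dist <- suppressWarnings(as.numeric(pos))  # NA for Eg/Ba by design
    data.frame(
      site = f[["site"]], transect_kind = dialect$kinds[[f[["transect_kind"]]]],
      position = .positionFactor(pos, dialect$positions), distance_m = dist,
      month = f[["month"]],
      bottle_id = paste(f[["site"]], pos, f[["month"]], sep = "_"),
      replicate_index = rep_idx, run_id = f[["run"]],
      sample_class = "environmental", stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(name, one))
  rownames(out) <- name
  DataFrame(out)
}

#' Read an ASV count table from TSV
#'
#' Accepts long format (columns `asv_id`/`asv`, `sample_name`/`sample`,
#' `count`/`reads`) or wide format (first column ASV ids, remaining columns
#' one per sample); the layout is auto-detected from the header.
#'
#' @param path TSV file of counts.
#' @param taxonomyPath optional TSV of taxonomy, see [readTaxonomy()].
#' @param dialect sample-name dialect for metadata parsing.
#' @return an [EdnaExperiment-class].
#' @export
readCountTable <- function(path, taxonomyPath = NULL,
                           dialect = defaultDialect()) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lc <- tolower(colnames(df))
  asv_col <- match(TRUE, lc %in% c("asv_id", "asv"))
  smp_col <- match(TRUE, lc %in% c("sample_name", "sample"))
  cnt_col <- match(TRUE, lc %in% c("count", "reads"))
  if (!is.na(asv_col) && !is.na(smp_col) && !is.na(cnt_col)) {
    long <- data.frame(asv_id = as.character(df[[asv_col]]),
                       sample_name = as.character(df[[smp_col]]),
                       count = as.numeric(df[[cnt_col]]))
  } else {
    if (ncol(df) < 2) stop("wide count table needs >= 2 columns")
    asvs <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    long <- data.frame(asv_id = rep(asvs, times = ncol(m)),
                       sample_name = rep(colnames(m), each = nrow(m)),
                       count = as.numeric(m))
  }
  if (anyNA(long$count)) stop("non-numeric counts in ", path)
  if (any(long$count < 0)) stop("negative counts in ", path)
  key <- paste(long$asv_id, long$sample_name, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (asv, sample) records in ", path, ": ",
         sub("\r", " / ", key[duplicated(key)][1]))
  asvs <- sort(unique(long$asv_id))
  samples <- unique(long$sample_name)
  m <- matrix(0, length(asvs), length(samples),
              dimnames = list(asvs, samples))
  m[cbind(match(long$asv_id, asvs), match(long$sample_name, samples))] <-
    long$count
  tax <- if (!is.null(taxonomyPath)) readTaxonomy(taxonomyPath) else NULL
  EdnaExperiment(m, taxonomy = tax, dialect = dialect)
}

#' Write counts to TSV
#'
#' @param x an [EdnaExperiment-class] or count matrix.
#' @param path output file.
#' @param format `"long"` (canonical; zero counts omitted) or `"wide"`.
#' @param keepZeros in long format, keep explicit zero records.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(x, path, format = c("long", "wide"),
                            keepZeros = FALSE) {
  format <- match.arg(format)
  m <- if (is(x, "EdnaExperiment")) counts(x) else as.matrix(x)
  if (format == "wide") {
    out <- data.frame(asv_id = rownames(m), m, check.names = FALSE)
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    long <- data.frame(
      asv_id = rep(rownames(m), times = ncol(m)),
      sample_name = rep(colnames(m), each = nrow(m)),
      count = as.numeric(m))
    if (!keepZeros) long <- long[long$count > 0, , drop = FALSE]
    long <- long[order(long$asv_id, long$sample_name), , drop = FALSE]
    write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' TSV keyed by `asv_id` with columns `phylum` and optionally `family`,
#' `genus`, `taxon_unit` and `control` (logical flag for positive-control
#' tissue ASVs such as kangaroo or ostrich). When `taxon_unit` is absent it
#' is derived as genus within family where known, else family, else the ASV
#' id, so that redundant variants of one taxon can be merged.
#'
#' @param path TSV file.
#' @return data.frame with one row per ASV.
#' @export
readTaxonomy <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("asv_id", "phylum") %in% colnames(df)))
    stop("taxonomy must have columns asv_id and phylum")
  if (anyDuplicated(df$asv_id))
    stop("duplicate asv_id in taxonomy: ", df$asv_id[duplicated(df$asv_id)][1])
  if (!"family" %in% colnames(df)) df$family <- NA_character_
  if (!"genus" %in% colnames(df)) df$genus <- NA_character_
  if (!"control" %in% colnames(df)) df$control <- FALSE
  df$control <- as.logical(df$control)
  if (!"taxon_unit" %in% colnames(df)) {
    df$taxon_unit <- ifelse(
      !is.na(df$family) & !is.na(df$genus), paste(df$family, df$genus),
      ifelse(!is.na(df$family), df$family, df$asv_id))
  }
  if (any(!is.na(df$family) & is.na(df$taxon_unit)))
    stop("taxon_unit must be defined wherever family is defined")
  df
}

#' Load an analysis configuration
#'
#' Reads a YAML file of thresholds and seeds, filling documented defaults for
#' anything absent. Unknown keys produce a warning, not an error.
#'
#' @param path YAML config file, or `NULL` for all defaults.
#' @param overrides named list applied on top of the file.
#' @return named list of settings: `min_reads` (low-read replicate cutoff),
#'   `detect_threshold` (reads counting as a detection), `occupancy_threshold`
#'   (presence-probability cull at 0.2, i.e. 20%), `occupancy_aggregate`
#'   (`"max"` or `"mean"` over bottles), `qc_alpha`, `n_permutations`,
#'   `nmds_max_starts`, `mcmc` (chains/draws/burn_in), `seed`, `timestamps`,
#'   `stages` (logical flags to skip pipeline stages).
#' @export
loadConfig <- function(path = NULL, overrides = list()) {
  defaults <- list(
    min_reads = 1000, detect_threshold = 1, occupancy_threshold = 0.2,
    occupancy_aggregate = "max", qc_alpha = 0.05, n_permutations = 999,
    nmds_max_starts = 100, nmds_dims = 2,
    mcmc = list(chains = 2, draws = 5000, burn_in = 2000),
    seed = 1, timestamps = FALSE,
    stages = list(decontam = TRUE, occupancy = TRUE, qc = TRUE,
                  nmds = TRUE, permanova = TRUE, habitat = TRUE, halo = TRUE))
  cfg <- defaults
  apply_over <- function(cfg, user, src) {
    unknown <- setdiff(names(user), names(defaults))
    if (length(unknown))
      warning("ignoring unknown config keys (", src, "): ",
              paste(unknown, collapse = ", "))
    for (k in intersect(names(user), names(defaults))) {
      if (is.list(defaults[[k]]) && is.list(user[[k]]))
        cfg[[k]] <- utils::modifyList(cfg[[k]], user[[k]])
      else cfg[[k]] <- user[[k]]
    }
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    if (!is.null(user)) cfg <- apply_over(cfg, user, path)
  }
  if (length(overrides)) cfg <- apply_over(cfg, overrides, "overrides")
  for (k in c("occupancy_threshold", "qc_alpha")) {
    v <- cfg[[k]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1)
      stop(k, " must be a probability in [0,1], got ", v)
  }
  if (cfg$min_reads < 0) stop("min_reads must be >= 0")
  if (cfg$n_permutations < 1) stop("n_permutations must be >= 1")
  cfg
}
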