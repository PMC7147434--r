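# Small in-code fixtures shared across test files.

# A hand-built experiment: 3 environmental replicates of one bottle plus two
# positive controls, 3 environmental ASVs and one control-tissue ASV.
tinyExperiment <- function(envCounts = NULL) {
  if (is.null(envCounts))
    envCounts <- matrix(c(50, 500, 450,
                          60, 520, 400,
                          40, 480, 470,
                          0, 0, 0), nrow = 4, byrow = TRUE)
  stopifnot(nrow(envCounts) == 4, ncol(envCounts) == 3)
  ctl <- matrix(c(10, 30,
                  0, 0,
                  0, 0,
                  990, 970), nrow = 4, byrow = TRUE)
  m <- cbind(envCounts, ctl)
  dimnames(m) <- list(
    c("A1", "A2", "A3", "ACTL"),
    c("CI_Eg_0_May_1_run1", "CI_Eg_0_May_2_run1", "CI_Eg_0_May_3_run1",
      "POS_run1_1", "POS_run1_2"))
  tax <- data.frame(asv_id = rownames(m),
                    phylum = c("Dinoflagellata", "Chlorophyta", "Chlorophyta",
                               "Chordata"),
                    family = c("DinoFam", "ChloroFam", "ChloroFam",
                               "Macropodidae"),
                    genus = NA_character_,
                    control = c(FALSE, FALSE, FALSE, TRUE))
  EdnaExperiment(m, taxonomy = tax)
}

# A designed experiment over arbitrary positions/sites/months where each
# (taxon, replicate) count is supplied by `fill(site, month, position, rep)`
# returning a named numeric vector over taxa.
designedExperiment <- function(fill, sites = "CI", months = "May",
                               positions = c("Eg", "1", "3", "6", "10", "15", "Ba"),
                               nrep = 2, phyla = NULL) {
  posField <- function(p) if (p == "Eg") "0" else if (p == "Ba") "50" else p
  kind <- function(p) if (p == "Eg") "Eg" else if (p == "Ba") "Ba" else "Al"
  cols <- list()
  for (s in sites) for (mo in months) for (p in positions) for (r in seq_len(nrep)) {
    nm <- paste(s, kind(p), posField(p), mo, r, "run1", sep = "_")
    cols[[nm]] <- fill(s, mo, p, r)
  }
  m <- do.call(cbind, cols)
  taxa <- names(cols[[1]])
  rownames(m) <- taxa
  tax <- data.frame(asv_id = taxa,
                    phylum = if (is.null(phyla)) taxa else phyla,
                    family = taxa, genus = NA_character_, control = FALSE)
  tax$taxon_unit <- tax$family
  EdnaExperiment(m, taxonomy = tax)
}
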