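# Shared fixture builders. Everything is constructed in code at test time.

# One PSM row with sensible defaults; site_glycans given as c(`pos` = "comp").
make_psm <- function(peptide,
                     site_glycans = setNames(character(0), character(0)),
                     q_value = 0.001,
                     is_decoy = FALSE,
                     localization_level = "Level1",
                     protein_accession = "P1",
                     file_name = "f1",
                     enzyme = "AM0627",
                     substrate = "S1",
                     sialidase = FALSE,
                     replicate = 1L,
                     timepoint_h = 24,
                     start = NA_integer_,
                     end = NA_integer_,
                     psm_id = NA_integer_) {
  tibble::tibble(
    psm_id = psm_id, file_name = file_name, peptide = peptide,
    protein_accession = protein_accession, start = start, end = end,
    site_glycans = list(site_glycans), q_value = q_value, is_decoy = is_decoy,
    localization_level = localization_level, enzyme = enzyme,
    substrate = substrate, sialidase = sialidase, replicate = replicate,
    timepoint_h = timepoint_h
  )
}

make_psms <- function(...) {
  out <- dplyr::bind_rows(...)
  out$psm_id <- seq_len(nrow(out))
  out
}

# The six-record filter fixture: one decoy, one q = 0.02, one Level 2, one
# peptide with an N-X-S/T sequon, and two clean records.
six_record_fixture <- function() {
  make_psms(
    make_psm("TTPAP", c(`1` = "HexNAc(1)")),
    make_psm("TTPAP", c(`1` = "HexNAc(1)"), is_decoy = TRUE),
    make_psm("TTPAP", c(`1` = "HexNAc(1)"), q_value = 0.02),
    make_psm("TTPAP", c(`1` = "HexNAc(1)"), localization_level = "Level2"),
    make_psm("ANVST", c(`4` = "HexNAc(1)")),
    make_psm("STTAV", c(`2` = "HexNAc(1)"))
  )
}

demo_proteins <- function() {
  tibble::tibble(
    accession = c("P1", "P2"),
    description = c("demo substrate", "demo substrate"),
    sequence = c("PAQTTPAK", "GATTSPAGTTK")
  )
}

# A minimal event row for the stats unit tests. `covered_glycans` is the
# site_glycans map of the evidencing peptide.
make_event <- function(terminus, p1_index, start, end, peptide,
                       site_glycans = setNames(character(0), character(0)),
                       protein = "PAQTTPAK",
                       p1_glycan = "unobserved", p1prime_glycan = "unobserved",
                       enzyme = "AM0627", substrate = "S1", replicate = 1L,
                       timepoint_h = 24, attribution = "mucinase",
                       flank = 4L) {
  tibble::tibble(
    psm_id = 1L, protein_accession = "P1", terminus = terminus,
    p1_index = p1_index,
    p1_residue = substring(protein, p1_index, p1_index),
    p1prime_residue = substring(protein, p1_index + 1L, p1_index + 1L),
    p1_glycan = p1_glycan, p1prime_glycan = p1prime_glycan,
    window = extract_window(protein, p1_index, flank),
    start = start, end = end, peptide = peptide,
    site_glycans = list(site_glycans),
    enzyme = enzyme, substrate = substrate, replicate = replicate,
    timepoint_h = timepoint_h, attribution = attribution
  )
}

# Strict closed-loop configuration: full occupancy, all-Tn glycans, certain
# cleavage at Tn|Tn bonds, no trypsin, no identification noise.
strict_config <- function(seed = 11L, length = 400L) {
  Cmat <- matrix(1, 1, 1, dimnames = list("Tn", "Tn"))
  simulation_config(
    seed = seed,
    substrates = tibble::tibble(accession = "SUB1", length = length),
    occupancy = 1,
    glycan_dist = c(Tn = 1),
    enzymes = list(AM0627 = Cmat),
    trypsin = FALSE,
    decoy_fraction = 0,
    target_q_contam = 0,
    level_probs = c(Level1 = 1),
    peptide_length = c(1L, 10000L),
    replicates = 2L,
    timepoints_h = 24
  )
}

# Independent brute-force enumeration of qualifying bonds (both residues S/T,
# both glycosylated) — the oracle for simulate_mucinase at probability 1.
enumerate_qualifying_bonds <- function(sequence, glycoform) {
  chars <- strsplit(sequence, "")[[1]]
  gly <- as.integer(names(glycoform))
  which(vapply(seq_len(length(chars) - 1L), function(i) {
    chars[i] %in% c("S", "T") && chars[i + 1L] %in% c("S", "T") &&
      i %in% gly && (i + 1L) %in% gly
  }, TRUE))
}

# Rule-based tryptic split oracle: cut after K/R except before P.
trypsin_split_oracle <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  cuts <- which(chars %in% c("K", "R"))
  cuts <- cuts[cuts < n & chars[pmin(cuts + 1L, n)] != "P"]
  bounds <- sort(unique(c(0L, cuts, n)))
  substring(sequence, head(bounds, -1) + 1L, bounds[-1])
}
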