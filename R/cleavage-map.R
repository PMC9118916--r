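# Mapping filtered glycopeptides onto substrate sequences, inferring scissile
# bonds from peptide termini, attributing termini to mucinase vs trypsin, and
# extracting fixed-width motif windows.
#
# Coordinates are 1-based and inclusive; a scissile bond is named by the
# protein position of its P1 residue (the bond lies between p1_index and
# p1_index + 1), following the Schechter-Berger P1/P1' convention.

#' Window configuration
#'
#' @param flank Number of positions on each side of the scissile bond
#'   (window spans P`flank`..P1 | P1'..P`flank`', length `2 * flank`).
#' @param pad Pad character for positions beyond the protein termini.
#' @param use_n_terminal,use_c_terminal Emit events from peptide N-/C-termini?
#' @param keep_tryptic Keep trypsin-attributed events in motif statistics?
#' @param keep_ambiguous Keep multi-placement peptides? (Default drops them so
#'   tandem-repeat motifs are not double-counted.)
#' @return A `window_config` list.
#' @export
window_config <- function(flank = 4L, pad = "-",
                          use_n_terminal = TRUE, use_c_terminal = TRUE,
                          keep_tryptic = FALSE, keep_ambiguous = FALSE) {
  stopifnot(flank >= 1, nchar(pad) == 1L)
  structure(list(flank = as.integer(flank), pad = pad,
                 use_n_terminal = use_n_terminal,
                 use_c_terminal = use_c_terminal,
                 keep_tryptic = keep_tryptic,
                 keep_ambiguous = keep_ambiguous),
            class = "window_config")
}

#' Locate peptides on substrate sequences
#'
#' Exact substring search of every peptide against every protein. Peptides
#' with exactly one match get `start`/`end`/`protein_accession` assigned;
#' multi-match peptides are flagged ambiguous and zero-match peptides are
#' recorded as unmapped. By default only uniquely placed peptides proceed to
#' event inference.
#'
#' @param psms PSM tibble.
#' @param proteins Tibble from [read_fasta()].
#' @return List with `placed` (uniquely placed PSMs, coordinates filled),
#'   `ambiguous` (multi-match PSMs), and `audit` (tibble `psm_id`, `peptide`,
#'   `n_matches`, `status`).
#' @export
locate_peptides <- function(psms, proteins) {
  stopifnot(nrow(proteins) > 0)
  place_one <- function(pep) {
    hits <- lapply(seq_len(nrow(proteins)), function(i) {
      m <- gregexpr(pep, proteins$sequence[i], fixed = TRUE)[[1]]
      if (m[1] == -1L) return(NULL)
      tibble::tibble(protein_accession = proteins$accession[i],
                     start = as.integer(m))
    })
    dplyr::bind_rows(hits)
  }
  placements <- lapply(psms$peptide, place_one)
  n_matches <- vapply(placements, nrow, 0L)
  status <- dplyr::case_when(n_matches == 0L ~ "unmapped",
                             n_matches == 1L ~ "unique",
                             TRUE ~ "ambiguous")
  placed <- psms[status == "unique", , drop = FALSE]
  if (nrow(placed) > 0) {
    hit <- dplyr::bind_rows(placements[status == "unique"])
    placed$protein_accession <- hit$protein_accession
    placed$start <- hit$start
    placed$end <- hit$start + nchar(placed$peptide) - 1L
  }
  audit <- tibble::tibble(psm_id = psms$psm_id, peptide = psms$peptide,
                          n_matches = n_matches, status = status)
  list(placed = placed,
       ambiguous = psms[status == "ambiguous", , drop = FALSE],
       audit = audit)
}

#' Extract a motif window around a scissile bond
#'
#' The window covers protein positions `p1_index - flank + 1` through
#' `p1_index + flank`; positions outside the protein are replaced by the pad
#' character, so the result always has length `2 * flank`.
#'
#' @param sequence Protein sequence.
#' @param p1_index Protein position of the P1 residue (`1 <= p1_index < length`).
#' @param flank Flank width.
#' @param pad Pad character.
#' @return Window string of length `2 * flank`.
#' @examples
#' extract_window("PAQTTPAK", 4, flank = 2)  # "QTTP"
#' @export
extract_window <- function(sequence, p1_index, flank = 4L, pad = "-") {
  n <- nchar(sequence)
  if (p1_index < 1L || p1_index >= n) {
    stop("p1_index must lie in [1, protein length - 1]", call. = FALSE)
  }
  pos <- (p1_index - flank + 1L):(p1_index + flank)
  chars <- ifelse(pos >= 1L & pos <= n, substring(sequence, pos, pos), pad)
  paste(chars, collapse = "")
}

#' Motif position labels
#'
#' @param flank Flank width.
#' @return Character vector `P<flank>`..`P1`, `P1'`..`P<flank>'`.
#' @export
window_position_labels <- function(flank = 4L) {
  c(paste0("P", flank:1), paste0("P", 1:flank, "'"))
}

#' Infer cleavage events from placed glycopeptides
#'
#' Each uniquely placed peptide evidences up to two scissile bonds: its
#' N-terminus evidences the bond at `start - 1` (the peptide's first residue
#' is that bond's P1') and its C-terminus the bond at `end` (the last residue
#' is P1). Termini coinciding with a protein terminus evidence no bond.
#' The glycan at the peptide-covered residue is observed (a composition, or
#' `"unglycosylated"`); the residue across the bond lies outside the peptide
#' and is `"unobserved"` — never imputed. A bond whose P1 residue is K or R is
#' attributed to the tryptic co-digest, all others to the mucinase.
#'
#' @param placed Uniquely placed PSM tibble from [locate_peptides()].
#' @param proteins Protein tibble.
#' @param cfg A [window_config()].
#' @return Tibble of cleavage events (one row per evidencing terminus) with
#'   P1/P1' residues and glycans, attribution, motif window, and the sample
#'   metadata and placement of the source PSM.
#' @export
infer_cleavage_events <- function(placed, proteins, cfg = window_config()) {
  seq_of <- stats::setNames(proteins$sequence, proteins$accession)
  meta_cols <- intersect(c("enzyme", "substrate", "sialidase", "replicate",
                           "timepoint_h", "file_name"), names(placed))
  events <- vector("list", 2L * nrow(placed))
  k <- 0L
  for (i in seq_len(nrow(placed))) {
    prot <- seq_of[[placed$protein_accession[i]]]
    n <- nchar(prot)
    start <- placed$start[i]
    end <- placed$end[i]
    pep <- placed$peptide[i]
    sites <- placed$site_glycans[[i]]
    glycan_at <- function(pep_pos) {
      hit <- match(as.character(pep_pos), names(sites))
      if (is.na(hit)) "unglycosylated" else unname(sites[hit])
    }
    base <- placed[i, meta_cols, drop = FALSE]
    if (cfg$use_n_terminal && start > 1L) {
      p1 <- start - 1L
      k <- k + 1L
      events[[k]] <- dplyr::bind_cols(
        tibble::tibble(
          psm_id = placed$psm_id[i],
          protein_accession = placed$protein_accession[i],
          terminus = "N",
          p1_index = p1,
          p1_residue = substring(prot, p1, p1),
          p1prime_residue = substring(prot, p1 + 1L, p1 + 1L),
          p1_glycan = "unobserved",
          p1prime_glycan = glycan_at(1L),
          window = extract_window(prot, p1, cfg$flank, cfg$pad),
          start = start, end = end, peptide = pep,
          site_glycans = list(sites)
        ), base)
    }
    if (cfg$use_c_terminal && end < n) {
      p1 <- end
      k <- k + 1L
      events[[k]] <- dplyr::bind_cols(
        tibble::tibble(
          psm_id = placed$psm_id[i],
          protein_accession = placed$protein_accession[i],
          terminus = "C",
          p1_index = p1,
          p1_residue = substring(prot, p1, p1),
          p1prime_residue = substring(prot, p1 + 1L, p1 + 1L),
          p1_glycan = glycan_at(nchar(pep)),
          p1prime_glycan = "unobserved",
          window = extract_window(prot, p1, cfg$flank, cfg$pad),
          start = start, end = end, peptide = pep,
          site_glycans = list(sites)
        ), base)
    }
  }
  out <- dplyr::bind_rows(events[seq_len(k)])
  if (nrow(out) == 0) return(out)
  out$attribution <- ifelse(out$p1_residue %in% c("K", "R"), "tryptic", "mucinase")
  if (!cfg$keep_tryptic) {
    attr(out, "n_tryptic") <- sum(out$attribution == "tryptic")
  }
  out
}
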