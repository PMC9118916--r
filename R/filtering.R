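# Identification filters producing the analysis-ready glycopeptide list:
# target-only, q-value < threshold, site-localization level, and exclusion of
# peptides containing an N-glycosylation sequon.

#' Filter configuration
#'
#' Defaults reproduce the standard post-search filter chain for O-glycopeptide
#' identifications: target matches only, q-value strictly below 0.01, Level 1
#' (unambiguous) glycosite localization only, and exclusion of peptides
#' containing an N-glycosylation sequon (N-X-S/T). The sequon pattern is
#' applied literally — any X, including proline — unless
#' `sequon_allows_proline_x = FALSE`, which restores the conventional X != P
#' reading.
#'
#' @param q_max q-value threshold (strict `<`).
#' @param required_levels Localization levels accepted.
#' @param exclude_sequon Drop peptides containing an N-X-S/T sequon?
#' @param sequon_allows_proline_x Does X in N-X-S/T include proline?
#' @param targets_only Drop decoy matches?
#' @return A `filter_config` list.
#' @export
filter_config <- function(q_max = 0.01,
                          required_levels = "Level1",
                          exclude_sequon = TRUE,
                          sequon_allows_proline_x = TRUE,
                          targets_only = TRUE) {
  stopifnot(q_max > 0, q_max <= 1, length(required_levels) >= 1)
  structure(list(q_max = q_max,
                 required_levels = required_levels,
                 exclude_sequon = exclude_sequon,
                 sequon_allows_proline_x = sequon_allows_proline_x,
                 targets_only = targets_only),
            class = "filter_config")
}

#' Detect an N-glycosylation sequon
#'
#' True iff the peptide contains N-X-S/T at any position (overlaps included).
#' With `allow_proline_x = FALSE`, X must not be proline.
#'
#' @param peptide Character vector of peptide sequences.
#' @param allow_proline_x Does X include proline?
#' @return Logical vector.
#' @examples
#' contains_n_sequon(c("ANVSA", "TTPAP", "ANPSA"))
#' contains_n_sequon("ANPSA", allow_proline_x = FALSE)
#' @export
contains_n_sequon <- function(peptide, allow_proline_x = TRUE) {
  stopifnot(all(nzchar(peptide)))
  pattern <- if (allow_proline_x) "N(?=.[ST])" else "N(?=[^P][ST])"
  grepl(pattern, peptide, perl = TRUE)
}

#' Apply identification filters
#'
#' A PSM is kept iff it passes every enabled rule. The audit attributes each
#' rejected PSM to the first failing rule in the fixed order decoy, q-value,
#' localization level, sequon; the kept set itself is order-independent.
#' Idempotent: re-filtering the kept set changes nothing.
#'
#' @param psms PSM tibble.
#' @param cfg A [filter_config()].
#' @return List with `kept` (tibble) and `audit` (named integer counts:
#'   `n_in`, `decoy`, `q_value`, `level`, `sequon`, `n_kept`).
#' @export
apply_filters <- function(psms, cfg = filter_config()) {
  if (nrow(psms) == 0) {
    audit <- c(n_in = 0L, decoy = 0L, q_value = 0L, level = 0L, sequon = 0L,
               n_kept = 0L)
    return(list(kept = psms, audit = audit))
  }
  fail_decoy <- if (cfg$targets_only) psms$is_decoy else rep(FALSE, nrow(psms))
  fail_q <- !(psms$q_value < cfg$q_max)
  fail_level <- !(psms$localization_level %in% cfg$required_levels)
  fail_sequon <- if (cfg$exclude_sequon) {
    contains_n_sequon(psms$peptide, cfg$sequon_allows_proline_x)
  } else {
    rep(FALSE, nrow(psms))
  }
  first_fail <- rep(NA_character_, nrow(psms))
  first_fail[fail_sequon] <- "sequon"
  first_fail[fail_level] <- "level"
  first_fail[fail_q] <- "q_value"
  first_fail[fail_decoy] <- "decoy"
  kept <- psms[is.na(first_fail), , drop = FALSE]
  audit <- c(
    n_in = nrow(psms),
    decoy = sum(first_fail == "decoy", na.rm = TRUE),
    q_value = sum(first_fail == "q_value", na.rm = TRUE),
    level = sum(first_fail == "level", na.rm = TRUE),
    sequon = sum(first_fail == "sequon", na.rm = TRUE),
    n_kept = nrow(kept)
  )
  list(kept = kept, audit = audit)
}
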