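# Core domain types: glycan compositions, glycan classes, glycan database.
#
# A glycan composition is represented canonically as its `Name(count)` string
# (e.g. "HexNAc(1)Hex(1)"), with monosaccharide keys in a fixed vocabulary
# order. All public functions accept and return these strings; the parsed
# named-integer form is an implementation detail.

#' Monosaccharide vocabulary
#'
#' The monosaccharide keys recognised by the composition grammar, in canonical
#' order. `HexNAc`, `Hex`, `NeuAc` and `Fuc` cover the default O-glycan
#' database; the remaining keys allow user-extended databases.
#'
#' @return Character vector of monosaccharide names.
#' @export
monosaccharide_vocabulary <- function() {
  c("HexNAc", "Hex", "NeuAc", "NeuGc", "Fuc", "Pent", "Sulfo", "Phospho")
}

#' Parse a glycan composition string
#'
#' Compositions use the explicit grammar `Name(count)` repeated, e.g.
#' `"HexNAc(1)Hex(1)NeuAc(1)"` for the sialyl-T antigen. Counts must be
#' positive integers and every name must be in `vocabulary`.
#'
#' @param text Composition string.
#' @param vocabulary Allowed monosaccharide names.
#' @return Named integer vector of counts (names in vocabulary order).
#' @examples
#' parse_glycan_string("HexNAc(1)Hex(1)")
#' @export
parse_glycan_string <- function(text, vocabulary = monosaccharide_vocabulary()) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text)) {
    stop("empty glycan composition string", call. = FALSE)
  }
  m <- gregexpr("([A-Za-z]+)\\((-?[0-9]+)\\)", text, perl = TRUE)[[1]]
  tokens <- if (m[1] == -1L) character(0) else regmatches(text, list(m))[[1]]
  if (paste(tokens, collapse = "") != gsub("[[:space:]]", "", text)) {
    stop("malformed glycan composition: ", sQuote(text), call. = FALSE)
  }
  names_ <- sub("\\(.*$", "", tokens)
  counts <- as.integer(sub("^.*\\((-?[0-9]+)\\)$", "\\1", tokens))
  bad <- setdiff(names_, vocabulary)
  if (length(bad) > 0) {
    stop("unknown monosaccharide ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(counts <= 0L)) {
    stop("non-positive count for ",
         paste(names_[counts <= 0L], collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, factor(names_, levels = vocabulary), sum)
  out <- out[!is.na(out)]
  stats::setNames(as.integer(out), names(out))
}

#' Write a glycan composition to its canonical string
#'
#' Inverse of [parse_glycan_string()]: zero counts are dropped and keys are
#' emitted in vocabulary order, so the writer is a canonicalising round-trip.
#'
#' @param counts Named integer vector of monosaccharide counts.
#' @param vocabulary Monosaccharide name order.
#' @return Canonical composition string.
#' @export
write_glycan_string <- function(counts, vocabulary = monosaccharide_vocabulary()) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) {
    stop("composition must contain at least one monosaccharide", call. = FALSE)
  }
  keys <- c(intersect(vocabulary, names(counts)),
            setdiff(names(counts), vocabulary))
  paste0(keys, "(", counts[keys], ")", collapse = "")
}

#' Canonicalise one or more composition strings
#'
#' @param x Character vector of composition strings.
#' @return Character vector with counts merged and keys ordered canonically.
#' @export
canonical_glycan <- function(x) {
  vapply(x, function(s) write_glycan_string(parse_glycan_string(s)), "",
         USE.NAMES = FALSE)
}

#' Remove sialic acid from a composition
#'
#' Models exo-sialidase treatment: the NeuAc count is set to zero and all other
#' counts are left unchanged. Idempotent.
#'
#' @param x Character vector of composition strings.
#' @return Desialylated composition strings (canonical form).
#' @examples
#' desialylate("HexNAc(1)Hex(1)NeuAc(1)")  # -> "HexNAc(1)Hex(1)"
#' @export
desialylate <- function(x) {
  vapply(x, function(s) {
    counts <- parse_glycan_string(s)
    counts["NeuAc"] <- 0L
    write_glycan_string(counts)
  }, "", USE.NAMES = FALSE)
}

#' Default glycan class vocabulary
#'
#' Maps compositions to the named antigen classes used throughout mucinase
#' specificity analysis: Tn (a single O-GalNAc), T (core 1, GalNAc-Gal),
#' their mono-/di-sialylated forms, and the core 2 branch point. Compositions
#' matching none of these classify as `"other"`.
#'
#' @return Tibble with columns `label` and `composition` (canonical strings).
#' @export
default_glycan_classes <- function() {
  tibble::tibble(
    label = c("Tn", "T", "sialyl-Tn", "sialyl-T", "disialyl-T", "core2"),
    composition = c(
      "HexNAc(1)",
      "HexNAc(1)Hex(1)",
      "HexNAc(1)NeuAc(1)",
      "HexNAc(1)Hex(1)NeuAc(1)",
      "HexNAc(1)Hex(1)NeuAc(2)",
      "HexNAc(2)Hex(1)"
    )
  )
}

#' Classify glycan compositions into antigen classes
#'
#' Exact-composition lookup against a class vocabulary; compositions not in the
#' vocabulary map to `"other"`. Class assignment is not subsumption: e.g. a
#' fucosylated core 1 extension is `"other"`, not `"T"`.
#'
#' @param x Character vector of composition strings.
#' @param classes Class vocabulary as from [default_glycan_classes()].
#' @return Character vector of class labels.
#' @examples
#' classify_glycan(c("HexNAc(1)", "HexNAc(1)Hex(1)", "HexNAc(2)Hex(2)NeuAc(2)Fuc(1)"))
#' @export
classify_glycan <- function(x, classes = default_glycan_classes()) {
  stopifnot(nrow(classes) > 0, !anyDuplicated(classes$label))
  key <- canonical_glycan(classes$composition)
  lab <- classes$label[match(canonical_glycan(x), key)]
  lab[is.na(lab)] <- "other"
  lab
}

#' Default O-glycan database
#'
#' A stand-in database of 22 common mucin-type O-glycan compositions (core 1
#' and core 2 series with sialylation and fucosylation), mirroring the size of
#' the search database used for glycopeptide identification, together with the
#' per-peptide maximum of 4 glycans. The exact published database is
#' supplementary material; this set is synthetic but covers the same antigen
#' classes.
#'
#' @return List with elements `glycans` (22 canonical composition strings) and
#'   `max_per_peptide` (4).
#' @export
default_glycan_database <- function() {
  glycans <- c(
    "HexNAc(1)",                      # Tn
    "HexNAc(1)Hex(1)",                # T (core 1)
    "HexNAc(1)NeuAc(1)",              # sialyl-Tn
    "HexNAc(1)Hex(1)NeuAc(1)",        # sialyl-T
    "HexNAc(1)Hex(1)NeuAc(2)",        # disialyl-T
    "HexNAc(2)Hex(1)",                # core 2
    "HexNAc(2)Hex(2)",
    "HexNAc(2)Hex(1)NeuAc(1)",
    "HexNAc(2)Hex(2)NeuAc(1)",
    "HexNAc(2)Hex(2)NeuAc(2)",
    "HexNAc(1)Hex(1)Fuc(1)",
    "HexNAc(1)Hex(1)NeuAc(1)Fuc(1)",
    "HexNAc(2)Hex(1)Fuc(1)",
    "HexNAc(2)Hex(2)Fuc(1)",
    "HexNAc(2)Hex(2)NeuAc(1)Fuc(1)",
    "HexNAc(2)Hex(2)NeuAc(2)Fuc(1)",
    "HexNAc(2)Hex(3)",
    "HexNAc(3)Hex(2)",
    "HexNAc(3)Hex(2)NeuAc(1)",
    "HexNAc(3)Hex(2)Fuc(1)",
    "HexNAc(3)Hex(3)",
    "HexNAc(3)Hex(3)NeuAc(1)"
  )
  stopifnot(!anyDuplicated(glycans))
  list(glycans = glycans, max_per_peptide = 4L)
}

#' Validate a glycopeptide identification table
#'
#' Checks the structural invariants of a glycopeptide-spectrum-match (PSM)
#' tibble: glycosite positions lie inside the peptide and on S/T residues,
#' start/end (when set) are consistent with the peptide length, q-values lie in
#' \[0, 1\], and no peptide exceeds the database glycan maximum.
#'
#' @param psms Tibble as produced by [read_psm_table()] or [simulate_dataset()].
#' @param max_glycans Per-peptide maximum glycan count.
#' @return `psms`, invisibly, if valid; otherwise an error listing offending rows.
#' @export
validate_glyco_psms <- function(psms, max_glycans = default_glycan_database()$max_per_peptide) {
  problems <- psm_row_problems(psms, max_glycans)
  if (nrow(problems) > 0) {
    stop("invalid PSM rows:\n",
         paste0("  row ", problems$row, ": ", problems$reason, collapse = "\n"),
         call. = FALSE)
  }
  invisible(psms)
}

# Per-row invariant check shared by validate_glyco_psms() and read_psm_table().
# Returns a tibble(row, reason); valid rows contribute nothing.
psm_row_problems <- function(psms, max_glycans) {
  out <- vector("list", nrow(psms))
  for (i in seq_len(nrow(psms))) {
    pep <- psms$peptide[i]
    sites <- psms$site_glycans[[i]]
    reasons <- character(0)
    if (!nzchar(pep)) reasons <- c(reasons, "empty peptide")
    if (length(sites) > 0) {
      pos <- as.integer(names(sites))
      if (anyNA(pos) || any(pos < 1L) || any(pos > nchar(pep))) {
        reasons <- c(reasons, "glycosite out of range")
      } else {
        res <- substring(pep, pos, pos)
        if (!all(res %in% c("S", "T"))) {
          reasons <- c(reasons, "glycosite on non-S/T residue")
        }
      }
      if (length(sites) > max_glycans) {
        reasons <- c(reasons, sprintf("more than %d glycans on one peptide", max_glycans))
      }
    }
    qv <- psms$q_value[i]
    if (is.na(qv) || qv < 0 || qv > 1) reasons <- c(reasons, "q-value outside [0, 1]")
    if (!is.na(psms$start[i]) && !is.na(psms$end[i]) &&
        psms$end[i] - psms$start[i] + 1L != nchar(pep)) {
      reasons <- c(reasons, "start/end inconsistent with peptide length")
    }
    if (length(reasons) > 0) {
      out[[i]] <- tibble::tibble(row = i, reason = paste(reasons, collapse = "; "))
    }
  }
  dplyr::bind_rows(out)
}
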