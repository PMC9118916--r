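# Readers and writers: FASTA substrates, the PSM-table dialect, the sample
# sheet, and generic TSV output.

#' Read substrate protein sequences from FASTA
#'
#' Sequences are uppercased and validated against the 20-letter amino-acid
#' alphabet; `X` is tolerated but flagged with a warning. The accession is the
#' first whitespace-delimited token of each header.
#'
#' @param path FASTA file.
#' @return Tibble with columns `accession`, `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  # Biostrings drops invalid sequence codes with a warning; that is a format
  # error for substrate sequences, so escalate it
  aa <- withCallingHandlers(
    Biostrings::readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("non-amino-acid characters in ", path, call. = FALSE)
      }
    }
  )
  if (length(aa) == 0) {
    stop("empty FASTA file: ", path, call. = FALSE)
  }
  headers <- names(aa)
  accession <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  dup <- accession[duplicated(accession)]
  if (length(dup) > 0) {
    stop("duplicate accession in ", path, ": ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  seqs <- toupper(as.character(aa))
  ok <- grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", seqs)
  if (!all(ok)) {
    stop("non-amino-acid characters in record(s) ",
         paste(accession[!ok], collapse = ", "), call. = FALSE)
  }
  if (any(grepl("X", seqs, fixed = TRUE))) {
    warning("sequence(s) containing X: ",
            paste(accession[grepl("X", seqs, fixed = TRUE)], collapse = ", "),
            call. = FALSE)
  }
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record(s) ",
         paste(accession[!nzchar(seqs)], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(accession = accession, description = description,
                 sequence = unname(seqs))
}

#' Write protein records to FASTA
#'
#' @param proteins Tibble with `accession`, `description`, `sequence`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- ifelse(nzchar(proteins$description),
                      paste(proteins$accession, proteins$description),
                      proteins$accession)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' PSM table dialect
#'
#' Column-name bindings for glycopeptide identification tables. Defaults
#' follow the O-Pair-style output that these pipelines consume (`Base
#' Sequence`, `Protein Accession`, `QValue`, a `Decoy/Contaminant/Target`
#' column where targets are `"T"`, and a glycosite-localization level column);
#' every binding is overridable because column names drift between search
#' engine versions. Site glycans are encoded in one column as
#' `pos:composition` pairs separated by `";"`, positions 1-based and
#' peptide-relative.
#'
#' @param peptide,protein_accession,q_value,target_decoy,localization_level,site_glycans,file_name
#'   Column names in the file.
#' @param delimiter Field delimiter (single character).
#' @param target_value,decoy_value Values of the target/decoy column.
#' @return A `psm_dialect` list.
#' @export
psm_dialect <- function(peptide = "Base Sequence",
                        protein_accession = "Protein Accession",
                        q_value = "QValue",
                        target_decoy = "Decoy/Contaminant/Target",
                        localization_level = "GlycanLocalizationLevel",
                        site_glycans = "Localized Glycans",
                        file_name = "File Name",
                        delimiter = "\t",
                        target_value = "T",
                        decoy_value = "D") {
  stopifnot(nchar(delimiter) == 1L)
  structure(list(
    columns = c(peptide = peptide, protein_accession = protein_accession,
                q_value = q_value, target_decoy = target_decoy,
                localization_level = localization_level,
                site_glycans = site_glycans, file_name = file_name),
    delimiter = delimiter,
    target_value = target_value,
    decoy_value = decoy_value
  ), class = "psm_dialect")
}

# "4:HexNAc(1);7:HexNAc(1)Hex(1)" -> named character vector c(`4` = ..., `7` = ...)
parse_site_glycans <- function(x) {
  if (is.na(x) || !nzchar(x)) {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(x, ";", fixed = TRUE)[[1]]
  pieces <- regmatches(parts, regexec("^\\s*([0-9]+)\\s*:\\s*(\\S+)\\s*$", parts))
  bad <- vapply(pieces, length, 0L) != 3L
  if (any(bad)) {
    stop("malformed site glycan token: ", sQuote(parts[bad][1]), call. = FALSE)
  }
  pos <- vapply(pieces, `[`, "", 2L)
  comp <- vapply(pieces, `[`, "", 3L)
  stats::setNames(comp, pos)
}

format_site_glycans <- function(sites) {
  if (length(sites) == 0) return("")
  ord <- order(as.integer(names(sites)))
  paste0(names(sites)[ord], ":", sites[ord], collapse = ";")
}

#' Read a glycopeptide PSM table
#'
#' One row per glycopeptide-spectrum match. Rows violating the structural
#' invariants (glycosite outside the peptide, glycosite on a non-S/T residue,
#' bad q-value, too many glycans) are rejected with row-numbered diagnostics
#' in the `rejected` attribute and a warning — never silently dropped. Sample
#' metadata (enzyme, substrate, sialidase, replicate, timepoint) is joined
#' from a sidecar sample sheet keyed by file name.
#'
#' @param path PSM table file.
#' @param dialect Column bindings; see [psm_dialect()].
#' @param sample_sheet Optional tibble from [read_sample_sheet()].
#' @param max_glycans Per-peptide maximum glycan count.
#' @return Tibble of PSMs (attributes: `rejected`, a tibble of row/reason
#'   diagnostics).
#' @export
read_psm_table <- function(path, dialect = psm_dialect(), sample_sheet = NULL,
                           max_glycans = default_glycan_database()$max_per_peptide) {
  raw <- readr::read_delim(path, delim = dialect$delimiter,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  q_raw <- raw[[dialect$columns[["q_value"]]]]
  q_num <- suppressWarnings(as.numeric(q_raw))
  psms <- tibble::tibble(
    psm_id = seq_len(nrow(raw)),
    file_name = raw[[dialect$columns[["file_name"]]]],
    peptide = raw[[dialect$columns[["peptide"]]]],
    protein_accession = raw[[dialect$columns[["protein_accession"]]]],
    start = NA_integer_,
    end = NA_integer_,
    site_glycans = lapply(raw[[dialect$columns[["site_glycans"]]]], parse_site_glycans),
    q_value = q_num,
    is_decoy = raw[[dialect$columns[["target_decoy"]]]] != dialect$target_value,
    localization_level = raw[[dialect$columns[["localization_level"]]]]
  )
  bad_q <- which(!is.na(q_raw) & nzchar(q_raw) & is.na(q_num))
  problems <- psm_row_problems(psms, max_glycans)
  if (length(bad_q) > 0) {
    problems <- dplyr::bind_rows(
      problems,
      tibble::tibble(row = bad_q, reason = "unparseable q-value")
    )
    problems <- dplyr::distinct(dplyr::arrange(problems, .data$row))
  }
  if (nrow(problems) > 0) {
    warning(nrow(problems), " PSM row(s) rejected; see attr(, \"rejected\")",
            call. = FALSE)
    psms <- psms[-problems$row, , drop = FALSE]
  }
  if (!is.null(sample_sheet)) {
    psms <- dplyr::left_join(psms, sample_sheet, by = "file_name")
  }
  attr(psms, "rejected") <- problems
  psms
}

#' Write a glycopeptide PSM table
#'
#' Inverse of [read_psm_table()]: emits the dialect's column names so that the
#' result round-trips through the reader.
#'
#' @param psms PSM tibble.
#' @param path Output file.
#' @param dialect Column bindings.
#' @return `path`, invisibly.
#' @export
write_psm_table <- function(psms, path, dialect = psm_dialect()) {
  out <- tibble::tibble(
    a = psms$file_name,
    b = psms$peptide,
    c = psms$protein_accession,
    d = format(psms$q_value, scientific = FALSE, trim = TRUE, digits = 12),
    e = ifelse(psms$is_decoy, dialect$decoy_value, dialect$target_value),
    f = psms$localization_level,
    g = vapply(psms$site_glycans, format_site_glycans, "")
  )
  names(out) <- unname(dialect$columns[c("file_name", "peptide",
                                         "protein_accession", "q_value",
                                         "target_decoy", "localization_level",
                                         "site_glycans")])
  readr::write_delim(out, path, delim = dialect$delimiter, progress = FALSE)
  invisible(path)
}

#' Read the sample sheet
#'
#' TSV with columns `file_name`, `enzyme`, `substrate`, `sialidase`,
#' `replicate`, `timepoint_h`, mapping each raw-file name to the experimental
#' condition it came from.
#'
#' @param path Sample sheet file.
#' @return Tibble with typed columns.
#' @export
read_sample_sheet <- function(path) {
  sheet <- readr::read_tsv(path, col_types = readr::cols(
    file_name = readr::col_character(),
    enzyme = readr::col_character(),
    substrate = readr::col_character(),
    sialidase = readr::col_logical(),
    replicate = readr::col_integer(),
    timepoint_h = readr::col_double()
  ), progress = FALSE)
  required <- c("file_name", "enzyme", "substrate", "sialidase", "replicate",
                "timepoint_h")
  missing_cols <- setdiff(required, names(sheet))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sheet
}

#' Write a tabular result as TSV
#'
#' Deterministic column order (as given), UTF-8. List columns holding site
#' glycans are serialised to the `pos:composition;...` encoding.
#'
#' @param x Data frame or tibble.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  for (col in names(x)) {
    if (is.list(x[[col]])) {
      x[[col]] <- vapply(x[[col]], function(v) {
        if (!is.null(names(v))) format_site_glycans(v)
        else paste(v, collapse = ";")
      }, "")
    }
  }
  readr::write_tsv(tibble::as_tibble(x), path, progress = FALSE)
  invisible(path)
}
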