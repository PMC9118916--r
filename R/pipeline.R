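# End-to-end orchestration: (optionally simulate) -> read -> filter -> map ->
# stats, with every stage output written to disk and a machine-readable run
# report.

#' Run the cleavage-specificity pipeline
#'
#' Reads substrates and a PSM table (or first simulates them when
#' `simulate_cfg` is given), applies the identification filters, maps the
#' filtered glycopeptides onto the substrates, infers cleavage events, and
#' computes the specificity statistics. All stage outputs are written as TSV
#' under `out_dir` together with a JSON report of per-stage counts, output
#' checksums, and the seed, so a run is reproducible and auditable.
#'
#' @param out_dir Output directory.
#' @param fasta,psm_table,sample_sheet Input paths (ignored when
#'   `simulate_cfg` is given; the simulated inputs are written under
#'   `out_dir/simulated` and consumed from there).
#' @param simulate_cfg Optional [simulation_config()] to generate the inputs.
#' @param filter_cfg A [filter_config()].
#' @param win_cfg A [window_config()].
#' @param control_enzyme Control (wild-type) enzyme for Dunnett comparisons;
#'   `NULL` skips them.
#' @param stats_timepoint_h Timepoint (hours) whose digests feed the motif and
#'   occurrence statistics; `NULL` pools all timepoints.
#' @param count_psms Spectrum-level instead of species-level counting in the
#'   frequency table.
#' @param dialect PSM table dialect.
#' @return The run report (list), invisibly. Report fields: `seed`, `counts`
#'   per stage, `outputs` (paths and md5 checksums), `package_version`.
#' @export
run_pipeline <- function(out_dir,
                         fasta = NULL, psm_table = NULL, sample_sheet = NULL,
                         simulate_cfg = NULL,
                         filter_cfg = filter_config(),
                         win_cfg = window_config(),
                         control_enzyme = NULL,
                         stats_timepoint_h = 24,
                         count_psms = FALSE,
                         dialect = psm_dialect()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- NULL
  if (!is.null(simulate_cfg)) {
    seed <- simulate_cfg$seed
    sim <- simulate_dataset(simulate_cfg)
    sim_paths <- write_simulation(sim, file.path(out_dir, "simulated"), dialect)
    fasta <- sim_paths[["fasta"]]
    psm_table <- sim_paths[["psms"]]
    sample_sheet <- sim_paths[["sample_sheet"]]
  }
  for (p in c(fasta, psm_table, sample_sheet)) {
    if (is.null(p) || !file.exists(p)) {
      stop("input path missing or not found: ",
           if (is.null(p)) "(NULL)" else p, call. = FALSE)
    }
  }
  proteins <- read_fasta(fasta)
  sheet <- read_sample_sheet(sample_sheet)
  psms <- read_psm_table(psm_table, dialect, sample_sheet = sheet)
  n_rejected_parse <- nrow(attr(psms, "rejected"))

  filt <- apply_filters(psms, filter_cfg)
  placed <- locate_peptides(filt$kept, proteins)
  events <- infer_cleavage_events(placed$placed, proteins, win_cfg)

  stats_events <- events
  stats_psms <- placed$placed
  if (!is.null(stats_timepoint_h) && nrow(events) > 0) {
    stats_events <- events[events$timepoint_h %in% stats_timepoint_h, ,
                           drop = FALSE]
    stats_psms <- stats_psms[stats_psms$timepoint_h %in% stats_timepoint_h, ,
                             drop = FALSE]
  }
  attribution <- if (win_cfg$keep_tryptic) c("mucinase", "tryptic") else "mucinase"
  profile <- positional_glyco_percent(stats_events, win_cfg$flank, attribution)
  freq <- peptide_frequency_table(stats_psms, count_psms)
  occ <- glycan_occurrence(stats_events, attribution = attribution)
  motif_windows <- stats_events$window[stats_events$attribution %in% attribution]
  pfm <- if (length(motif_windows) > 0) build_pfm(motif_windows, win_cfg$pad) else NULL
  dunnett <- NULL
  if (!is.null(control_enzyme) && nrow(occ$per_replicate) > 0) {
    dunnett <- tryCatch(dunnett_vs_control(occ, control_enzyme),
                        error = function(e) {
                          warning("Dunnett comparisons skipped: ",
                                  conditionMessage(e), call. = FALSE)
                          NULL
                        })
  }

  outputs <- c(
    filtered_psms = "filtered_psms.tsv",
    filter_audit = "filter_audit.tsv",
    placement_audit = "placement_audit.tsv",
    events = "events.tsv",
    motif_profile = "motif_profile.tsv",
    frequency_table = "frequency_table.tsv",
    glycan_occurrence = "glycan_occurrence.tsv",
    glycan_occurrence_summary = "glycan_occurrence_summary.tsv",
    pfm = "pfm.tsv"
  )
  outputs <- file.path(out_dir, outputs)
  names(outputs) <- c("filtered_psms", "filter_audit", "placement_audit",
                      "events", "motif_profile", "frequency_table",
                      "glycan_occurrence", "glycan_occurrence_summary", "pfm")
  write_psm_table(filt$kept, outputs[["filtered_psms"]], dialect)
  write_table(tibble::tibble(rule = names(filt$audit),
                             count = as.integer(filt$audit)),
              outputs[["filter_audit"]])
  write_table(placed$audit, outputs[["placement_audit"]])
  write_table(events, outputs[["events"]])
  write_table(profile, outputs[["motif_profile"]])
  write_table(freq, outputs[["frequency_table"]])
  write_table(occ$per_replicate, outputs[["glycan_occurrence"]])
  write_table(occ$summary, outputs[["glycan_occurrence_summary"]])
  if (!is.null(pfm)) {
    pfm_tab <- tibble::as_tibble(pfm$pfm, .name_repair = "minimal")
    names(pfm_tab) <- window_position_labels(win_cfg$flank)
    pfm_tab <- dplyr::bind_cols(tibble::tibble(residue = rownames(pfm$pfm)),
                                pfm_tab)
    pfm_tab <- dplyr::bind_rows(
      pfm_tab,
      dplyr::bind_cols(tibble::tibble(residue = "IC_bits"),
                       stats::setNames(as.data.frame(t(pfm$ic)),
                                       window_position_labels(win_cfg$flank)))
    )
    write_table(pfm_tab, outputs[["pfm"]])
  }
  if (!is.null(dunnett)) {
    outputs[["dunnett"]] <- file.path(out_dir, "dunnett.tsv")
    write_table(dunnett, outputs[["dunnett"]])
  }

  report <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("oglycospec")),
    counts = list(
      psm_rows_read = nrow(psms) + n_rejected_parse,
      psm_rows_rejected_parse = n_rejected_parse,
      psm_rows_parsed = nrow(psms),
      filter_audit = as.list(filt$audit),
      placed_unique = nrow(placed$placed),
      placed_ambiguous = nrow(placed$ambiguous),
      unmapped = sum(placed$audit$status == "unmapped"),
      events = nrow(events),
      events_mucinase = sum(events$attribution == "mucinase"),
      events_tryptic = sum(events$attribution == "tryptic"),
      stats_events = nrow(stats_events)
    ),
    outputs = lapply(stats::setNames(as.list(outputs), names(outputs)),
                     function(p) list(path = p,
                                      md5 = unname(tools::md5sum(p))))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(report)
}
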