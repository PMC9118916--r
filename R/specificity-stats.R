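# Specificity statistics: positional O-glycosylation percentages, normalized
# glycopeptide frequency tables, P1/P1' glycan-class occurrence distributions
# with replicate summaries, position frequency matrices / information content,
# and Dunnett-adjusted mutant-vs-control comparisons.

#' Positional O-glycosylation percentage profile
#'
#' For each motif position around the scissile bond, counts O-glycosylated
#' S/T residues relative to all S/T residues at that position, with serine and
#' threonine counts summed. Only positions covered by the identified peptide
#' contribute (residues across the bond from the evidencing terminus are
#' unobserved and excluded from denominators, never imputed as
#' unglycosylated). By default only mucinase-attributed events are scored.
#'
#' @param events Cleavage-event tibble from [infer_cleavage_events()].
#' @param flank Flank width used for the profile (must not exceed the window
#'   flank of the events).
#' @param attribution Attributions to include.
#' @return Tibble with one row per motif position: `position`,
#'   `n_glycosylated`, `n_st_observed`, `n_observed`, `percent`
#'   (`NA` where no S/T was observed).
#' @export
positional_glyco_percent <- function(events, flank = 4L,
                                     attribution = "mucinase") {
  labels <- window_position_labels(flank)
  empty <- tibble::tibble(position = factor(labels, levels = labels),
                          n_glycosylated = 0L, n_st_observed = 0L,
                          n_observed = 0L, percent = NA_real_)
  if (nrow(events) == 0) return(empty)
  events <- events[events$attribution %in% attribution, , drop = FALSE]
  if (nrow(events) == 0) return(empty)
  rel <- (-flank + 1L):flank
  rows <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    pos <- events$p1_index[i] + rel
    covered <- pos >= events$start[i] & pos <= events$end[i]
    pep_pos <- pos - events$start[i] + 1L
    residue <- ifelse(covered,
                      substring(events$peptide[i], pep_pos, pep_pos), NA)
    sites <- events$site_glycans[[i]]
    glyco <- covered & !is.na(match(as.character(pep_pos), names(sites)))
    rows[[i]] <- tibble::tibble(position = labels, covered = covered,
                                residue = residue, glycosylated = glyco)
  }
  long <- dplyr::bind_rows(rows)
  prof <- long |>
    dplyr::group_by(position = factor(.data$position, levels = labels)) |>
    dplyr::summarise(
      n_glycosylated = sum(.data$glycosylated),
      n_st_observed = sum(.data$covered & .data$residue %in% c("S", "T")),
      n_observed = sum(.data$covered),
      .groups = "drop"
    ) |>
    tidyr::complete(position, fill = list(n_glycosylated = 0L,
                                          n_st_observed = 0L,
                                          n_observed = 0L)) |>
    dplyr::arrange(.data$position)
  prof$percent <- ifelse(prof$n_st_observed > 0,
                         100 * prof$n_glycosylated / prof$n_st_observed,
                         NA_real_)
  prof
}

# Glycopeptide species key: peptide sequence plus its glycan multiset
# (site positions ignored, compositions sorted), matching the notion of a
# distinct O-glycopeptide rather than a distinct localisation.
glycopeptide_species <- function(peptide, site_glycans) {
  glyc <- vapply(site_glycans, function(s) {
    if (length(s) == 0) return("")
    paste(sort(canonical_glycan(unname(s))), collapse = "+")
  }, "")
  paste0(peptide, ifelse(nzchar(glyc), paste0("|", glyc), ""))
}

#' Normalized glycopeptide frequency table
#'
#' Counts distinct glycopeptide species (peptide sequence plus glycan
#' multiset) per enzyme and substrate and normalizes each count by the total
#' number of that substrate's O-glycopeptides generated by the enzyme, so
#' frequencies sum to 1 within each (enzyme, substrate) group. By default
#' repeated PSMs of the same species within a replicate collapse to one
#' (species-level counting); `count_psms = TRUE` restores spectrum-level
#' counting.
#'
#' @param psms Filtered PSM tibble with sample metadata.
#' @param count_psms Count every PSM instead of distinct species per replicate?
#' @return Tibble `enzyme`, `substrate`, `species`, `peptide`, `count`,
#'   `frequency`, ordered by descending frequency then species within group.
#' @export
peptide_frequency_table <- function(psms, count_psms = FALSE) {
  stopifnot(all(c("enzyme", "substrate") %in% names(psms)))
  tab <- psms
  tab$species <- glycopeptide_species(tab$peptide, tab$site_glycans)
  if (!count_psms) {
    rep_col <- if ("replicate" %in% names(tab)) "replicate" else NULL
    tab <- dplyr::distinct(tab[, c("enzyme", "substrate", rep_col,
                                   "species", "peptide")])
  }
  tab |>
    dplyr::count(.data$enzyme, .data$substrate, .data$species, .data$peptide,
                 name = "count") |>
    dplyr::group_by(.data$enzyme, .data$substrate) |>
    dplyr::mutate(frequency = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$enzyme, .data$substrate,
                   dplyr::desc(.data$frequency), .data$species)
}

#' Glycan-class occurrence distributions at P1 and P1'
#'
#' P1 occurrences come from C-terminal events (the only terminus where the P1
#' glycan is observed) and P1' occurrences from N-terminal events. Within each
#' (enzyme, position, replicate), observed glycans are classified and counts
#' converted to fractions over the class vocabulary (zero-count classes kept);
#' the summary reports mean and standard deviation (n - 1 denominator) across
#' replicates. Replicates with no scorable event at a position are excluded
#' from that position's summary with a warning.
#'
#' @param events Cleavage-event tibble.
#' @param classes Glycan class vocabulary.
#' @param attribution Attributions to include.
#' @return List with `per_replicate` (`enzyme`, `position`, `replicate`,
#'   `class`, `count`, `fraction`) and `summary` (`enzyme`, `position`,
#'   `class`, `mean_fraction`, `sd_fraction`, `n_replicates`).
#' @export
glycan_occurrence <- function(events, classes = default_glycan_classes(),
                              attribution = "mucinase") {
  events <- events[events$attribution %in% attribution, , drop = FALSE]
  scorable <- dplyr::bind_rows(
    events |>
      dplyr::filter(.data$terminus == "C",
                    !.data$p1_glycan %in% c("unobserved", "unglycosylated")) |>
      dplyr::transmute(.data$enzyme, position = "P1", .data$replicate,
                       glycan = .data$p1_glycan),
    events |>
      dplyr::filter(.data$terminus == "N",
                    !.data$p1prime_glycan %in% c("unobserved", "unglycosylated")) |>
      dplyr::transmute(.data$enzyme, position = "P1'", .data$replicate,
                       glycan = .data$p1prime_glycan)
  )
  class_levels <- c(classes$label, "other")
  if (nrow(scorable) == 0) {
    per_rep <- tibble::tibble(enzyme = character(0), position = character(0),
                              replicate = integer(0), class = character(0),
                              count = integer(0), fraction = numeric(0))
    return(list(per_replicate = per_rep,
                summary = tibble::tibble(enzyme = character(0),
                                         position = character(0),
                                         class = character(0),
                                         mean_fraction = numeric(0),
                                         sd_fraction = numeric(0),
                                         n_replicates = integer(0))))
  }
  scorable$class <- factor(classify_glycan(scorable$glycan, classes),
                           levels = class_levels)
  all_reps <- dplyr::distinct(events, .data$enzyme, .data$replicate)
  per_rep <- scorable |>
    dplyr::count(.data$enzyme, .data$position, .data$replicate, .data$class,
                 name = "count") |>
    tidyr::complete(tidyr::nesting(enzyme, position, replicate),
                    class = factor(class_levels, levels = class_levels),
                    fill = list(count = 0L)) |>
    dplyr::group_by(.data$enzyme, .data$position, .data$replicate) |>
    dplyr::mutate(fraction = .data$count / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::mutate(class = as.character(.data$class))
  # replicates present in the event list but with nothing scorable
  have <- dplyr::distinct(per_rep, .data$enzyme, .data$position, .data$replicate)
  expected <- tidyr::crossing(all_reps, position = c("P1", "P1'"))
  missing_reps <- dplyr::anti_join(expected, have,
                                   by = c("enzyme", "replicate", "position"))
  if (nrow(missing_reps) > 0) {
    warning(nrow(missing_reps),
            " (enzyme, position, replicate) cell(s) had no scorable events ",
            "and are excluded from the replicate summary", call. = FALSE)
  }
  summary <- per_rep |>
    dplyr::group_by(.data$enzyme, .data$position, .data$class) |>
    dplyr::summarise(mean_fraction = mean(.data$fraction),
                     sd_fraction = stats::sd(.data$fraction),
                     n_replicates = dplyr::n(), .groups = "drop")
  list(per_replicate = per_rep, summary = summary)
}

#' Position frequency matrix and information content
#'
#' Builds a 20-amino-acid position frequency matrix from equal-length motif
#' windows (pad characters excluded from denominators) and the per-position
#' information content `IC_j = log2(20) - H_j`, where `H_j` is the Shannon
#' entropy (bits) of position j — the quantity drawn by sequence-logo tools.
#' The small-sample correction used by some logo tools is available via
#' `small_sample_correction` and off by default for determinism.
#'
#' @param windows Character vector of equal-length window strings.
#' @param pad Pad character.
#' @param small_sample_correction Subtract the asymptotic small-n bias
#'   `19 / (2 ln 2 n_j)` from `IC_j`?
#' @return List with `counts` (20 x width matrix), `pfm` (column-normalised
#'   frequencies), `ic` (information content per position, bits), and
#'   `n_observed` (non-pad count per position).
#' @export
build_pfm <- function(windows, pad = "-", small_sample_correction = FALSE) {
  stopifnot(length(windows) > 0)
  widths <- nchar(windows)
  if (length(unique(widths)) != 1L) {
    stop("windows must all have the same length", call. = FALSE)
  }
  width <- widths[1]
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  mat <- matrix(0L, nrow = 20L, ncol = width, dimnames = list(aa, NULL))
  chars <- do.call(rbind, strsplit(windows, ""))
  for (j in seq_len(width)) {
    tab <- table(factor(chars[, j], levels = aa))
    mat[, j] <- as.integer(tab)
  }
  n_obs <- colSums(mat)
  pfm <- sweep(mat, 2, pmax(n_obs, 1L), "/")
  ic <- vapply(seq_len(width), function(j) {
    if (n_obs[j] == 0) return(NA_real_)
    p <- pfm[, j][pfm[, j] > 0]
    h <- -sum(p * log2(p))
    val <- log2(20) - h
    if (small_sample_correction) val <- val - 19 / (2 * log(2) * n_obs[j])
    max(val, 0)
  }, 0)
  list(counts = mat, pfm = pfm, ic = ic, n_observed = n_obs)
}

#' Dunnett many-to-one comparisons of enzymes against a control
#'
#' Compares each enzyme's per-replicate glycan-class fractions against the
#' control enzyme, separately at each position (P1, P1'). For a position, a
#' two-way enzyme x class cell-means model supplies the pooled error term, and
#' within each glycan class every non-control enzyme is compared to the
#' control with single-step multivariate-t (Dunnett) adjustment over that
#' class's comparisons. Significance stars follow the 0.05 / 0.005 / 0.0005 /
#' 0.0001 convention.
#'
#' With the minimal replication of a typical duplicate design (n = 2) these
#' tests have very low power; a warning says so.
#'
#' @param occ Output of [glycan_occurrence()] (or its `per_replicate` tibble).
#' @param control_enzyme Name of the control (wild-type) enzyme.
#' @return Tibble `position`, `class`, `enzyme`, `estimate` (mean difference
#'   from control), `p_adj`, `stars`.
#' @export
dunnett_vs_control <- function(occ, control_enzyme) {
  per_rep <- if (is.data.frame(occ)) occ else occ$per_replicate
  if (!control_enzyme %in% per_rep$enzyme) {
    stop("control enzyme ", sQuote(control_enzyme), " not present; ",
         "supply the wild-type enzyme name as spelled in the sample sheet",
         call. = FALSE)
  }
  n_rep <- per_rep |>
    dplyr::distinct(.data$enzyme, .data$position, .data$replicate) |>
    dplyr::count(.data$enzyme, .data$position)
  if (any(n_rep$n < 2)) {
    stop("every enzyme needs >= 2 replicates per position for the pooled ",
         "error term; re-run with more replicates", call. = FALSE)
  }
  if (min(n_rep$n) < 3) {
    warning("only ", min(n_rep$n), " replicates per group: Dunnett ",
            "comparisons have very low power at this replication",
            call. = FALSE)
  }
  out <- list()
  for (pos in unique(per_rep$position)) {
    d <- per_rep[per_rep$position == pos, , drop = FALSE]
    d$cell <- interaction(d$enzyme, d$class, sep = "\r", drop = TRUE)
    fit <- stats::lm(fraction ~ 0 + cell, data = d)
    sigma2 <- sum(stats::resid(fit)^2) / fit$df.residual
    cells <- levels(d$cell)
    enzymes <- setdiff(unique(d$enzyme), control_enzyme)
    for (cl in unique(d$class)) {
      ctrl_cell <- paste(control_enzyme, cl, sep = "\r")
      comps <- enzymes[paste(enzymes, cl, sep = "\r") %in% cells]
      if (!ctrl_cell %in% cells || length(comps) == 0) next
      K <- matrix(0, nrow = length(comps), ncol = length(cells),
                  dimnames = list(paste(comps, "- control"),
                                  paste0("cell", cells)))
      for (r in seq_along(comps)) {
        K[r, match(paste(comps[r], cl, sep = "\r"), cells)] <- 1
        K[r, match(ctrl_cell, cells)] <- -1
      }
      est <- drop(K %*% stats::coef(fit))
      if (sigma2 < .Machine$double.eps) {
        # degenerate zero-variance layout: identical groups are not different
        p <- ifelse(abs(est) < sqrt(.Machine$double.eps), 1, 0)
      } else {
        gl <- multcomp::glht(fit, linfct = K)
        # mvtnorm emits a harmless "lower == upper" warning for degenerate
        # integration bounds in the multivariate-t tail; keep other warnings
        p <- withCallingHandlers(
          summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues,
          warning = function(w) {
            if (grepl("lower == upper", conditionMessage(w))) {
              invokeRestart("muffleWarning")
            }
          }
        )
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        position = pos, class = cl, enzyme = comps,
        estimate = unname(est), p_adj = as.numeric(p)
      )
    }
  }
  res <- dplyr::bind_rows(out)
  res$stars <- dplyr::case_when(
    res$p_adj < 0.0001 ~ "****",
    res$p_adj < 0.0005 ~ "***",
    res$p_adj < 0.005 ~ "**",
    res$p_adj < 0.05 ~ "*",
    TRUE ~ "ns"
  )
  dplyr::arrange(res, .data$position, .data$class, .data$enzyme)
}
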