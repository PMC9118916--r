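# In-silico mucin digestion: substrate generation, glycoform assignment,
# sialidase, glycan-dependent mucinase cleavage, tryptic co-digestion, and
# emission of an identification table with known ground truth.
#
# All sampling uses R's global RNG; simulate_dataset() seeds it once from the
# config, so identical configs give byte-identical outputs.

default_glycan_distribution <- function() {
  c("Tn" = 0.30, "T" = 0.30, "sialyl-T" = 0.25, "sialyl-Tn" = 0.10,
    "disialyl-T" = 0.05)
}

# Per-class cleavage propensity weights; the bond probability for (P1, P1')
# classes is the outer product w[P1] * w[P1']. Values are illustrative (no
# per-pair efficiencies are published): the wild type cuts efficiently at
# truncated-core-1 pairs, the point mutants cut less overall and skew toward
# the Tn antigen, the strongest skew for the two hydrophobic-pocket mutants.
default_enzyme_weights <- function() {
  list(
    AM0627 = c("Tn" = 0.75, "T" = 0.75, "sialyl-T" = 0.65, "sialyl-Tn" = 0.45,
               "disialyl-T" = 0.30, "core2" = 0.30, "other" = 0.15),
    W149A = c("Tn" = 0.50, "T" = 0.28, "sialyl-T" = 0.20, "sialyl-Tn" = 0.18,
              "disialyl-T" = 0.08, "core2" = 0.10, "other" = 0.05),
    Y287A = c("Tn" = 0.60, "T" = 0.48, "sialyl-T" = 0.40, "sialyl-Tn" = 0.30,
              "disialyl-T" = 0.18, "core2" = 0.18, "other" = 0.09),
    F290A = c("Tn" = 0.40, "T" = 0.18, "sialyl-T" = 0.12, "sialyl-Tn" = 0.10,
              "disialyl-T" = 0.05, "core2" = 0.05, "other" = 0.03)
  )
}

#' Default cleavage-preference matrices
#'
#' One matrix per enzyme mapping (glycan class at P1, glycan class at P1') to
#' a per-bond cleavage probability. The wild-type enzyme prefers truncated
#' core 1 glycans (Tn/T) on both sides of the bond; the three point mutants
#' are less active overall and Tn-skewed. Values are illustrative defaults,
#' not measured efficiencies.
#'
#' @return Named list of numeric matrices (rows = P1 class, cols = P1' class).
#' @export
default_cleavage_matrices <- function() {
  lapply(default_enzyme_weights(), function(w) outer(w, w))
}

#' Simulation configuration
#'
#' Defaults describe the study design the simulator emulates: four
#' mucin-domain substrates digested by a wild-type mucinase and three point
#' mutants, duplicate digests at 24 h and 72 h, tryptic co-digestion, peptides
#' retained between 5 and 60 residues, and identification noise (decoys,
#' q-values, localization levels) so the filter chain has work to do.
#'
#' @param seed Integer seed controlling all sampling.
#' @param substrates Tibble `accession`, `length` and optionally
#'   `repeat_unit`, `copies` for tandem-repeat substrates.
#' @param st_density Target S/T fraction of generated sequences.
#' @param kr_density Target K/R fraction (tryptic site supply).
#' @param occupancy Per-site O-glycosylation probability.
#' @param glycan_dist Probability vector over glycan class labels.
#' @param sialidase_conditions Logical vector of sialidase states to simulate
#'   (`FALSE` = untreated).
#' @param sialidase_efficiency Per-glycan probability that sialidase removes
#'   all NeuAc.
#' @param enzymes Named list of cleavage-preference matrices.
#' @param require_adjacent_glycans Must both residues flanking a bond carry a
#'   glycan for cleavage?
#' @param trypsin Simulate the tryptic co-digest?
#' @param missed_cleavage_prob Per-site tryptic missed-cleavage probability.
#' @param peptide_length Retained peptide length window `c(min, max)`.
#' @param decoy_fraction Decoy rows appended per target row.
#' @param target_q_contam Fraction of target rows drawn with q-value above
#'   0.01 (identification noise).
#' @param level_probs Probability vector over localization levels.
#' @param replicates Digest replicates per condition.
#' @param timepoints_h Digest timepoints in hours.
#' @param classes Glycan class vocabulary.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              substrates = tibble::tibble(
                                accession = c("MUC16L", "PSGL1L", "PODXLL", "CD43L"),
                                length = c(600L, 400L, 500L, 400L)
                              ),
                              st_density = 0.35,
                              kr_density = 0.05,
                              occupancy = 0.8,
                              glycan_dist = default_glycan_distribution(),
                              sialidase_conditions = FALSE,
                              sialidase_efficiency = 0.95,
                              enzymes = default_cleavage_matrices(),
                              require_adjacent_glycans = TRUE,
                              trypsin = TRUE,
                              missed_cleavage_prob = 0.3,
                              peptide_length = c(5L, 60L),
                              decoy_fraction = 0.2,
                              target_q_contam = 0.05,
                              level_probs = c(Level1 = 0.85, Level1b = 0.05,
                                              Level2 = 0.07, Level3 = 0.03),
                              replicates = 2L,
                              timepoints_h = c(24, 72),
                              classes = default_glycan_classes()) {
  stopifnot(
    st_density > 0, st_density < 1, kr_density >= 0, kr_density < 1,
    st_density + kr_density < 1,
    occupancy >= 0, occupancy <= 1,
    abs(sum(glycan_dist) - 1) < 1e-8, all(glycan_dist >= 0),
    sialidase_efficiency >= 0, sialidase_efficiency <= 1,
    length(enzymes) >= 1, !is.null(names(enzymes)),
    all(vapply(enzymes, function(m) all(m >= 0 & m <= 1), TRUE)),
    peptide_length[1] >= 1, peptide_length[2] >= peptide_length[1],
    decoy_fraction >= 0, abs(sum(level_probs) - 1) < 1e-8,
    replicates >= 1
  )
  if (!all(names(glycan_dist) %in% classes$label)) {
    stop("glycan_dist names must be class labels with defined compositions",
         call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), substrates = substrates,
    st_density = st_density, kr_density = kr_density, occupancy = occupancy,
    glycan_dist = glycan_dist, sialidase_conditions = sialidase_conditions,
    sialidase_efficiency = sialidase_efficiency, enzymes = enzymes,
    require_adjacent_glycans = require_adjacent_glycans, trypsin = trypsin,
    missed_cleavage_prob = missed_cleavage_prob,
    peptide_length = as.integer(peptide_length),
    decoy_fraction = decoy_fraction, target_q_contam = target_q_contam,
    level_probs = level_probs, replicates = as.integer(replicates),
    timepoints_h = timepoints_h, classes = classes
  ), class = "simulation_config")
}

# Background residue frequencies for non-S/T, non-K/R positions, loosely
# mucin-domain-like (Pro/Ala/Gly rich; Asn kept low but non-zero so sequon
# contamination exists).
mucin_background_freqs <- function() {
  c(P = 0.22, A = 0.20, G = 0.14, V = 0.10, E = 0.06, Q = 0.06, L = 0.06,
    I = 0.04, D = 0.04, N = 0.02, H = 0.02, F = 0.02, Y = 0.02)
}

#' Generate a mucin-domain-like substrate sequence
#'
#' Either repeats a tandem-repeat unit or samples residues independently with
#' the configured S/T and K/R densities over a Pro/Ala/Gly-rich background.
#' Threonine is drawn slightly more often than serine (55/45), as in mucin
#' tandem repeats. Deterministic given the RNG state.
#'
#' @param length Sequence length (ignored when `repeat_unit` is given).
#' @param st_density,kr_density Target residue-category fractions.
#' @param repeat_unit,copies Optional tandem-repeat construction.
#' @return Amino-acid string.
#' @export
generate_mucin <- function(length, st_density = 0.35, kr_density = 0.05,
                           repeat_unit = NULL, copies = NULL) {
  if (!is.null(repeat_unit)) {
    stopifnot(!is.null(copies), copies >= 1)
    return(strrep(toupper(repeat_unit), copies))
  }
  stopifnot(length >= 1, st_density + kr_density < 1)
  bg <- mucin_background_freqs()
  residues <- c("S", "T", "K", "R", names(bg))
  probs <- c(st_density * 0.45, st_density * 0.55,
             kr_density * 0.5, kr_density * 0.5,
             (1 - st_density - kr_density) * bg / sum(bg))
  paste(sample(residues, length, replace = TRUE, prob = probs), collapse = "")
}

#' Assign a glycoform to a substrate
#'
#' Each S/T residue is independently glycosylated with probability
#' `occupancy`; the glycan class is sampled from `glycan_dist` and the class's
#' defining composition attached. Non-S/T residues are never glycosylated.
#'
#' @param sequence Substrate sequence.
#' @param occupancy Per-site glycosylation probability.
#' @param glycan_dist Probability vector over class labels.
#' @param classes Class vocabulary supplying compositions.
#' @return Named character vector: names are 1-based site positions, values
#'   canonical composition strings.
#' @export
assign_glycans <- function(sequence, occupancy = 0.8,
                           glycan_dist = default_glycan_distribution(),
                           classes = default_glycan_classes()) {
  comp_of <- stats::setNames(classes$composition, classes$label)
  chars <- strsplit(sequence, "")[[1]]
  st_pos <- which(chars %in% c("S", "T"))
  if (length(st_pos) == 0 || occupancy == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  occupied <- st_pos[stats::runif(length(st_pos)) < occupancy]
  if (length(occupied) == 0) {
    return(stats::setNames(character(0), character(0)))
  }
  labels <- sample(names(glycan_dist), length(occupied), replace = TRUE,
                   prob = glycan_dist)
  stats::setNames(unname(comp_of[labels]), as.character(occupied))
}

#' Simulate sialidase treatment of a glycoform
#'
#' Each NeuAc-containing glycan independently loses all its NeuAc with
#' probability `efficiency` (the treatment acts per glycan, not per residue).
#' `efficiency = 1` removes every NeuAc; `efficiency = 0` is the identity.
#'
#' @param glycoform Named composition vector from [assign_glycans()].
#' @param efficiency Per-glycan desialylation probability.
#' @return Glycoform with treated glycans desialylated.
#' @export
simulate_sialidase <- function(glycoform, efficiency) {
  if (length(glycoform) == 0) return(glycoform)
  has_neuac <- vapply(glycoform, function(g) {
    counts <- parse_glycan_string(g)
    !is.na(counts["NeuAc"]) && counts[["NeuAc"]] > 0
  }, TRUE)
  treat <- has_neuac & stats::runif(length(glycoform)) < efficiency
  glycoform[treat] <- desialylate(glycoform[treat])
  glycoform
}

#' Simulate mucinase cleavage
#'
#' A bond between residues i and i+1 is cleavable iff both residues are S or T
#' and (when `require_adjacent_glycans`) both carry a glycan. A cleavable bond
#' is cut independently with probability `C[class(P1), class(P1')]`, where
#' classes missing from the matrix fall back to `"other"` (or
#' `"unglycosylated"` for bare S/T when adjacency is not required; absent
#' fallback rows give probability 0).
#'
#' @param sequence Substrate sequence.
#' @param glycoform Named composition vector.
#' @param cleavage_matrix Class-by-class probability matrix.
#' @param require_adjacent_glycans Must both flanking residues be glycosylated?
#' @param classes Class vocabulary.
#' @return Integer vector of cut positions (P1 indices), sorted.
#' @export
simulate_mucinase <- function(sequence, glycoform, cleavage_matrix,
                              require_adjacent_glycans = TRUE,
                              classes = default_glycan_classes()) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (n < 2) return(integer(0))
  class_at <- rep(NA_character_, n)
  if (length(glycoform) > 0) {
    pos <- as.integer(names(glycoform))
    class_at[pos] <- classify_glycan(unname(glycoform), classes)
  }
  lookup <- function(lbl, dimnames_) {
    if (is.na(lbl)) lbl <- "unglycosylated"
    if (lbl %in% dimnames_) lbl else if ("other" %in% dimnames_ && !is.na(lbl) &&
                                         lbl != "unglycosylated") "other" else NA
  }
  cuts <- integer(0)
  for (i in seq_len(n - 1L)) {
    if (!(chars[i] %in% c("S", "T")) || !(chars[i + 1L] %in% c("S", "T"))) next
    gly_i <- !is.na(class_at[i])
    gly_j <- !is.na(class_at[i + 1L])
    if (require_adjacent_glycans && !(gly_i && gly_j)) next
    r <- lookup(class_at[i], rownames(cleavage_matrix))
    cc <- lookup(class_at[i + 1L], colnames(cleavage_matrix))
    p <- if (is.na(r) || is.na(cc)) 0 else cleavage_matrix[r, cc]
    if (p > 0 && stats::runif(1) < p) cuts <- c(cuts, i)
  }
  cuts
}

# Cut positions (bond after each index) -> fragment coordinate tibble.
fragments_from_cuts <- function(n, cuts) {
  bounds <- sort(unique(c(0L, cuts, n)))
  tibble::tibble(start = utils::head(bounds, -1) + 1L, end = bounds[-1])
}

#' Simulate the tryptic co-digest
#'
#' Cleaves C-terminal to K or R except before proline; each eligible site is
#' independently missed with probability `missed_prob`. Operates on fragments
#' so a prior mucinase digest is refined in place.
#'
#' @param fragments Tibble `start`, `end` (protein coordinates).
#' @param sequence Protein sequence.
#' @param missed_prob Per-site missed-cleavage probability.
#' @return Refined fragment tibble; attribute `cuts` holds the realised
#'   tryptic cut positions.
#' @export
simulate_trypsin <- function(fragments, sequence, missed_prob = 0.3) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  out <- vector("list", nrow(fragments))
  all_cuts <- integer(0)
  for (i in seq_len(nrow(fragments))) {
    s <- fragments$start[i]
    e <- fragments$end[i]
    candidates <- s:(e - 1L)
    candidates <- candidates[candidates >= 1L & candidates < e]
    eligible <- candidates[chars[candidates] %in% c("K", "R") &
                           chars[candidates + 1L] != "P"]
    cut <- eligible[stats::runif(length(eligible)) >= missed_prob]
    all_cuts <- c(all_cuts, cut)
    bounds <- sort(unique(c(s - 1L, cut, e)))
    out[[i]] <- tibble::tibble(start = utils::head(bounds, -1) + 1L,
                               end = bounds[-1])
  }
  res <- dplyr::bind_rows(out)
  attr(res, "cuts") <- sort(all_cuts)
  res
}

# One digest condition -> target PSM rows + per-condition truth.
digest_condition <- function(sequence, glycoform, cleavage_matrix, cfg) {
  cuts <- simulate_mucinase(sequence, glycoform, cleavage_matrix,
                            cfg$require_adjacent_glycans, cfg$classes)
  frags <- fragments_from_cuts(nchar(sequence), cuts)
  tryp_cuts <- integer(0)
  if (cfg$trypsin) {
    frags <- simulate_trypsin(frags, sequence, cfg$missed_cleavage_prob)
    tryp_cuts <- attr(frags, "cuts")
  }
  frags$peptide <- substring(sequence, frags$start, frags$end)
  frags$length <- frags$end - frags$start + 1L
  site_pos <- as.integer(names(glycoform))
  frags$site_glycans <- lapply(seq_len(nrow(frags)), function(i) {
    inside <- site_pos >= frags$start[i] & site_pos <= frags$end[i]
    stats::setNames(unname(glycoform[inside]),
                    as.character(site_pos[inside] - frags$start[i] + 1L))
  })
  n_glycans <- vapply(frags$site_glycans, length, 0L)
  frags$retained <- frags$length >= cfg$peptide_length[1] &
    frags$length <= cfg$peptide_length[2] &
    n_glycans >= 1L & n_glycans <= 4L
  list(fragments = frags, mucinase_cuts = cuts, tryptic_cuts = tryp_cuts)
}

sample_q_target <- function(n, contam) {
  above <- stats::runif(n) < contam
  ifelse(above, stats::runif(n, 0.01, 0.05), stats::runif(n, 0, 0.0099))
}

sample_q_decoy <- function(n) {
  above <- stats::runif(n) < 0.7
  ifelse(above, stats::runif(n, 0.01, 0.5), stats::runif(n, 0, 0.0099))
}

#' Simulate a full digestion study
#'
#' Generates the substrates, assigns glycoforms (one per substrate and
#' sialidase state), digests each substrate with every enzyme for every
#' replicate and timepoint, applies the tryptic co-digest and the retained
#' peptide-length window, and emits an identification table in the pipeline's
#' PSM dialect together with decoys, q-values, localization levels, a sample
#' sheet, and the full ground truth.
#'
#' @param cfg A [simulation_config()].
#' @return List with `proteins`, `psms`, `sample_sheet`, and `truth`
#'   (glycoforms, per-condition mucinase/tryptic cut sets, fragment table).
#' @export
simulate_dataset <- function(cfg = simulation_config()) {
  set.seed(cfg$seed)
  subs <- cfg$substrates
  proteins <- tibble::tibble(
    accession = subs$accession,
    description = paste("synthetic mucin-domain substrate,",
                        subs$length, "aa"),
    sequence = vapply(seq_len(nrow(subs)), function(i) {
      ru <- if ("repeat_unit" %in% names(subs)) subs$repeat_unit[i] else NULL
      cp <- if ("copies" %in% names(subs)) subs$copies[i] else NULL
      if (!is.null(ru) && !is.na(ru)) {
        generate_mucin(NA, repeat_unit = ru, copies = cp)
      } else {
        generate_mucin(subs$length[i], cfg$st_density, cfg$kr_density)
      }
    }, "")
  )
  # one glycoform per substrate x sialidase state (treatment precedes digestion)
  glycoforms <- list()
  for (i in seq_len(nrow(proteins))) {
    base <- assign_glycans(proteins$sequence[i], cfg$occupancy,
                           cfg$glycan_dist, cfg$classes)
    for (sial in cfg$sialidase_conditions) {
      gf <- if (sial) simulate_sialidase(base, cfg$sialidase_efficiency) else base
      glycoforms[[paste(proteins$accession[i], sial, sep = "|")]] <- gf
    }
  }
  rows <- list()
  truth_cuts <- list()
  truth_frags <- list()
  for (enz in names(cfg$enzymes)) {
    for (i in seq_len(nrow(proteins))) {
      for (sial in cfg$sialidase_conditions) {
        gf <- glycoforms[[paste(proteins$accession[i], sial, sep = "|")]]
        for (tp in cfg$timepoints_h) {
          for (rep_ in seq_len(cfg$replicates)) {
            dg <- digest_condition(proteins$sequence[i], gf,
                                   cfg$enzymes[[enz]], cfg)
            fn <- sprintf("%s_%s_%s_rep%d_%gh", enz, proteins$accession[i],
                          if (sial) "sia" else "nosia", rep_, tp)
            kept <- dg$fragments[dg$fragments$retained, , drop = FALSE]
            n_t <- nrow(kept)
            cond <- tibble::tibble(
              file_name = fn, enzyme = enz,
              substrate = proteins$accession[i], sialidase = sial,
              replicate = rep_, timepoint_h = tp
            )
            if (n_t > 0) {
              targets <- tibble::tibble(
                file_name = fn,
                peptide = kept$peptide,
                protein_accession = proteins$accession[i],
                start = kept$start, end = kept$end,
                site_glycans = kept$site_glycans,
                q_value = sample_q_target(n_t, cfg$target_q_contam),
                is_decoy = FALSE,
                localization_level = sample(names(cfg$level_probs), n_t,
                                            replace = TRUE,
                                            prob = cfg$level_probs)
              )
              n_d <- round(cfg$decoy_fraction * n_t)
              if (n_d > 0) {
                src <- sample.int(n_t, n_d, replace = TRUE)
                rev_pep <- vapply(kept$peptide[src], function(p) {
                  paste(rev(strsplit(p, "")[[1]]), collapse = "")
                }, "", USE.NAMES = FALSE)
                rev_sites <- lapply(src, function(j) {
                  s <- kept$site_glycans[[j]]
                  len <- nchar(kept$peptide[j])
                  stats::setNames(unname(s),
                                  as.character(len - as.integer(names(s)) + 1L))
                })
                decoys <- tibble::tibble(
                  file_name = fn, peptide = rev_pep,
                  protein_accession = paste0("DECOY_", proteins$accession[i]),
                  start = NA_integer_, end = NA_integer_,
                  site_glycans = rev_sites,
                  q_value = sample_q_decoy(n_d),
                  is_decoy = TRUE,
                  localization_level = sample(names(cfg$level_probs), n_d,
                                              replace = TRUE,
                                              prob = cfg$level_probs)
                )
                targets <- dplyr::bind_rows(targets, decoys)
              }
              rows[[length(rows) + 1L]] <- dplyr::bind_cols(
                targets,
                cond[rep(1L, nrow(targets)),
                     c("enzyme", "substrate", "sialidase", "replicate",
                       "timepoint_h")]
              )
            }
            truth_cuts[[length(truth_cuts) + 1L]] <- dplyr::bind_rows(
              dplyr::bind_cols(cond,
                tibble::tibble(type = rep("mucinase", length(dg$mucinase_cuts)),
                               p1_index = dg$mucinase_cuts)),
              dplyr::bind_cols(cond,
                tibble::tibble(type = rep("tryptic", length(dg$tryptic_cuts)),
                               p1_index = dg$tryptic_cuts))
            )
            truth_frags[[length(truth_frags) + 1L]] <- dplyr::bind_cols(
              cond[rep(1L, nrow(dg$fragments)), ],
              dg$fragments[, c("start", "end", "length", "retained")]
            )
          }
        }
      }
    }
  }
  psms <- dplyr::bind_rows(rows)
  psms <- dplyr::bind_cols(tibble::tibble(psm_id = seq_len(nrow(psms))), psms)
  sample_sheet <- psms |>
    dplyr::distinct(.data$file_name, .data$enzyme, .data$substrate,
                    .data$sialidase, .data$replicate, .data$timepoint_h)
  list(proteins = proteins, psms = psms, sample_sheet = sample_sheet,
       truth = list(glycoforms = glycoforms,
                    cuts = dplyr::bind_rows(truth_cuts),
                    fragments = dplyr::bind_rows(truth_frags)))
}

#' Write a simulated dataset to disk
#'
#' Emits `substrates.fasta`, `psms.tsv` (pipeline PSM dialect),
#' `sample_sheet.tsv`, and `ground_truth.json`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @param dialect PSM dialect for `psms.tsv`.
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir, dialect = psm_dialect()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    fasta = file.path(dir, "substrates.fasta"),
    psms = file.path(dir, "psms.tsv"),
    sample_sheet = file.path(dir, "sample_sheet.tsv"),
    ground_truth = file.path(dir, "ground_truth.json")
  )
  write_fasta(sim$proteins, paths[["fasta"]])
  write_psm_table(sim$psms, paths[["psms"]], dialect)
  write_table(sim$sample_sheet, paths[["sample_sheet"]])
  truth <- list(
    glycoforms = lapply(sim$truth$glycoforms, as.list),
    cuts = sim$truth$cuts,
    fragments = sim$truth$fragments
  )
  jsonlite::write_json(truth, paths[["ground_truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
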