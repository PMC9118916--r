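test_that("substrate generation honours repeats, determinism, and densities", {
  rep10 <- generate_mucin(NA, repeat_unit = "PTTTPLK", copies = 10)
  expect_equal(nchar(rep10), 70L)
  st <- sum(strsplit(rep10, "")[[1]] %in% c("S", "T"))
  expect_equal(st / 70, 3 / 7, tolerance = 1e-12)

  set.seed(5); a <- generate_mucin(500, 0.35, 0.05)
  set.seed(5); b <- generate_mucin(500, 0.35, 0.05)
  expect_identical(a, b)

  set.seed(6)
  long <- generate_mucin(1000, 0.4, 0.05)
  frac <- sum(strsplit(long, "")[[1]] %in% c("S", "T")) / 1000
  expect_gte(frac, 0.35); expect_lte(frac, 0.45)
})

test_that("glycoform assignment follows the occupancy and class distribution", {
  seq_ <- strrep("TA", 400)   # 400 isolated T sites
  set.seed(7)
  full <- assign_glycans(seq_, occupancy = 1)
  expect_length(full, 400L)
  expect_true(all(strsplit(seq_, "")[[1]][as.integer(names(full))] == "T"))
  none <- assign_glycans(seq_, occupancy = 0)
  expect_length(none, 0L)
  set.seed(8)
  half <- assign_glycans(seq_, occupancy = 0.5)
  ci <- qbinom(c(0.005, 0.995), 400, 0.5)
  expect_gte(length(half), ci[1]); expect_lte(length(half), ci[2])
})

test_that("sialidase removes NeuAc per glycan at the configured efficiency", {
  gf <- setNames(rep("HexNAc(1)Hex(1)NeuAc(1)", 200), seq(1, 399, 2))
  set.seed(9)
  all_gone <- simulate_sialidase(gf, 1)
  expect_false(any(grepl("NeuAc", all_gone)))
  expect_identical(simulate_sialidase(gf, 0), gf)
  set.seed(10)
  half <- simulate_sialidase(gf, 0.5)
  n_desial <- sum(!grepl("NeuAc", half))
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(n_desial, ci[1]); expect_lte(n_desial, ci[2])
})

test_that("mucinase cleavage follows the adjacent-glycan rule", {
  Cmat <- matrix(1, 1, 1, dimnames = list("Tn", "Tn"))
  gf <- c(`4` = "HexNAc(1)", `5` = "HexNAc(1)")
  set.seed(11)
  expect_equal(simulate_mucinase("PAQTTPAK", gf, Cmat), 4L)
  # one bare partner blocks the bond
  expect_equal(simulate_mucinase("PAQTTPAK", gf[1], Cmat), integer(0))
  # non-S/T neighbours never qualify even when glycosylated
  gf2 <- c(`4` = "HexNAc(1)")
  expect_equal(simulate_mucinase("PAQTAPAK", gf2, Cmat), integer(0))
})

test_that("probability-1 cut sets equal brute-force enumeration (oracle)", {
  classes <- default_glycan_classes()
  all_one <- matrix(1, nrow(classes) + 1, nrow(classes) + 1,
                    dimnames = list(c(classes$label, "other"),
                                    c(classes$label, "other")))
  set.seed(12)
  for (i in 1:20) {
    seq_ <- generate_mucin(300, 0.35, 0.05)
    gf <- assign_glycans(seq_, occupancy = 0.7)
    cuts <- simulate_mucinase(seq_, gf, all_one)
    expect_identical(cuts, enumerate_qualifying_bonds(seq_, gf))
  }
})

test_that("tryptic digestion matches the rule-based split oracle", {
  frag <- tibble::tibble(start = 1L, end = 7L)
  set.seed(13)
  cut0 <- simulate_trypsin(frag, "AKRPSTK", missed_prob = 0)
  expect_equal(substring("AKRPSTK", cut0$start, cut0$end), c("AK", "RPSTK"))
  all_missed <- simulate_trypsin(frag, "AKRPSTK", missed_prob = 1)
  expect_equal(nrow(all_missed), 1L)
  for (i in 1:100) {
    seq_ <- generate_mucin(50, 0.3, 0.15)
    f <- simulate_trypsin(tibble::tibble(start = 1L, end = 50L), seq_,
                          missed_prob = 0)
    expect_equal(substring(seq_, f$start, f$end), trypsin_split_oracle(seq_))
  }
})

test_that("fragments tile the substrate exactly once and retention is correct", {
  cfg <- simulation_config(
    seed = 19L,
    substrates = tibble::tibble(accession = "SUB1", length = 400L),
    replicates = 1L, timepoints_h = 24,
    enzymes = default_cleavage_matrices()["AM0627"]
  )
  sim <- simulate_dataset(cfg)
  frags <- sim$truth$fragments
  for (fn in unique(frags$file_name)) {
    f <- frags[frags$file_name == fn, ]
    f <- f[order(f$start), ]
    expect_equal(f$start[1], 1L)
    expect_equal(f$end[nrow(f)], 400L)
    expect_true(all(f$start[-1] == utils::head(f$end, -1) + 1L))
  }
  # retained targets in the PSM table obey the length window and glycan cap
  targets <- sim$psms[!sim$psms$is_decoy, ]
  len <- nchar(targets$peptide)
  expect_true(all(len >= 5 & len <= 60))
  n_gly <- vapply(targets$site_glycans, length, 0L)
  expect_true(all(n_gly >= 1 & n_gly <= 4))
  # decoys appended at the configured fraction per condition
  per_cond <- dplyr::count(sim$psms, file_name, is_decoy) |>
    tidyr::pivot_wider(names_from = is_decoy, values_from = n, values_fill = 0L)
  expect_equal(per_cond[["TRUE"]], round(0.2 * per_cond[["FALSE"]]))
})

test_that("identical configurations produce byte-identical outputs", {
  cfg <- simulation_config(
    seed = 23L,
    substrates = tibble::tibble(accession = c("S1", "S2"),
                                length = c(200L, 250L)),
    replicates = 2L, timepoints_h = 24,
    enzymes = default_cleavage_matrices()[c("AM0627", "W149A")]
  )
  sim1 <- simulate_dataset(cfg)
  sim2 <- simulate_dataset(cfg)
  expect_identical(sim1$psms, sim2$psms)
  expect_identical(sim1$truth$cuts, sim2$truth$cuts)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_simulation(sim1, d1)
  p2 <- write_simulation(sim2, d2)
  for (k in names(p1)) {
    expect_identical(unname(tools::md5sum(p1[[k]])),
                     unname(tools::md5sum(p2[[k]])), label = k)
  }
})

test_that("Tn-skewed and T-skewed enzymes order pipeline Tn fractions correctly", {
  classes <- default_glycan_classes()
  lbl <- c(classes$label, "other")
  w_tn <- setNames(c(0.9, 0.2, 0.1, 0.1, 0.05, 0.05, 0.02), lbl)
  w_t <- setNames(c(0.2, 0.9, 0.1, 0.1, 0.05, 0.05, 0.02), lbl)
  cfg <- simulation_config(
    seed = 29L,
    substrates = tibble::tibble(accession = "SUB1", length = 1500L),
    glycan_dist = c(Tn = 0.5, T = 0.5),
    enzymes = list(TnWard = outer(w_tn, w_tn), TWard = outer(w_t, w_t)),
    replicates = 2L, timepoints_h = 24,
    decoy_fraction = 0, target_q_contam = 0, level_probs = c(Level1 = 1)
  )
  sim <- simulate_dataset(cfg)
  filt <- apply_filters(sim$psms)
  placed <- locate_peptides(filt$kept, sim$proteins)
  ev <- infer_cleavage_events(placed$placed, sim$proteins)
  occ <- suppressWarnings(glycan_occurrence(ev))
  tn <- occ$summary[occ$summary$class == "Tn" & occ$summary$position == "P1'", ]
  expect_gt(tn$mean_fraction[tn$enzyme == "TnWard"],
            tn$mean_fraction[tn$enzyme == "TWard"])
})
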