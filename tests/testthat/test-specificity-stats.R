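test_that("positional glycosylation percent counts modified over total S/T", {
  prot <- "GAVPAQTTSPAKGAV"
  # three C-terminal events whose covered P1 residues are T(glyco), S(bare),
  # T(glyco)
  ev <- dplyr::bind_rows(
    make_event("C", 8, start = 4, end = 8, peptide = "PAQTT",
               site_glycans = c(`5` = "HexNAc(1)"), protein = prot,
               p1_glycan = "HexNAc(1)"),
    make_event("C", 9, start = 5, end = 9, peptide = "AQTTS",
               site_glycans = setNames(character(0), character(0)),
               protein = prot),
    make_event("C", 7, start = 4, end = 7, peptide = "PAQT",
               site_glycans = c(`4` = "HexNAc(1)"), protein = prot,
               p1_glycan = "HexNAc(1)")
  )
  prof <- positional_glyco_percent(ev, flank = 4)
  p1 <- prof[prof$position == "P1", ]
  expect_equal(p1$n_glycosylated, 2L)
  expect_equal(p1$n_st_observed, 3L)
  expect_equal(p1$percent, 100 * 2 / 3, tolerance = 1e-12)
  # positions beyond the peptide are unobserved, not imputed: P1' of a
  # C-terminal event contributes nothing
  p1p <- prof[prof$position == "P1'", ]
  expect_equal(p1p$n_observed, 0L)
  expect_true(is.na(p1p$percent))
})

test_that("positional percent handles empty input and event-order invariance", {
  empty <- positional_glyco_percent(make_event("C", 4, 1, 4, "PAQT")[0, ])
  expect_true(all(is.na(empty$percent)))
  ev <- dplyr::bind_rows(
    make_event("C", 4, start = 1, end = 4, peptide = "PAQT",
               site_glycans = c(`4` = "HexNAc(1)"), p1_glycan = "HexNAc(1)"),
    make_event("N", 4, start = 5, end = 8, peptide = "TPAK",
               site_glycans = c(`1` = "HexNAc(1)"),
               p1prime_glycan = "HexNAc(1)")
  )
  expect_equal(positional_glyco_percent(ev),
               positional_glyco_percent(ev[2:1, ]))
})

test_that("peptide frequencies are normalized within (enzyme, substrate)", {
  psms <- make_psms(
    make_psm("AAATT", c(`4` = "HexNAc(1)"), replicate = 1L),
    make_psm("AAATT", c(`4` = "HexNAc(1)"), replicate = 2L),
    make_psm("AAATT", c(`4` = "HexNAc(1)"), replicate = 2L),  # dup within rep
    make_psm("GGGST", c(`5` = "HexNAc(1)"), replicate = 1L),
    make_psm("CCCCT", c(`5` = "HexNAc(1)"), enzyme = "W149A")
  )
  ft <- peptide_frequency_table(psms)
  am <- ft[ft$enzyme == "AM0627", ]
  # species-level default: the duplicate PSM within replicate 2 collapses
  expect_equal(sum(am$count), 3L)
  expect_equal(am$frequency[am$peptide == "AAATT"], 2 / 3)
  expect_equal(sum(am$frequency), 1)
  # groups never share denominators
  expect_equal(ft$frequency[ft$enzyme == "W149A"], 1)
  # spectrum-level counting restores the raw PSM count
  ft2 <- peptide_frequency_table(psms, count_psms = TRUE)
  expect_equal(sum(ft2$count[ft2$enzyme == "AM0627"]), 4L)
})

test_that("identical peptides with different glycans are distinct species", {
  psms <- make_psms(
    make_psm("AAATT", c(`4` = "HexNAc(1)")),
    make_psm("AAATT", c(`4` = "HexNAc(1)Hex(1)"))
  )
  ft <- peptide_frequency_table(psms)
  expect_equal(nrow(ft), 2L)
  expect_equal(ft$frequency, c(0.5, 0.5))
})

test_that("glycan occurrences give per-replicate fractions and summaries", {
  mk <- function(gly, rep_) {
    make_event("N", 4, start = 5, end = 9, peptide = "TPAKG",
               site_glycans = c(`1` = gly), protein = "PAQTTPAKG",
               p1prime_glycan = gly, replicate = rep_)
  }
  ev <- dplyr::bind_rows(
    mk("HexNAc(1)", 1L), mk("HexNAc(1)", 1L),
    mk("HexNAc(1)Hex(1)", 1L), mk("HexNAc(1)Hex(1)NeuAc(1)", 1L),
    mk("HexNAc(1)", 2L), mk("HexNAc(1)", 2L),
    mk("HexNAc(1)Hex(1)", 2L), mk("HexNAc(1)Hex(1)NeuAc(1)", 2L)
  )
  occ <- suppressWarnings(glycan_occurrence(ev))  # N-only events: no P1 cells
  r1 <- occ$per_replicate[occ$per_replicate$replicate == 1L, ]
  expect_equal(r1$fraction[r1$class == "Tn"], 0.5)
  expect_equal(r1$fraction[r1$class == "T"], 0.25)
  expect_equal(r1$fraction[r1$class == "sialyl-T"], 0.25)
  expect_equal(sum(r1$fraction), 1)
  # zero-count classes stay in the table
  expect_true("core2" %in% r1$class)
  expect_equal(r1$fraction[r1$class == "core2"], 0)
  # identical replicates: sd = 0 everywhere
  expect_true(all(occ$summary$sd_fraction == 0))
  expect_true(all(occ$summary$n_replicates == 2L))
})

test_that("PFM information content matches hand-computed entropies", {
  res <- build_pfm(rep("QTTP", 5))
  expect_equal(res$ic, rep(log2(20), 4), tolerance = 1e-12)
  # a position uniform over the 20 residues has zero information
  uni <- build_pfm(strsplit(paste0("ACDEFGHIKLMNPQRSTVWY"), "")[[1]])
  expect_equal(uni$ic, 0, tolerance = 1e-12)
  # entropy 1 bit at position 1 for {"QTTP","ATTP"}
  two <- build_pfm(c("QTTP", "ATTP"))
  expect_equal(two$ic[1], log2(20) - 1, tolerance = 1e-12)
  expect_equal(two$ic[2], log2(20), tolerance = 1e-12)
  # frequencies are column-normalised with pads excluded
  pad <- build_pfm(c("-TTP", "ATTP"))
  expect_equal(pad$n_observed[1], 1)
  expect_equal(sum(pad$pfm[, 1]), 1)
  expect_error(build_pfm(c("QTTP", "QT")), "same length")
})

test_that("Dunnett comparisons: identical groups give p = 1, big shifts detect", {
  classes <- c("Tn", "T")
  base <- tidyr::crossing(
    enzyme = c("AM0627", "W149A", "Y287A", "F290A"),
    position = "P1'", replicate = 1:2, class = classes
  )
  same <- dplyr::mutate(base, fraction = ifelse(class == "Tn", 0.5, 0.5))
  res_same <- dunnett_vs_control(same, "AM0627") |> suppressWarnings()
  expect_true(all(res_same$p_adj == 1))

  shifted <- dplyr::mutate(base, fraction = dplyr::case_when(
    enzyme == "W149A" & class == "Tn" ~ c(0.60, 0.62)[replicate],
    enzyme == "W149A" & class == "T" ~ c(0.40, 0.38)[replicate],
    class == "Tn" ~ c(0.10, 0.12)[replicate],
    TRUE ~ c(0.90, 0.88)[replicate]
  ))
  res <- dunnett_vs_control(shifted, "AM0627") |> suppressWarnings()
  w_tn <- res[res$enzyme == "W149A" & res$class == "Tn", ]
  expect_lt(w_tn$p_adj, 0.05)
  expect_equal(w_tn$estimate, 0.5, tolerance = 1e-12)
  # near-control contrasts stay non-significant
  expect_gt(min(res$p_adj[res$enzyme == "Y287A"]), 0.05)

  # independent Monte-Carlo oracle: simulate the all-groups-equal null with
  # the observed within-group spread and compare the max shift from control
  mc_p <- local({
    d <- shifted[shifted$class == "Tn", ]
    obs <- abs(mean(d$fraction[d$enzyme == "W149A"]) -
                 mean(d$fraction[d$enzyme == "AM0627"]))
    resid_sd <- sqrt(mean(tapply(d$fraction, d$enzyme, stats::var)))
    set.seed(99)
    stat <- replicate(2000, {
      mu <- colMeans(matrix(rnorm(8, 0, resid_sd), nrow = 2))
      max(abs(mu[-1] - mu[1]))
    })
    mean(stat >= obs)
  })
  expect_lt(mc_p, 0.05)
})

test_that("Dunnett p-values shrink as the shift from control grows", {
  base <- tidyr::crossing(enzyme = c("AM0627", "E1", "E2", "E3"),
                          position = "P1", replicate = 1:2, class = "Tn")
  noise <- c(-0.01, 0.01)
  d <- dplyr::mutate(base, fraction = dplyr::case_when(
    enzyme == "AM0627" ~ 0.10 + noise[replicate],
    enzyme == "E1" ~ 0.15 + noise[replicate],
    enzyme == "E2" ~ 0.30 + noise[replicate],
    enzyme == "E3" ~ 0.60 + noise[replicate]
  ))
  res <- dunnett_vs_control(d, "AM0627") |> suppressWarnings()
  res <- res[order(abs(res$estimate)), ]
  expect_true(all(diff(res$p_adj) <= 1e-12))
})

test_that("Dunnett errors carry a remedy for missing control or replication", {
  d <- tidyr::crossing(enzyme = c("A", "B"), position = "P1",
                       replicate = 1:2, class = "Tn")
  d$fraction <- 0.5
  expect_error(dunnett_vs_control(d, "WT"), "control enzyme")
  single <- d[d$replicate == 1, ]
  expect_error(dunnett_vs_control(single, "A"), "replicates")
})
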