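test_that("peptides are located by exact substring search with ambiguity flags", {
  prot <- demo_proteins()
  psms <- make_psms(
    make_psm("TTPAK"),                 # unique in P1 at start 4
    make_psm("TT"),                    # P1 pos 4 and P2 pos 3/8: ambiguous
    make_psm("WWWWW")                  # absent
  )
  res <- locate_peptides(psms, prot)
  expect_equal(res$placed$psm_id, 1L)
  expect_equal(res$placed$protein_accession, "P1")
  expect_equal(res$placed$start, 4L)
  expect_equal(res$placed$end, 8L)
  expect_equal(res$audit$status, c("unique", "ambiguous", "unmapped"))
  expect_gte(res$audit$n_matches[2], 2L)
  expect_equal(res$ambiguous$psm_id, 2L)
})

test_that("cleavage events carry the observed terminus glycan and attribution", {
  prot <- tibble::tibble(accession = "P1", description = "",
                         sequence = "PAQTTPAK")
  # N-terminal evidence: "TPAK" at 5..8 ends at the protein C-terminus
  placed <- make_psms(make_psm("TPAK", c(`1` = "HexNAc(1)"),
                               start = 5L, end = 8L))
  ev <- infer_cleavage_events(placed, prot)
  expect_equal(nrow(ev), 1L)                    # no C event at protein end
  expect_equal(ev$terminus, "N")
  expect_equal(ev$p1_index, 4L)
  expect_equal(ev$p1prime_residue, "T")
  expect_equal(ev$p1prime_glycan, "HexNAc(1)")
  expect_equal(ev$p1_glycan, "unobserved")
  expect_equal(ev$attribution, "mucinase")

  # C-terminal evidence: "PAQT" at 1..4 starts at the protein N-terminus
  placed2 <- make_psms(make_psm("PAQT", c(`4` = "HexNAc(1)"),
                                start = 1L, end = 4L))
  ev2 <- infer_cleavage_events(placed2, prot)
  expect_equal(nrow(ev2), 1L)                   # no N event at protein start
  expect_equal(ev2$terminus, "C")
  expect_equal(ev2$p1_index, 4L)
  expect_equal(ev2$p1_residue, "T")
  expect_equal(ev2$p1_glycan, "HexNAc(1)")
  expect_equal(ev2$p1prime_glycan, "unobserved")

  # peptide ending in K away from the protein end is trypsin-attributed
  prot3 <- tibble::tibble(accession = "P1", description = "",
                          sequence = "PAQTKTTPA")
  placed3 <- make_psms(make_psm("PAQTK", c(`4` = "HexNAc(1)"),
                                start = 1L, end = 5L))
  ev3 <- infer_cleavage_events(placed3, prot3)
  expect_equal(ev3$terminus, "C")
  expect_equal(ev3$attribution, "tryptic")
})

test_that("motif windows use fixed width with pad characters at the termini", {
  expect_equal(extract_window("PAQTTPAK", 4, flank = 2), "QTTP")
  expect_equal(extract_window("PAQTTPAK", 1, flank = 3), "--PAQT")
  expect_equal(extract_window("PAQTTPAK", 7, flank = 3), "TPAK--")
  expect_equal(nchar(extract_window(strrep("A", 50), 25, flank = 4)), 8L)
  expect_error(extract_window("PAQTTPAK", 8, flank = 2), "p1_index")
  expect_error(extract_window("PAQTTPAK", 0, flank = 2), "p1_index")
  expect_equal(window_position_labels(2), c("P2", "P1", "P1'", "P2'"))
})

test_that("an interior peptide yields exactly two events that recover its bounds", {
  prot <- tibble::tibble(accession = "P1", description = "",
                         sequence = "GAVPAQTTPAKGAV")
  placed <- make_psms(make_psm("AQTTP", c(`3` = "HexNAc(1)"),
                               start = 5L, end = 9L))
  ev <- infer_cleavage_events(placed, prot)
  expect_equal(nrow(ev), 2L)
  n_ev <- ev[ev$terminus == "N", ]
  c_ev <- ev[ev$terminus == "C", ]
  # round trip: the two events encode (start, end) exactly
  expect_equal(n_ev$p1_index + 1L, placed$start)
  expect_equal(c_ev$p1_index, placed$end)
  expect_true(all(ev$p1_index >= 1 & ev$p1_index < nchar(prot$sequence)))
})

test_that("inferred mucinase cut sets match simulator ground truth (trypsin off)", {
  cfg <- strict_config(seed = 17L, length = 400L)
  sim <- simulate_dataset(cfg)
  filt <- apply_filters(sim$psms)
  placed <- locate_peptides(filt$kept, sim$proteins)
  ev <- infer_cleavage_events(placed$placed, sim$proteins)
  for (r in seq_len(cfg$replicates)) {
    truth <- sim$truth$cuts
    truth_r <- truth$p1_index[truth$type == "mucinase" & truth$replicate == r]
    frags <- sim$truth$fragments
    frags_r <- frags[frags$replicate == r & frags$retained, ]
    # only retained fragments that place uniquely on the substrate can
    # evidence a cut (multi-match peptides are excluded by design)
    seqs <- sim$proteins$sequence
    frags_r$peptide <- substring(seqs[1], frags_r$start, frags_r$end)
    n_hits <- vapply(frags_r$peptide, function(p) {
      m <- gregexpr(p, seqs[1], fixed = TRUE)[[1]]
      if (m[1] == -1L) 0L else length(m)
    }, 0L)
    uniq <- frags_r[n_hits == 1L, ]
    evidenced <- intersect(truth_r, c(uniq$end, uniq$start - 1L))
    inferred <- ev[ev$attribution == "mucinase" & ev$replicate == r, ]
    expect_setequal(unique(inferred$p1_index), evidenced)
  }
})
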