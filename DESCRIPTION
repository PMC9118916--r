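Package: oglycospec
Title: Cleavage-Specificity Analysis for Mucin-Type O-Glycoproteases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers protease cleavage-site specificity from O-glycoproteomics
    glycopeptide identification tables. Implements the post-search workflow for
    mucinase digests: target/decoy, q-value, site-localization and
    N-glycosylation-sequon filtering of glycopeptide-spectrum matches; mapping of
    glycopeptides onto substrate sequences to infer scissile bonds with P1/P1'
    context; positional O-glycosylation percentages, normalized glycopeptide
    frequency tables, P1/P1' glycan-class occurrence distributions with
    Dunnett-adjusted mutant-versus-wild-type comparisons, and position frequency
    matrices for sequence logos. Includes an in-silico mucin digestion simulator
    (glycoform assignment, sialidase, glycan-dependent mucinase cleavage, tryptic
    co-digestion) that emits identification tables with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
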