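---
title: "Inferring mucinase cleavage specificity from O-glycoproteomics identifications"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring mucinase cleavage specificity from O-glycoproteomics identifications}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oglycospec)
```

## The analysis in one paragraph

O-glycoproteases cut the backbone of mucin-domain glycoproteins only when
specific O-glycans flank the scissile bond. Their specificity is read out by
digesting defined substrates, identifying the released glycopeptides by mass
spectrometry, and asking: at which positions around the inferred cut sites
are Ser/Thr residues glycosylated, and which glycan structures sit at P1 and
P1′? `oglycospec` implements this readout as a pipeline of small, testable
stages — filter, map, infer events, summarise — plus a generative simulator
whose ground truth closes the loop on every stage.

## Data model

A glycopeptide-spectrum match (PSM) carries the peptide sequence, a map from
peptide positions to glycan compositions, a q-value, a target/decoy flag,
and a glycosite-localization confidence level. Glycan compositions use the
explicit `Name(count)` grammar (`"HexNAc(1)Hex(1)NeuAc(1)"`); classification
into antigen classes (Tn, T, sialyl-Tn, sialyl-T, disialyl-T, core2, other)
is an exact-composition lookup, not subsumption, because specificity is
reported over discrete antigen categories. Compositions outside the
vocabulary fall into `other`; linkage isomers (for example α2,3- versus
α2,6-sialylation) are not recoverable from compositions and are out of
scope. The packaged 22-entry O-glycan database mirrors the size and
per-peptide maximum (4) of the search configuration these tables come from;
its exact entries are a documented stand-in of common mucin-type
compositions.

## Filtering

Four rules, in a fixed audit order: decoys out; q-value strictly below 0.01;
only Level 1 (unambiguous) localizations; no N-glycosylation sequon
(N-X-S/T) in the peptide. Two deliberate choices:

* the q-value comparison is a **strict** inequality — a PSM at exactly 0.01
  is rejected;
* the sequon pattern is applied **literally**, so X may be proline. The
  conventional X ≠ P reading is available via
  `filter_config(sequon_allows_proline_x = FALSE)`; the default follows the
  pattern as usually written in search-tool documentation.

The kept set is the conjunction of all rules and therefore independent of
rule order; only the attribution of a rejected PSM to its first failing rule
depends on the order, which is fixed (decoy → q → level → sequon) so audits
are comparable across runs.

## From peptides to scissile bonds

Peptides are placed on the substrates by exact substring search.
Multi-match peptides — common in tandem-repeat mucin domains — are excluded
from event inference by default (`window_config(keep_ambiguous = TRUE)`
reverses this) because counting one spectrum at several repeat positions
would inflate the motif exactly where mucins are most repetitive; the count
of excluded peptides is reported in the placement audit.

Coordinates are 1-based and a scissile bond is named by the protein position
of its P1 residue. A peptide at `[start, end]` evidences the bond at
`start − 1` through its N-terminus (the first peptide residue is that bond's
P1′) and the bond at `end` through its C-terminus (the last residue is P1);
termini at the protein boundary evidence nothing. Each event observes the
glycan on its peptide-covered side only. The residue across the bond lies
outside the identified peptide, and its status is recorded as `unobserved` —
never imputed as unglycosylated — so denominators in the motif statistic
contain only residues the data actually saw.

Because the digests include a tryptic co-digest, a bond whose P1 residue is
K or R is attributed to trypsin and excluded from mucinase statistics by
default. This is an interpretive choice (the handling of tryptic termini in
published motif analyses is usually unstated); `window_config(keep_tryptic
= TRUE)` restores them, and the event table always carries the attribution
so either analysis can be reproduced.

## The statistics

**Positional glycosylation percent.** For each motif position (default
window P4…P1 | P1′…P4′; the flank is configurable since published logos do
not state their width), the statistic is `100 · glycosylated S/T / observed
S/T`, with serine and threonine pooled. N- and C-terminal events both
contribute wherever the window position is peptide-covered; a position with
no observed S/T reports `NA`, not 0.

**Frequency tables.** Distinct glycopeptide species — peptide sequence plus
glycan multiset — are counted per (enzyme, substrate) and normalised within
the group. Repeated observations of one species within a replicate collapse
to a single count by default, reading "number of generated glycopeptides"
as species rather than spectra; `count_psms = TRUE` switches to
spectrum-level counting.

**P1/P1′ glycan occurrence.** The P1 glycan is only observed on C-terminal
events and the P1′ glycan only on N-terminal events, so each position draws
from its evidencing terminus. Fractions over the class vocabulary are
computed per replicate (required for a mean ± s.d. summary across
replicates, s.d. with the n − 1 denominator), with zero-count classes kept
in the table.

**Sequence-logo input.** `build_pfm()` returns the position frequency
matrix (pads excluded from denominators) and information content
`IC_j = log2(20) − H_j` in bits, bounded by the 20-letter protein alphabet.
The small-sample correction used by some logo tools is off by default so
outputs are deterministic functions of the frequencies; a flag enables it.

**Mutant-versus-control comparisons.** Replicate class fractions enter a
two-way enzyme × glycan-class cell-means model per position; each mutant is
compared to the control within each class using the pooled residual
variance, with single-step multivariate-t (Dunnett) adjustment over the
class's comparisons — matching the per-class star placement of a
many-to-one figure panel. The adjustment family is the set of enzymes
within one class; an alternative (one family across all classes) would be
stricter, and the per-class choice matches how such panels are annotated.
With duplicate digests (n = 2) these tests have very little power, and the
function warns accordingly; zero-variance degenerate layouts return p = 1
for zero differences rather than NaN.

## The simulator

`simulate_dataset()` generates the whole study: substrates, glycoforms,
digests, and an identification table in the same dialect the reader
consumes, with complete ground truth (glycoforms, cut sets, fragment
provenance). Its defaults are the emulated study design, chosen once:

* **Design**: 4 mucin-domain substrates (400–600 aa), wild type + three
  point mutants, duplicate digests, 24 h and 72 h timepoints. Activity is
  near-maximal by 24 h, so both timepoints share per-bond probabilities and
  differ only by sampling.
* **Substrates**: random sequences at S/T density 0.35 (T:S = 55:45) and
  K/R density 0.05 over a Pro/Ala/Gly-rich background; tandem-repeat units
  are supported. Asn is rare but present, so sequon contamination exists
  for the filter to catch.
* **Glycoforms**: per-site occupancy 0.8; class mix Tn 0.30 / T 0.30 /
  sialyl-T 0.25 / sialyl-Tn 0.10 / disialyl-T 0.05, reflecting sialyl-T
  occurring at frequencies comparable to Tn and T on such substrates.
  Sialidase treatment removes all NeuAc of a glycan as one event with
  probability 0.95.
* **Cleavage**: a bond qualifies iff both flanking residues are
  glycosylated S/T (the adjacent-glycan requirement; relaxable), and is cut
  independently with probability `C[class(P1), class(P1′)]`. The packaged
  matrices are outer products of per-class weights — wild type efficient on
  Tn/T pairs, mutants less active and Tn-skewed — and are illustrative: no
  per-pair efficiencies are published. Independence per bond keeps the
  exhaustive enumeration oracle exact; there is no processivity or
  product-re-digestion kinetics.
* **Noise**: tryptic co-digest (missed-cleavage probability 0.3), retained
  peptide length 5–60, at most 4 glycans per peptide (fragments outside
  these windows are dropped, as a capped search would), decoys at 0.2 of
  target count with 70% of decoy q-values above 0.01 (so the decoy and q
  filters are separately informative), 5% of target q-values above 0.01,
  localization levels Level1 0.85 / Level1b 0.05 / Level2 0.07 / Level3
  0.03.

Everything derives from one seed; identical configurations give
byte-identical outputs.

### What the simulator does and does not emulate

It reproduces the *statistical structure* the analysis assumes: nonspecific
(mucinase) plus tryptic termini, per-site glycan compositions from a small
database, q-values, decoys, localization levels, replicate/timepoint
design. It does not emulate spectra, retention, intensity, co-isolation, or
sequence-dependent identification bias; real mucins also have correlated
(not independent) site occupancy and richer glycan heterogeneity. Passing
closed-loop tests therefore demonstrates that the pipeline's inference is
correct *given* correct identifications — not that any search engine's
identifications are correct.

## Numerical and degenerate-input choices

Windows are padded with `-` beyond protein termini and pads never enter PFM
denominators. Undefined percentages (no observed S/T) are `NA`. Replicates
with no scorable event at a position are excluded from that position's
mean ± s.d. with a warning. Peptides placed zero times are recorded as
unmapped, not errors. Rejected PSM rows keep their original file row
numbers in the diagnostics. Ties in frequency tables order
deterministically (descending frequency, then species string).

## Problem sizes used in the packaged tests

The test suite runs the full default design (about 600 PSM rows), a strict
closed-loop configuration (full occupancy, all-Tn, certain cleavage, no
trypsin or noise) where recovery must be exact, a 20,000-residue single
substrate giving over 1000 scorable P1′ events for distribution recovery
within binomial error, and 100-sequence oracle sweeps for the digestion
rules. These sizes keep each property estimable with comfortable margins
while the whole suite stays quick to run.

## Known limitations

Cleavage probabilities are per-bond and time-free; enzyme kinetics,
processivity, and substrate depletion are not modelled. Glycan classes are
composition-level only. The Dunnett layout (enzyme × class per position) is
one defensible reading of a two-way-ANOVA-with-Dunnett figure annotation;
the per-replicate fraction input is required by the mean ± s.d. replicate
summary and is the documented alternative to pooling events across
replicates before normalisation. Statistics at n = 2 are reported with a
low-power warning rather than suppressed.
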