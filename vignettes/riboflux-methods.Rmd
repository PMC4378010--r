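---
title: "Models and methods behind riboflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind riboflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

riboflux analyses bacterial ribosome-profiling (RP) and mRNA-seq libraries
at two scales — per gene and per codon — and ships a generative simulator
that provides exact ground truth for every estimator. This vignette
explains the models, the tunable parameters, the numerical choices, and
what the simulation-based tests do and do not establish about real data.

## Coordinate conventions

All genomic intervals are 0-based, half-open, with explicit strand; this is
the single conversion point for BED (already 0-based half-open) and GFF3
(1-based inclusive). Positions around the ribosome are *transcript*
offsets computed from the gene model: position 0 is the first base of the
A-site codon and the 5′ direction is negative. Reads overlapping a gene on
the opposite strand never count toward it: the two strands are analysed
separately throughout. SAM input is reduced to mapped primary alignments,
with soft-clipped bases excluded from the end coordinates, because the
3′-end position is the analytic signal.

## Gene level

RPKMc normalizes a gene's read count by CDS length (kb) and by the total
number of *distinct* reads overlapping any CDS (a read spanning two
overlapping genes increments both genes but the total once; whether the
total should double-count such reads is underdetermined, so the distinct
rule is declared as the contract). A read counts for a gene if it overlaps
the CDS by at least one nucleotide on the gene's strand.

The R/m ratio is the replicate-averaged RP RPKMc over the
replicate-averaged mRNA RPKMc. Replicate averaging is arithmetic by
default (a geometric option exists). Genes with fewer than 10 total mapped
mRNA reads are excluded with a recorded reason: no stated floor exists for
this filter, and 10 reads is the point below which a denominator is mostly
Poisson noise; the cutoff is exposed as `min_mrna`.

SAM-style selection uses the two-class unpaired d-statistic on
log2(RPKMc + 1) with fudge constant s0 set to the 5th percentile of
per-gene pooled standard errors, 1000 seeded label permutations by
default, and a delta band on the observed-vs-expected order statistics.
These details (transform, s0 rule, permutation count) are not pinned down
by any published default worth chasing, so they are fixed here for
reproducibility and exposed as arguments. One guard is added to the
textbook procedure: a gene selected as RP-high must itself have d > 0 (and
symmetrically for RP-low). Without it, data in which every observed d is
zero but the permutation distribution is degenerate (e.g. duplicated
columns) would select everything; with it, such data select nothing, and
power on planted signals is unaffected because true positives always
satisfy the sign condition.

The transmembrane association regresses R/m on TM segments per nt of ORF
and reports the Spearman correlation, the slope, and the x-intercept
(−intercept/slope). Regressing the ratio on the density (rather than the
reverse) is chosen so the slope answers "how much does R/m drop per unit
membrane-segment density", the recoverable quantity in simulation; the
published parameterization of this fit is ambiguous.

CAI follows Sharp & Li: relative adaptiveness w is the codon's frequency in
a highly-expressed reference set divided by the frequency of its commonest
synonym, with zero reference counts floored at 0.5 occurrences; a gene's
CAI is the geometric mean of w over its codons excluding Met, Trp and
stops. The reference set is configurable; the default is the top 5% of
genes by RP RPKMc, since the historical reference list cannot be
reconstructed exactly.

Binning for covariate plots ranks genes by the covariate with ties broken
by gene id (deterministic partitions), splits them into `n_bins = 20`
near-equal groups, and reports the per-gene Kendall test alongside the
bin means; note that a rank correlation *test statistic* can exceed 1 even
though tau cannot, so both are returned.

## Codon level

**Offset calibration.** The nuclease leaves the footprint 3′ end a fixed
offset downstream of the A-site first base. In the frozen initiation
complex the start codon occupies the P-site, so the A-site first base is
at transcript position 3 and the 3′-end metagene peak of a
start-codon-anchored window sits at offset + 3. `calibrate_asite_offset()`
takes the per-gene argmax over the first 60 nt (genes with ≥ 10 reads in
the window; ≥ 100 such genes required), subtracts 3, and returns the modal
value; if the aggregate metagene has no peak above 3× its median the
calibration fails loudly rather than returning noise. The search window
for the initiation peak in `start_peak_stats()` extends to +30 for the
same geometric reason: with a 12-nt cut the peak lies at +15, and any
bound below that would exclude the object being measured.

**Relative density.** Each position's 3′-end depth is divided by the mean
of its ±60 nt window (121 nt), clipped to the transcript; positions whose
window covers less than 50% of 121 nt, or whose window mean is zero, are
flagged missing — never zero, since zeros would bias codon means downward.
Whether the window may span transcript boundaries is not defined by any
convention we know; clipping with the 50% floor is the package's choice.
Because depth differs systematically between the three bases of a codon,
per-frame factors (mean relative density of each frame class over the
included codons of all genes, per sample) are divided out. A frame class
with no signal yields an NA factor that propagates as missing.

**The codon × position matrix.** A codon occurrence at transcript position
t0 sits at relative position p for ribosomes whose A-site is at t0 − p;
their 3′ ends fall at t0 − p + offset. Cell (codon, p) is therefore the
mean relative 3′-end density at t0 + offset − p over all retained
occurrences (first 20 and last 10 codons of each gene excluded, where
depth is systematically inflated). Under this sign convention the read-end
artifact appears at p = +12, the E-site at p = −6 and anti-SD pausing near
p = −15, matching the ribosome's geometry. Each (position, sample) column
is renormalized to count-weighted mean 1, which makes the normalization
invariant exact by construction and leaves within-position codon
comparisons (and the CV profile) unchanged.

The positional spread statistic is the coefficient of variation across the
61 codon means (scale-free across positions); SD is available via
`statistic = "sd"`. The A-site metric at p = 0 uses the single nucleotide
at codon first base + offset; averaging the three codon bases is
deliberately not the default because frame normalization already absorbs
the within-codon structure.

The isoacceptor pair table (11 NNU/NNC pairs decoded by a single
GXX-anticodon tRNA, 4 NNA/NNG pairs decoded by a single UXX-anticodon
tRNA) is a curated reconstruction from E. coli K-12 anticodon assignments
— the wobble rule alone does not fix the membership — and is
user-replaceable via the `pairs` argument.

`rescale_to_external()` maps log(1/density) affinely so its range matches
the log range of an external decoding-rate table over shared codons:
observed relative densities compress the true rate range, and the affine
map answers "what would the gene-level folds be if the codon spread were
as large as externally measured".

## The simulator

`sim_scenario()` fixes every generative parameter and a seed; all outputs
are deterministic functions of it. Defaults encode the study conditions
the package is meant to emulate:

| parameter | default | meaning |
|---|---|---|
| `n_genes`, `gene_length_range` | 150, 80–300 codons | bacterial gene-length scale |
| `codon_dwell` | log-normal, sdlog 0.25 | ~3-fold max/min spread across 61 codons, the observed scale of A-site density differences |
| `initiation_rate` | log-normal, central 80% ≈ 7-fold | the observed R/m spread |
| `mrna_abundance` | log-normal, central 80% ≈ 200-fold | the observed mRNA depth spread |
| `cut_offset` | 12 nt | nuclease cut site 3′ of the A-site first base |
| `five_prime_jitter_sd` | 2 nt | footprint length ~ round(N(28, σ)) truncated to [20, 45]; 28 nt is the canonical bacterial footprint and only the 5′ end varies — the 3′ end (the mapped signal) is exact |
| `drug_mode` | `"cm"` | Cm is the primary harvesting condition; adds the E-site amino-acid effect (Gly/Ala/Ser ×3, Pro/Thr/Cys ×2) and a moderate initiation peak (fraction 0.1) |
| `tet_start_peak_fraction` | 0.5 | Tet mode freezes this fraction as initiation complexes |
| `antisd_pause_multiplier`, triplets | 2, {GGG, GGA, GAG, AGG, GGT, GTG} | G-rich C-free anti-SD-like triplets at −15 nt pause elongation |
| `polyA_tail` | FALSE | when on, A-ending 3′ ends are trimmed past the template A run with probability 0.5 per read |

Footprints choose a gene ∝ mRNA abundance × initiation rate × length, then
an A-site codon ∝ effective dwell among elongation-competent positions
(those whose cut site stays inside the transcript; the start codon and stop
are never A-sites of elongating ribosomes). The Cm field is added to the
scenario because a moderate initiation peak is part of the Cm signature
but no dedicated parameter existed for it. mRNA fragments are uniform
within the transcript with lengths Uniform(30, 70) nt (the gel-selected
range). No head/tail codons are excluded at generation: exclusion is the
analyst's job, and the simulator must not pre-apply it.

**What the simulator does not model:** sequencing errors, rRNA
contamination, mRNA degradation gradients along operons, ribosome
collisions/queueing, biological variability between replicate cultures
(replicates differ only by sampling noise), or a mechanistic account of
drug action — only the observable positional signatures are generated.
Passing recovery tests therefore shows the estimators are correct under
the stated generative model, not that real libraries satisfy that model.

## Numerical choices and degenerate inputs

- Ties in covariate binning break by gene id; bin sizes differ by ≤ 1.
- `central_fold_range()` uses type-7 quantiles and refuses non-positive
  values; it is invariant under multiplying all values by a constant.
- Degenerate rank tests (all-zero paired differences) return NA rather
  than erroring.
- Genes whose CDS length is not a positive codon multiple are kept for
  gene-level analyses but flagged out of codon-level ones, with a warning.
- Metagene windows crossing a reference edge are skipped, not padded; the
  "longer than 500 bp" filter is strict, and boundary genes are noted.
- Simulated 3′ ends carry no cut jitter, so simulated depth lives entirely
  in frame 0; the frame factors for the empty classes are NA and those
  matrix positions stay missing. Real libraries populate all three frames.

## Problem sizes in the test suite

The suite exercises full pipelines at sizes a laptop core handles in
minutes: 40–200 genes, 10⁵–2×10⁶ footprints. Dwell recovery uses 200 genes
and 2×10⁶ reads (Spearman ≥ 0.9 against planted dwell times);
translation-efficiency recovery uses 150 genes with two replicate
libraries per assay and a ≥ 50 mRNA-reads filter; the null-control and
drug-contrast checks use 150 genes at 0.5–1×10⁶ reads, with flatness
judged against 3× the pooled across-replicate SD of per-codon A-site
densities over three simulated replicates — a band that detects real
deviations but is not satisfied vacuously. A 3-gene toy genome with
hand-checkable sequences backs exact (1e-9) brute-force equality tests for
RPKMc, relative density and every matrix cell.

## Known limitations

- The offset calibration needs an initiation peak; libraries harvested
  without elongation inhibitors (or simulated with `drug_mode = "none"`)
  fail calibration by design, and the offset must then be supplied.
- Operon-aware transcript models are not implemented: each CDS is treated
  as its own transcript for windowing, so 5′/3′ ends of genes inside
  operons are handled like gene ends.
- The E-site contrast keys on the amino acid, not the codon; a
  codon-resolved E-site effect would be aliased into it.
- FDR from SAM permutations is a median-based plug-in estimate; with very
  few selected genes it is coarse.
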