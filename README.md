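# riboflux

Gene- and codon-level translation efficiency from bacterial ribosome
profiling (RP) and mRNA-seq.

## The problem

Ribosome density along an mRNA reflects two opposing rates: initiation
(more ribosomes load) and elongation (faster decoding means fewer ribosomes
caught per codon). Separating the two requires analysis at two scales:

- **Gene level.** Depth is normalized as RPKMc — reads per kilobase of CDS
  per million CDS-mapped reads:
  `RPKMc = count / (L/1000) / total_cds_reads × 10⁶`.
  The ratio of RP to mRNA-seq depth, the **R/m ratio**, is a proxy for
  translation (initiation) efficiency. The package computes R/m
  distributions and fold ranges, bins genes by covariates (predicted
  initiation score, codon adaptation index) with Kendall rank tests,
  fits the transmembrane-segment association, and selects genes with
  discordant RP/mRNA depth by a SAM-style permutation d-statistic.
  CAI follows the Sharp–Li convention: the geometric mean over a gene's
  codons of w_c = f_c / max(f_synonymous) computed from a highly-expressed
  reference set.

- **Codon level.** The footprint 3′ end is the mapped signal: RNase I
  cleaves a fixed offset (~12 nt) downstream of the first base of the
  A-site codon, so 3′-end depth, after normalization by the ±60 nt window
  mean and per-frame factors, measures the relative dwell time of the codon
  being decoded. The package calibrates the offset from a
  start-codon-anchored metagene (the initiation complex holds the start
  codon in the P-site, putting the 3′-end peak at offset + 3 nt), then
  builds the mean relative density of each of the 61 sense codons at every
  position from −45 to +45 nt around the A-site (position 0 = A-site first
  base, 5′ negative), excluding the first 20 and last 10 codons of each
  gene. On top of that sit synonymous-usage comparisons, isoacceptor-pair
  contrasts, per-position coefficient-of-variation profiles, gene-level
  densities predicted from codon composition, and rescaling onto external
  decoding-rate scales.

Every estimator is paired with a **simulator** (`sim_scenario()`,
`build_genome()`, `simulate_footprints()`, `simulate_mrna_reads()`) whose
generative model — codon-specific dwell times, per-gene initiation rates
decoupled from mRNA abundance, the fixed 3′ cut offset, drug-mode artifacts
(chloramphenicol: E-site amino-acid effect plus a moderate initiation peak;
tetracycline: dominant initiation peak), anti-Shine–Dalgarno pausing at
−15 nt, and poly(A) 3′-end ambiguity — provides exact ground truth for
recovery tests.

## Worked example

```r
library(riboflux)

scen <- sim_scenario(seed = 42, n_genes = 150)      # chemostat-like library
gen  <- build_genome(scen)
rp   <- simulate_footprints(scen, gen$genome, gen$models, 1e6)
mrna <- simulate_mrna_reads(scen, gen$genome, gen$models, 1e6)

trk <- build_depth_track(rp$records, "three_prime_only",
                         Biostrings::width(gen$genome)[1])
(off <- calibrate_asite_offset(trk, gen$models))
#> [1] 12

rm <- rm_ratio(expression_table(list(rp1 = rp$records), gen$models),
               expression_table(list(m1 = mrna), gen$models))
head(rm, 3)
#> # A tibble: 3 × 6
#>   gene_id mean_rp mean_mrna mrna_reads rm_ratio excluded_reason
#>   <chr>     <dbl>     <dbl>      <int>    <dbl> <chr>
#> 1 g0001      82.7      457.        177    0.181 <NA>
#> 2 g0002     255.       963.        419    0.265 <NA>
#> 3 g0003     235.      1278.        893    0.184 <NA>
central_fold_range(rm$rm_ratio[!is.na(rm$rm_ratio)], 0.8)
#> [1] 7.74

rl   <- relative_density(trk, gen$models)
mat  <- codon_position_matrix(rl, gen$models, gen$genome, off, sample_id = "rp1")
asite_summary(list(rp1 = mat))
#> <asite_summary> 61 codons, 1 sample(s)
#> # A tibble: 61 × 5
#>   codon aa     mean    sd norm_mean
#> 1 CAG   Q      1.64    NA      1.44
#> 2 CTC   L      1.60    NA      1.56
#> ...
```

The calibrated offset (12 nt) is the simulator's cut model recovered from
the data alone. The R/m ratio tracks the planted per-gene initiation rates
(Spearman 0.98 here) and the A-site densities track the planted codon dwell
times (Spearman 0.93); the central-80% R/m fold range (~7.7) emerges from
the generative initiation-rate spread. `autoplot()` methods exist for
metagene profiles, bin summaries and A-site summaries; `tidy()`/`glance()`
for SAM selections, bin summaries and regression fits.

A one-config driver runs everything (`run_pipeline()`, YAML accepted;
`inst/scripts/riboflux` wraps it for the shell) and writes every table plus
a manifest with file hashes so reruns under the same seed are
bit-identical.

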