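# Generative model for footprint and mRNA-seq libraries with known ground
# truth: codon-specific dwell times, per-gene initiation rates decoupled
# from mRNA abundance, a fixed nuclease cut offset 3' of the A-site,
# drug-mode artifacts (Cm: E-site amino-acid effect plus a moderate
# initiation peak; Tet: dominant initiation peak), anti-SD-like pausing
# when a G-rich triplet sits 15 nt 5' of the A-site, and optional
# poly(A)-tailing ambiguity of 3'-end bases.

#' Default anti-SD-like triplets
#'
#' G-rich, C-free triplets that resemble the Shine-Dalgarno element and
#' pause elongation when positioned ~15 nt 5' of the A-site first base.
#' @return Character vector of DNA triplets.
#' @export
default_antisd_triplets <- function() c("GGG", "GGA", "GAG", "AGG", "GGT", "GTG")

#' Default Cm-mode E-site amino-acid multipliers
#'
#' Under chloramphenicol, ribosome density rises when the E-site amino acid
#' (second residue of the nascent chain from the tunnel entrance) has a
#' small side chain: Gly/Ala/Ser 3.0, Pro/Thr/Cys 2.0, all others 1.0.
#' @return Named numeric vector over the 20 one-letter amino-acid codes.
#' @export
default_cm_esite_multiplier <- function() {
  aa <- unique(sense_codons()$aa)
  m <- setNames(rep(1, length(aa)), aa)
  m[c("G", "A", "S")] <- 3
  m[c("P", "T", "C")] <- 2
  m
}

#' Define a simulation scenario
#'
#' Bundles every generative parameter (and the seed) of the footprint/mRNA
#' simulator. Per-gene initiation rates and mRNA abundances, and per-codon
#' dwell times, may be supplied explicitly; by default they are drawn
#' once, deterministically from `seed`, from log-normal distributions whose
#' central-80% spreads match a bacterial chemostat library: ~7-fold for
#' initiation rates, ~200-fold for mRNA abundance, and an ~3-fold max/min
#' spread of codon dwell times.
#'
#' @param seed Integer seed; everything downstream is a deterministic
#'   function of the scenario.
#' @param n_genes Number of genes to simulate.
#' @param gene_length_range Inclusive range of gene lengths in sense codons
#'   (start codon included, stop excluded; a stop codon is appended).
#' @param codon_dwell Named vector of relative dwell times over the 61
#'   sense codons, or `NULL` to draw log-normal(0, `dwell_sdlog`).
#' @param dwell_sdlog sdlog of the default dwell draw.
#' @param initiation_rate Optional per-gene vector (recycled/named by gene
#'   once the genome is built); `NULL` draws log-normal.
#' @param mrna_abundance Same for mRNA abundance.
#' @param cut_offset Nuclease cut site, nt 3' of the A-site first base
#'   (default 12).
#' @param five_prime_jitter_sd SD (nt) of the footprint length model
#'   round(Normal(28, sd)) truncated to [20, 45]; the 3' end is exact.
#' @param drug_mode `"cm"`, `"tet"` or `"none"`.
#' @param tet_start_peak_fraction Fraction of Tet-mode reads frozen as
#'   initiation complexes (start codon in the P-site).
#' @param cm_start_peak_fraction Same for Cm mode (moderate peak).
#' @param cm_esite_multiplier Named amino-acid multipliers applied to dwell
#'   via the E-site residue in Cm mode.
#' @param antisd_pause_multiplier Dwell multiplier when an anti-SD-like
#'   triplet sits at transcript offset -15 from the A-site first base.
#' @param antisd_triplets Triplet set; see [default_antisd_triplets()].
#' @param polyA_tail If TRUE, [apply_polya_ambiguity()] is part of the
#'   scenario's read model.
#' @return A `sim_scenario` object (named list).
#' @export
sim_scenario <- function(seed = 1L,
                         n_genes = 150L,
                         gene_length_range = c(80L, 300L),
                         codon_dwell = NULL,
                         dwell_sdlog = 0.25,
                         initiation_rate = NULL,
                         mrna_abundance = NULL,
                         cut_offset = 12L,
                         five_prime_jitter_sd = 2,
                         drug_mode = c("cm", "tet", "none"),
                         tet_start_peak_fraction = 0.5,
                         cm_start_peak_fraction = 0.1,
                         cm_esite_multiplier = default_cm_esite_multiplier(),
                         antisd_pause_multiplier = 2,
                         antisd_triplets = default_antisd_triplets(),
                         polyA_tail = FALSE) {
  drug_mode <- match.arg(drug_mode)
  seed <- as.integer(seed)
  sc <- sense_codons()
  if (is.null(codon_dwell)) {
    withr_seed(seed + 101L)
    codon_dwell <- setNames(rlnorm(nrow(sc), 0, dwell_sdlog), sc$codon)
  } else {
    miss <- setdiff(sc$codon, names(codon_dwell))
    if (length(miss)) abort(paste0("codon_dwell missing codons: ",
                                   paste(head(miss, 5), collapse = ", ")))
    codon_dwell <- codon_dwell[sc$codon]
  }
  if (any(codon_dwell <= 0)) abort("dwell times must be strictly positive")
  if (!is.null(initiation_rate) && any(initiation_rate <= 0)) {
    abort("initiation rates must be strictly positive")
  }
  if (!is.null(mrna_abundance) && any(mrna_abundance <= 0)) {
    abort("mRNA abundances must be strictly positive")
  }
  structure(list(
    seed = seed, n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    codon_dwell = codon_dwell,
    initiation_rate = initiation_rate, mrna_abundance = mrna_abundance,
    cut_offset = as.integer(cut_offset),
    five_prime_jitter_sd = five_prime_jitter_sd,
    drug_mode = drug_mode,
    tet_start_peak_fraction = tet_start_peak_fraction,
    cm_start_peak_fraction = cm_start_peak_fraction,
    cm_esite_multiplier = cm_esite_multiplier,
    antisd_pause_multiplier = antisd_pause_multiplier,
    antisd_triplets = toupper(chartr("U", "T", antisd_triplets)),
    polyA_tail = isTRUE(polyA_tail)
  ), class = "sim_scenario")
}

# deterministic seeding; kept in one place so every stochastic stage derives
# its stream from the scenario seed plus a fixed offset
withr_seed <- function(seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
}

#' Build a synthetic genome and annotation from a scenario
#'
#' Genes are non-overlapping, placed on both strands with random intergenic
#' spacers, each CDS starting with ATG and ending with a stop codon; sense
#' codons of the body are drawn uniformly, so with >= 100 genes every sense
#' codon occurs hundreds of times genome-wide. Per-gene true initiation
#' rates and mRNA abundances are resolved here and attached to the models.
#'
#' @param scenario A [sim_scenario()].
#' @return List with `genome` (a named `DNAStringSet`, single reference
#'   `"chrSim"`) and `models` (gene tibble incl. `true_initiation_rate`,
#'   `true_mrna_abundance`, `codon_eligible`).
#' @export
build_genome <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  withr_seed(scenario$seed)
  sc <- sense_codons()
  n <- scenario$n_genes
  lo <- scenario$gene_length_range[1]; hi <- scenario$gene_length_range[2]
  n_codons <- lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  body <- lapply(n_codons, function(k) {
    paste0(c("ATG", sample(sc$codon, k - 1L, replace = TRUE),
             sample(STOP_CODONS, 1L)), collapse = "")
  })
  spacers <- vapply(sample(20:100, n + 1L, replace = TRUE), function(w) {
    paste0(sample(c("A", "C", "G", "T"), w, replace = TRUE), collapse = "")
  }, character(1))
  pieces <- character(2L * n + 1L)
  pieces[1] <- paste0(strrep("C", 100), spacers[1])
  starts <- integer(n); ends <- integer(n)
  pos <- nchar(pieces[1])
  for (i in seq_len(n)) {
    cds <- body[[i]]
    placed <- if (strand[i] == "+") cds else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds)))
    starts[i] <- pos
    ends[i] <- pos + nchar(cds)
    pieces[2L * i] <- placed
    pieces[2L * i + 1L] <- spacers[i + 1L]
    pos <- ends[i] + nchar(spacers[i + 1L])
  }
  seqchr <- paste0(paste0(pieces, collapse = ""), strrep("C", 100))
  genome <- Biostrings::DNAStringSet(c(chrSim = seqchr))
  gene_id <- sprintf("g%04d", seq_len(n))
  init <- scenario$initiation_rate
  if (is.null(init)) {
    withr_seed(scenario$seed + 202L)
    init <- rlnorm(n, 0, log(7) / (2 * stats::qnorm(0.9)))
  }
  abund <- scenario$mrna_abundance
  if (is.null(abund)) {
    withr_seed(scenario$seed + 303L)
    abund <- rlnorm(n, 0, log(200) / (2 * stats::qnorm(0.9)))
  }
  models <- tibble(
    gene_id = gene_id, reference = "chrSim",
    start = starts, end = ends, strand = strand,
    n_codons = n_codons,
    true_initiation_rate = rep_len(unname(init), n),
    true_mrna_abundance = rep_len(unname(abund), n),
    codon_eligible = TRUE
  )
  list(genome = genome, models = models)
}

# per-gene codon vectors (sense codons only, stop dropped), from genome
gene_codon_list <- function(genome, models) {
  lapply(seq_len(nrow(models)), function(i) {
    cds <- gene_sequence(genome, models$reference[i], models$start[i],
                         models$end[i], models$strand[i])
    cdn <- split_codons(cds)
    cdn[seq_len(length(cdn) - 1L)]  # drop terminal stop
  })
}

#' Simulate ribosome footprints from a scenario
#'
#' For each read a gene is chosen with probability proportional to
#' mRNA abundance x initiation rate x transcript length; the A-site codon
#' is chosen among elongation-competent codons proportional to effective
#' dwell (codon dwell, times the Cm E-site amino-acid multiplier, times the
#' anti-SD pause multiplier when a G-rich triplet sits at transcript offset
#' -15 from the A-site first base). A drug-mode-dependent fraction of reads
#' are instead initiation complexes with the start codon in the P-site
#' (A-site = codon 1). The 3' end is placed exactly `cut_offset` nt
#' downstream of the A-site first base; the 5' end follows the truncated
#' normal footprint-length model. A-site positions whose cut site would
#' fall beyond the transcript are never drawn. No head/tail codons are
#' excluded at generation - exclusion is the analyst's job.
#'
#' @param scenario A [sim_scenario()].
#' @param genome,models Output of [build_genome()] (or compatible).
#' @param n_reads Number of footprints.
#' @param seed Optional override of the scenario seed for this read set
#'   (e.g. to draw replicate samples from one scenario).
#' @return List with `records` (alignment tibble) and `truth` (list:
#'   `per_read` tibble with `gene_id`, `asite_codon_index`, `asite_codon`,
#'   `is_start_peak`; plus `codon_dwell`, `cut_offset`,
#'   `initiation_rate`, `mrna_abundance`).
#' @export
simulate_footprints <- function(scenario, genome, models, n_reads,
                                seed = scenario$seed) {
  stopifnot(n_reads > 0)
  withr_seed(seed + 404L)
  models <- flag_codon_eligibility(validate_gene_models(models))
  codons <- gene_codon_list(genome, models)
  aa_map <- codon_aa_map()
  n_sense <- vapply(codons, length, integer(1))
  tlen <- models$end - models$start
  # elongation-competent A-site codons: 1 .. c_max (0-based), cut site inside
  c_max <- pmin(n_sense - 1L, (tlen - 1L - scenario$cut_offset) %/% 3L)
  if (any(c_max < 1L)) abort("gene too short for the cut model")
  # effective dwell weights per gene
  weights <- lapply(seq_len(nrow(models)), function(i) {
    idx <- seq.int(1L, c_max[i])
    w <- scenario$codon_dwell[codons[[i]][idx + 1L]]
    if (scenario$drug_mode == "cm") {
      e_idx <- idx - 2L
      mult <- rep(1, length(idx))
      has_e <- e_idx >= 0L
      mult[has_e] <- scenario$cm_esite_multiplier[aa_map[codons[[i]][e_idx[has_e] + 1L]]]
      w <- w * mult
    }
    sd_idx <- idx - 5L   # triplet whose first base is 15 nt 5' of the A-site
    pause <- rep(1, length(idx))
    has_sd <- sd_idx >= 0L
    pause[has_sd] <- ifelse(codons[[i]][sd_idx[has_sd] + 1L] %in%
                              scenario$antisd_triplets,
                            scenario$antisd_pause_multiplier, 1)
    unname(w * pause)
  })
  gene_w <- models$true_mrna_abundance * models$true_initiation_rate * tlen
  gi <- sample.int(nrow(models), n_reads, replace = TRUE, prob = gene_w)
  peak_frac <- switch(scenario$drug_mode,
                      tet = scenario$tet_start_peak_fraction,
                      cm = scenario$cm_start_peak_fraction,
                      none = 0)
  is_peak <- runif(n_reads) < peak_frac
  asite <- integer(n_reads)
  asite[is_peak] <- 1L                       # start codon in P-site
  for (i in unique(gi[!is_peak])) {
    sel <- which(gi == i & !is_peak)
    asite[sel] <- sample.int(c_max[i], length(sel), replace = TRUE,
                             prob = weights[[i]])
  }
  t3 <- 3L * asite + scenario$cut_offset
  L <- pmin(45L, pmax(20L, as.integer(round(rnorm(n_reads, 28,
                                                  scenario$five_prime_jitter_sd)))))
  t5 <- t3 - (L - 1L)
  g3 <- ifelse(models$strand[gi] == "+", models$start[gi] + t3,
               models$end[gi] - 1L - t3)
  g5 <- ifelse(models$strand[gi] == "+", models$start[gi] + t5,
               models$end[gi] - 1L - t5)
  records <- tibble(reference = models$reference[gi],
                    strand = models$strand[gi],
                    five_prime = as.integer(g5), three_prime = as.integer(g3),
                    read_length = L)
  asite_codon <- vapply(seq_len(n_reads),
                        function(k) codons[[gi[k]]][asite[k] + 1L], character(1))
  truth <- list(
    per_read = tibble(gene_id = models$gene_id[gi],
                      asite_codon_index = asite, asite_codon = asite_codon,
                      is_start_peak = is_peak),
    codon_dwell = scenario$codon_dwell,
    cut_offset = scenario$cut_offset,
    initiation_rate = setNames(models$true_initiation_rate, models$gene_id),
    mrna_abundance = setNames(models$true_mrna_abundance, models$gene_id))
  if (scenario$polyA_tail) {
    records <- apply_polya_ambiguity(records, genome, seed = seed + 505L)
  }
  list(records = records, truth = truth)
}

#' Simulate mRNA-seq fragments
#'
#' Genes are chosen proportional to mRNA abundance x transcript length;
#' fragment length is Uniform(30, 70) nt (the gel-selected range) and the
#' fragment start uniform within the transcript.
#'
#' @inheritParams simulate_footprints
#' @return Alignment tibble.
#' @export
simulate_mrna_reads <- function(scenario, genome, models, n_reads,
                                seed = scenario$seed) {
  stopifnot(n_reads > 0)
  withr_seed(seed + 606L)
  validate_gene_models(models)
  tlen <- models$end - models$start
  gi <- sample.int(nrow(models), n_reads, replace = TRUE,
                   prob = models$true_mrna_abundance * tlen)
  L <- pmin(sample.int(41L, n_reads, replace = TRUE) + 29L, tlen[gi])
  t5 <- floor(runif(n_reads) * (tlen[gi] - L + 1L))
  t3 <- t5 + L - 1L
  g5 <- ifelse(models$strand[gi] == "+", models$start[gi] + t5,
               models$end[gi] - 1L - t5)
  g3 <- ifelse(models$strand[gi] == "+", models$start[gi] + t3,
               models$end[gi] - 1L - t3)
  tibble(reference = models$reference[gi], strand = models$strand[gi],
         five_prime = as.integer(g5), three_prime = as.integer(g3),
         read_length = as.integer(L))
}

#' Apply poly(A)-tailing ambiguity to recorded 3' ends
#'
#' Library construction appends untemplated A residues, so a 3'-terminal A
#' that is template-encoded cannot be distinguished from the tail and is
#' trimmed together with it. For every record whose true 3'-end base (in
#' reading orientation) is a template A, with probability `prob` the
#' recorded 3' end is shifted upstream past the maximal run of template
#' A's. Other records pass unchanged.
#'
#' @param records Alignment tibble.
#' @param genome Named `DNAStringSet`.
#' @param prob Per-read trimming-collision probability.
#' @param seed Seed for the per-read coin flips.
#' @return Alignment tibble with updated `three_prime` / `read_length`.
#' @export
apply_polya_ambiguity <- function(records, genome, prob = 0.5, seed = 1L) {
  if (nrow(records) == 0) return(records)
  withr_seed(seed)
  refseq <- as.character(genome[[unique(records$reference)[1]]])
  n <- nrow(records)
  shift <- integer(n)
  plus <- records$strand == "+"
  # transcript-sense base at a genome position
  base_at <- function(gpos, plus) {
    b <- substring(refseq, gpos + 1L, gpos + 1L)
    ifelse(plus, b, chartr("ACGT", "TGCA", b))
  }
  hit <- base_at(records$three_prime, plus) == "A" & runif(n) < prob
  if (any(hit)) {
    idx <- which(hit)
    g3 <- records$three_prime[idx]
    run <- integer(length(idx))
    active <- seq_along(idx)
    step <- ifelse(plus[idx], -1L, 1L)  # upstream in transcript direction
    pos <- g3
    while (length(active)) {
      run[active] <- run[active] + 1L
      pos[active] <- pos[active] + step[active]
      nxt <- base_at(pos[active], plus[idx][active]) == "A" &
        pos[active] >= 0L & pos[active] < nchar(refseq)
      active <- active[nxt]
    }
    records$three_prime[idx] <- records$three_prime[idx] + step * run
    records$read_length <- abs(records$three_prime - records$five_prime) + 1L
  }
  records
}

#' Write a simulated data set to disk
#'
#' Emits `genome.fa`, `genes.bed`, `rp.tsv`, `mrna.tsv` and `truth.json`
#' into a directory.
#'
#' @param scenario A [sim_scenario()].
#' @param out_dir Output directory (created if needed).
#' @param n_rp,n_mrna Read counts for the two libraries.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(scenario, out_dir, n_rp = 2e5, n_mrna = 2e5) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gen <- build_genome(scenario)
  fp <- simulate_footprints(scenario, gen$genome, gen$models, n_rp)
  mr <- simulate_mrna_reads(scenario, gen$genome, gen$models, n_mrna)
  paths <- c(genome = file.path(out_dir, "genome.fa"),
             genes = file.path(out_dir, "genes.bed"),
             rp = file.path(out_dir, "rp.tsv"),
             mrna = file.path(out_dir, "mrna.tsv"),
             truth = file.path(out_dir, "truth.json"))
  Biostrings::writeXStringSet(gen$genome, paths["genome"])
  write_gene_models(gen$models, paths["genes"], "bed")
  write_alignments(fp$records, paths["rp"])
  write_alignments(mr, paths["mrna"])
  jsonlite::write_json(list(
    codon_dwell = as.list(fp$truth$codon_dwell),
    cut_offset = fp$truth$cut_offset,
    initiation_rate = as.list(fp$truth$initiation_rate),
    mrna_abundance = as.list(fp$truth$mrna_abundance)),
    paths["truth"], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
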