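# Shared fixtures, all generated in code.

# tiny hand-buildable genome: 3 genes (two +, one -), known sequences
toy_genome_fixture <- function() {
  # gene A: 10 codons + stop, + strand at 50
  gA <- "ATGAAACGTGCTAGCGGGTTTCCCGATCAATAA"          # 33 nt
  # gene B: 12 codons + stop, - strand at 120
  gB <- "ATGGGTGGTAGAAGAGCTGCTTTTCTGATCGATCAATAA"    # 39 nt
  # gene C: 10 codons + stop, + strand at 200
  gC <- "ATGCTGCTGAAAAAGGGCGCCTATTACTAA"              # 30 nt
  n <- 300
  base <- rep("C", n)
  put <- function(base, s, seqchr, strand) {
    v <- strsplit(seqchr, "")[[1]]
    if (strand == "-") {
      v <- rev(chartr("ACGT", "TGCA", v))
    }
    base[(s + 1):(s + length(v))] <- v
    base
  }
  base <- put(base, 50, gA, "+")
  base <- put(base, 120, gB, "-")
  base <- put(base, 200, gC, "+")
  genome <- Biostrings::DNAStringSet(c(chrT = paste0(base, collapse = "")))
  models <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    reference = "chrT",
    start = c(50L, 120L, 200L),
    end = c(83L, 159L, 230L),
    strand = c("+", "-", "+"),
    codon_eligible = TRUE)
  list(genome = genome, models = models,
       cds = list(gA = gA, gB = gB, gC = gC))
}

# uniform-scenario helper kept small for unit tests
small_uniform_scenario <- function(seed = 11, n_genes = 60, ...) {
  sim_scenario(seed = seed, n_genes = n_genes,
               gene_length_range = c(60L, 120L),
               initiation_rate = 1, mrna_abundance = 1,
               codon_dwell = stats::setNames(rep(1, 61), sense_codons()$codon),
               drug_mode = "none", antisd_pause_multiplier = 1, ...)
}

# alignment tibble from explicit ends
mk_reads <- function(five, three, strand = "+", reference = "chrT") {
  tibble::tibble(reference = reference, strand = strand,
                 five_prime = as.integer(five), three_prime = as.integer(three),
                 read_length = abs(as.integer(three) - as.integer(five)) + 1L)
}
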