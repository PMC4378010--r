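test_that("genome generation is deterministic and structurally sound", {
  scen <- sim_scenario(seed = 7, n_genes = 100)
  g1 <- build_genome(scen)
  g2 <- build_genome(scen)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$models, g2$models)
  m <- g1$models
  expect_true(all((m$end - m$start) %% 3 == 0))
  expect_setequal(unique(m$strand), c("+", "-"))
  # non-overlapping
  o <- order(m$start)
  expect_true(all(m$start[o][-1] >= m$end[o][-length(o)]))
  # ATG starts, stop ends, and every sense codon is well represented
  counts <- stats::setNames(numeric(61), sense_codons()$codon)
  for (i in seq_len(nrow(m))) {
    cds <- riboflux:::gene_sequence(g1$genome, m$reference[i], m$start[i],
                                    m$end[i], m$strand[i])
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_true(substr(cds, nchar(cds) - 2, nchar(cds)) %in%
                  c("TAA", "TAG", "TGA"))
    cdn <- riboflux:::split_codons(cds)
    cdn <- cdn[-length(cdn)]
    t <- table(cdn)
    counts[names(t)] <- counts[names(t)] + t
  }
  expect_true(all(counts >= 50))
})

test_that("footprint simulation is deterministic and conserves read count", {
  scen <- small_uniform_scenario()
  gen <- build_genome(scen)
  f1 <- simulate_footprints(scen, gen$genome, gen$models, 5000)
  f2 <- simulate_footprints(scen, gen$genome, gen$models, 5000)
  expect_identical(f1$records, f2$records)
  expect_equal(nrow(f1$records), 5000L)
  expect_true(all(f1$records$read_length >= 20 & f1$records$read_length <= 45))
})

test_that("uniform dwell yields uniform A-site positions within genes", {
  scen <- small_uniform_scenario(seed = 3, n_genes = 4)
  gen <- build_genome(scen)
  fp <- simulate_footprints(scen, gen$genome, gen$models, 6e4)
  pr <- fp$truth$per_read
  for (g in gen$models$gene_id) {
    idx <- pr$asite_codon_index[pr$gene_id == g & !pr$is_start_peak]
    if (length(idx) < 2000) next
    tab <- table(idx)
    p <- suppressWarnings(stats::chisq.test(tab)$p.value)
    expect_gt(p, 0.01)
  }
})

test_that("a 3x dwell codon draws ~3x the A-site reads at matched frequency", {
  dw <- stats::setNames(rep(1, 61), sense_codons()$codon)
  dw["AGA"] <- 3
  scen <- sim_scenario(seed = 5, n_genes = 80, gene_length_range = c(80L, 120L),
                       initiation_rate = 1, mrna_abundance = 1,
                       codon_dwell = dw, drug_mode = "none",
                       antisd_pause_multiplier = 1)
  gen <- build_genome(scen)
  fp <- simulate_footprints(scen, gen$genome, gen$models, 4e5)
  pr <- fp$truth$per_read[!fp$truth$per_read$is_start_peak, ]
  n_aga <- sum(pr$asite_codon == "AGA")
  n_gct <- sum(pr$asite_codon == "GCT")
  # occurrence counts of the two codons among eligible positions
  occ <- table(unlist(riboflux:::gene_codon_list(gen$genome, gen$models)))
  ratio <- (n_aga / occ[["AGA"]]) / (n_gct / occ[["GCT"]])
  expect_gt(ratio, 2.6)
  expect_lt(ratio, 3.4)
})

test_that("tet-mode start-peak fraction passes through", {
  scen <- sim_scenario(seed = 9, n_genes = 50, drug_mode = "tet",
                       tet_start_peak_fraction = 0.5)
  gen <- build_genome(scen)
  fp <- simulate_footprints(scen, gen$genome, gen$models, 2e4)
  frac <- mean(fp$truth$per_read$is_start_peak)
  expect_lt(abs(frac - 0.5), 0.02)
  # start-peak reads have the start codon in the P-site: A-site = codon 1
  expect_true(all(fp$truth$per_read$asite_codon_index[
    fp$truth$per_read$is_start_peak] == 1L))
})

test_that("mRNA reads follow abundance x length and stay in 30-70 nt", {
  scen <- sim_scenario(seed = 13, n_genes = 2, gene_length_range = c(100L, 100L),
                       mrna_abundance = c(1, 9), initiation_rate = 1)
  gen <- build_genome(scen)
  mr <- simulate_mrna_reads(scen, gen$genome, gen$models, 5e4)
  expect_true(all(mr$read_length >= 30 & mr$read_length <= 70))
  cnt <- count_gene_reads(mr, gen$models)
  ratio <- cnt$count[2] / cnt$count[1]
  expect_gt(ratio, 7.5)
  expect_lt(ratio, 10.7)
  expect_identical(mr, simulate_mrna_reads(scen, gen$genome, gen$models, 5e4))
})

test_that("poly(A) ambiguity shifts only A-ending 3' ends, past the full run", {
  fx <- toy_genome_fixture()
  # gA (+, start 50): transcript ATG AAA CGT... ; 3' end at tpos 5 is base A
  # with a template run AAA at tpos 3..5 -> shift lands before the run
  rec_a <- mk_reads(50, 55)                 # 3' end base A, run length 3
  rec_c <- mk_reads(50, 52)                 # 3' end base G (ATG): unchanged
  set.seed(1)
  out_c <- apply_polya_ambiguity(rec_c, fx$genome, prob = 1, seed = 2)
  expect_identical(out_c, rec_c)
  out_a <- apply_polya_ambiguity(rec_a, fx$genome, prob = 1, seed = 2)
  expect_equal(out_a$three_prime, 52L)      # moved 3 nt upstream past AAA
  expect_equal(out_a$read_length, 3L)
  # prob = 0 is the identity
  expect_identical(apply_polya_ambiguity(rec_a, fx$genome, prob = 0, seed = 2),
                   rec_a)
  # minus-strand gene: gB transcript ATG GGT GGT AGA AGA ...; tpos 11 is A
  # (AGA), run = tpos 10..11? codon AGA at 9..11: bases A G A; run length 1
  g3 <- 159 - 1 - 11                        # genome position of tpos 11
  rec_b <- mk_reads(159 - 1 - 0, g3, strand = "-")
  out_b <- apply_polya_ambiguity(rec_b, fx$genome, prob = 1, seed = 2)
  expect_equal(out_b$three_prime, g3 + 1L)  # one nt upstream on - strand
})
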