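test_that("relative density self-normalizes, spikes scale, depth scale cancels", {
  fx <- toy_genome_fixture()
  # constant depth 5 on gA positions
  trk <- build_depth_track(mk_reads(integer(), integer()), "three_prime_only", 300L)
  trk$depth[["+"]][51:83] <- 5
  rl <- relative_density(trk, fx$models[1, ], half_width = 4,
                         exclude_head = 1, exclude_tail = 1)
  mid <- rl$rel[rl$tpos >= 4 & rl$tpos <= 28]   # fully covered windows
  expect_true(all(abs(mid - 1) < 1e-12))
  # single spike of 9 in an otherwise-zero window: rel = 9 at the spike
  trk2 <- build_depth_track(mk_reads(integer(), integer()), "three_prime_only", 300L)
  trk2$depth[["+"]][66] <- 9
  rl2 <- relative_density(trk2, fx$models[1, ], half_width = 4,
                          exclude_head = 1, exclude_tail = 1)
  expect_equal(rl2$rel[rl2$tpos == 15], 9)
  # doubling depth changes nothing
  trk3 <- trk; trk3$depth[["+"]] <- trk3$depth[["+"]] * 2
  rl3 <- relative_density(trk3, fx$models[1, ], half_width = 4,
                          exclude_head = 1, exclude_tail = 1)
  expect_equal(rl3$rel, rl$rel)
  expect_equal(rl3$rel_norm, rl$rel_norm)
})

test_that("zero-window positions are missing, never zero", {
  fx <- toy_genome_fixture()
  trk <- build_depth_track(mk_reads(integer(), integer()), "three_prime_only", 300L)
  trk$depth[["+"]][51:60] <- 2                   # only the first 10 nt covered
  rl <- relative_density(trk, fx$models[1, ], half_width = 3,
                         exclude_head = 1, exclude_tail = 1)
  tailpos <- rl[rl$tpos > 20, ]
  expect_true(all(is.na(tailpos$rel)))
})

test_that("matrix cells equal a position-by-position brute-force recomputation", {
  fx <- toy_genome_fixture()
  set.seed(61)
  # random 3'-end piles inside each gene, transcript positions 0..L-1
  recs <- list()
  for (i in 1:3) {
    L <- fx$models$end[i] - fx$models$start[i]
    tp <- sample(0:(L - 1), 120, replace = TRUE)
    gp <- if (fx$models$strand[i] == "+") fx$models$start[i] + tp else
      fx$models$end[i] - 1 - tp
    recs[[i]] <- mk_reads(gp, gp, strand = fx$models$strand[i])
  }
  recs <- dplyr::bind_rows(recs)
  trk <- build_depth_track(recs, "three_prime_only", 300L)
  h <- 6L; eh <- 2L; et <- 1L; off <- 3L; pos <- -6:6
  rl <- relative_density(trk, fx$models, half_width = h,
                         exclude_head = eh, exclude_tail = et)
  m <- codon_position_matrix(rl, fx$models, fx$genome, off, positions = pos,
                             exclude_head = eh, exclude_tail = et)
  orc <- oracle_rel_density(trk, fx$models, h, eh, et)
  om <- oracle_matrix(orc, fx$models, fx$genome, off, pos, eh, et)
  expect_equal(attr(rl, "frame_factors"), orc$ff, tolerance = 1e-9)
  expect_equal(m$count, om$count, ignore_attr = TRUE)
  expect_equal(m$mean, om$mean, tolerance = 1e-9)
  # exclusions larger than every gene -> error
  expect_error(codon_position_matrix(rl, fx$models, fx$genome, off,
                                     positions = pos, exclude_head = 50,
                                     exclude_tail = 50), "no gene")
})

test_that("matrix columns have count-weighted mean one", {
  scen <- small_uniform_scenario(seed = 62, n_genes = 40)
  gen <- build_genome(scen)
  fp <- simulate_footprints(scen, gen$genome, gen$models, 2e5)
  trk <- build_depth_track(fp$records, "three_prime_only",
                           Biostrings::width(gen$genome)[1])
  rl <- relative_density(trk, gen$models)
  m <- codon_position_matrix(rl, gen$models, gen$genome, 12)
  for (j in seq_along(m$positions)) {
    ok <- !is.na(m$mean[, j])
    if (!any(ok)) next
    wm <- sum(m$count[ok, j] * m$mean[ok, j]) / sum(m$count[ok, j])
    expect_lt(abs(wm - 1), 1e-9)
  }
})

test_that("offset calibration recovers the cut model and fails without signal", {
  base <- list(seed = 63, n_genes = 150, gene_length_range = c(80L, 160L))
  for (cut in c(10L, 15L)) {
    scen <- sim_scenario(seed = base$seed, n_genes = base$n_genes,
                         gene_length_range = base$gene_length_range,
                         initiation_rate = 1, mrna_abundance = 1,
                         cut_offset = cut, drug_mode = "cm")
    gen <- build_genome(scen)
    fp <- simulate_footprints(scen, gen$genome, gen$models, 1e5)
    trk <- build_depth_track(fp$records, "three_prime_only",
                             Biostrings::width(gen$genome)[1])
    expect_equal(calibrate_asite_offset(trk, gen$models), cut)
  }
  # uniform random 3' ends: no initiation peak -> calibration failed
  scen <- small_uniform_scenario(seed = 64, n_genes = 120)
  gen <- build_genome(scen)
  glen <- Biostrings::width(gen$genome)[1]
  set.seed(64)
  pos <- sample(0:(glen - 1), 2e5, replace = TRUE)
  str <- sample(c("+", "-"), 2e5, replace = TRUE)
  trk <- build_depth_track(mk_reads(pos, pos, strand = str,
                                    reference = "chrSim"),
                           "three_prime_only", glen)
  expect_error(calibrate_asite_offset(trk, gen$models), "calibration failed")
})

test_that("synonymous usage is weighted family-normalized composition", {
  fx <- toy_genome_fixture()
  # single gene gC: ATG CTG CTG AAA AAG GGC GCC TAT TAC (stop dropped)
  one <- fx$models[3, ]
  u <- synonymous_usage(one, fx$genome)
  expect_equal(u$usage[u$codon == "AAA"], 0.5)        # AAA 1, AAG 1
  expect_equal(u$usage[u$codon == "CTG"], 1)          # only Leu codon used
  fam <- dplyr::summarise(dplyr::group_by(u, aa), s = sum(usage))
  expect_true(all(abs(fam$s - 1) < 1e-12 | is.na(fam$s)))
  # equal-composition genes: weights cannot change usage
  u_all <- synonymous_usage(fx$models, fx$genome,
                            tibble::tibble(gene_id = fx$models$gene_id,
                                           sample_id = "m1", count = 1L,
                                           rpkmc = c(1, 1, 1)))
  u_w <- synonymous_usage(fx$models, fx$genome,
                          tibble::tibble(gene_id = fx$models$gene_id,
                                         sample_id = "m1", count = 1L,
                                         rpkmc = c(2, 2, 2)))
  expect_equal(u_all$usage, u_w$usage)
  # upweighting one gene pulls usage toward its composition
  u10 <- synonymous_usage(fx$models, fx$genome,
                          tibble::tibble(gene_id = fx$models$gene_id,
                                         sample_id = "m1", count = 1L,
                                         rpkmc = c(0.001, 0.001, 10)))
  expect_gt(u10$usage[u10$codon == "CTG"], 0.99)
})

test_that("gene predicted density and its folds match direct recomputation", {
  fx <- toy_genome_fixture()
  sc <- sense_codons()
  dens1 <- stats::setNames(rep(1, 61), sc$codon)
  g1 <- gene_predicted_density(fx$models, fx$genome, dens1,
                               exclude_head = 1, exclude_tail = 1)
  expect_true(all(abs(g1$genes$predicted_density - 1) < 1e-12))
  expect_equal(g1$max_fold, 1)
  expect_equal(g1$central90_fold, 1)
  # random densities: brute force per gene
  set.seed(71)
  dens <- stats::setNames(exp(rnorm(61, 0, 0.3)), sc$codon)
  g2 <- gene_predicted_density(fx$models, fx$genome, dens,
                               exclude_head = 1, exclude_tail = 1)
  for (i in 1:3) {
    cds <- riboflux:::gene_sequence(fx$genome, fx$models$reference[i],
                                    fx$models$start[i], fx$models$end[i],
                                    fx$models$strand[i])
    cdn <- riboflux:::split_codons(cds)
    ns <- length(cdn) - 1
    cdn <- cdn[2:(ns - 1)]                 # drop codon 0 (head=1) and last (tail=1)
    expect_equal(g2$genes$predicted_density[i], mean(dens[cdn]),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(g2$max_fold,
               max(g2$genes$predicted_density) / min(g2$genes$predicted_density))
})

test_that("rescaling maps the density range onto the external rate range", {
  sc <- sense_codons()
  set.seed(72)
  dens <- stats::setNames(exp(rnorm(61, 0, 0.2)), sc$codon)
  # external with exactly 133-fold spread over a shared subset
  ext <- stats::setNames(exp(seq(log(1), log(133), length.out = 29)),
                         sample(sc$codon, 29))
  rs <- rescale_to_external(dens, ext)
  shared_rates <- rs$codon$rescaled_rate[rs$codon$codon %in% names(ext)]
  expect_equal(max(shared_rates) / min(shared_rates), 133, tolerance = 1e-9)
  # identity when the external range equals the reciprocal-density range
  sub <- names(dens)[1:10]
  ext2 <- 1 / dens[sub]
  rs2 <- rescale_to_external(dens[sub], ext2)
  expect_equal(stats::setNames(rs2$codon$rescaled_rate, rs2$codon$codon),
               ext2, tolerance = 1e-9)
  # two-codon toy against the closed-form affine map
  d2 <- c(AAA = 2, GAA = 0.5); e2 <- c(AAA = 1, GAA = 20)
  rs3 <- rescale_to_external(d2, e2)
  expect_equal(sort(rs3$codon$rescaled_rate), c(1, 20), tolerance = 1e-12)
  expect_error(rescale_to_external(c(AAA = 1, GAA = 1), e2), "degenerate")
  expect_error(rescale_to_external(d2, c(AAA = 1)), "2 shared")
})

test_that("isoacceptor pair machinery and asite summary behave on controlled input", {
  sc <- sense_codons()
  mk_mat <- function(vals) {
    m <- matrix(vals, nrow = 61, ncol = 3,
                dimnames = list(sc$codon, c("-3", "0", "3")))
    structure(list(mean = m, count = matrix(10L, 61, 3,
                                            dimnames = dimnames(m)),
                   positions = c(-3L, 0L, 3L), offset = 12L,
                   sample_id = NULL), class = "codon_density_matrix")
  }
  mats <- list(a = mk_mat(1), b = mk_mat(1))
  s <- asite_summary(mats)
  expect_true(all(s$codon$sd == 0))
  expect_true(all(abs(s$codon$norm_mean - 1) < 1e-12))
  pt <- isoacceptor_pair_test(s)
  expect_true(all(pt$pairs$diff == 0))
  # single pair: class test suppressed
  one <- isoacceptor_pair_test(s, default_isoacceptor_pairs()[1, ])
  expect_true(is.na(one$class_tests$p_value))
  # NNU dwell advantage across samples: strong one-sided signed rank
  set.seed(73)
  mats2 <- lapply(1:6, function(k) {
    v <- stats::setNames(rep(1, 61), sc$codon)
    prs <- default_isoacceptor_pairs()
    u <- prs$codon1[prs$pair_class == "NNU_NNC"]
    v[u] <- 1.2
    mk_mat(v * exp(rnorm(61, 0, 0.01)))
  })
  names(mats2) <- paste0("s", 1:6)
  pt2 <- isoacceptor_pair_test(asite_summary(mats2))
  p <- pt2$class_tests$p_value[pt2$class_tests$pair_class == "NNU_NNC"]
  expect_lt(p, 0.001)
  # missing codon -> pair skipped with warning
  m_miss <- mk_mat(1)
  m_miss$mean["TTT", ] <- NA
  vals <- asite_summary(list(a = m_miss, b = m_miss))$values
  vals <- vals[!is.na(vals$density), ]
  vals <- vals[vals$codon != "TTT", ]
  expect_warning(isoacceptor_pair_test(vals), "skipped")
})

test_that("CV profile is zero for equal cells and reports per-position spread", {
  sc <- sense_codons()
  m <- matrix(2, 61, 5, dimnames = list(sc$codon, as.character(-2:2)))
  cdm <- structure(list(mean = m, count = matrix(10L, 61, 5), positions = -2:2,
                        offset = 12L, sample_id = NULL),
                   class = "codon_density_matrix")
  cv <- position_cv_profile(cdm)
  expect_true(all(cv$value == 0))
  sdp <- position_cv_profile(cdm, statistic = "sd")
  expect_true(all(sdp$value == 0))
})

test_that("polyA sensitivity filter keeps only reads not followed by template A", {
  scen <- small_uniform_scenario(seed = 74, n_genes = 40)
  gen <- build_genome(scen)
  fp <- simulate_footprints(scen, gen$genome, gen$models, 1.5e5)
  res <- polya_sensitivity(fp$records, gen$genome, gen$models, 12)
  expect_lt(res$n_filtered, res$n_all)
  expect_gt(res$n_filtered, 0)
  # uniform dwell, no poly(A) corruption: both estimates sit near 1 and
  # the per-codon discrepancy stays small
  expect_lt(stats::median(res$per_codon$discrepancy, na.rm = TRUE), 0.1)
  expect_lt(max(abs(res$per_codon$density_all - 1), na.rm = TRUE), 0.5)
})
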