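test_that("read counting honours strand, >=1 nt overlap, and distinct totals", {
  fx <- toy_genome_fixture()
  recs <- dplyr::bind_rows(
    mk_reads(55, 70),            # inside gA (+)
    mk_reads(40, 50),            # overlaps gA by exactly 1 nt
    mk_reads(82, 95),            # overlaps gA last base
    mk_reads(0, 30),             # intergenic
    mk_reads(60, 70, strand = "-"))  # opposite strand of gA: never counts
  cnt <- count_gene_reads(recs, fx$models)
  expect_equal(cnt$count[cnt$gene_id == "gA"], 3L)
  expect_equal(cnt$count[cnt$gene_id == "gB"], 0L)
  expect_equal(total_cds_reads(cnt), 3L)
  # a read spanning two same-strand genes increments both, total once
  m2 <- tibble::tibble(gene_id = c("x", "y"), reference = "chrT",
                       start = c(10L, 40L), end = c(40L, 70L), strand = "+")
  c2 <- count_gene_reads(mk_reads(35, 45), m2)
  expect_equal(c2$count, c(1L, 1L))
  expect_equal(total_cds_reads(c2), 1L)
})

test_that("RPKMc matches the formula and is invariant to joint scaling", {
  models <- tibble::tibble(gene_id = "g", reference = "chrT",
                           start = 0L, end = 500L, strand = "+")
  counts <- tibble::tibble(gene_id = "g", count = 100L)
  e <- rpkmc(counts, models, total_cds_reads = 1e6)
  expect_equal(e$rpkmc, 100 / 0.5 / 1e6 * 1e6)   # = 200
  e0 <- rpkmc(tibble::tibble(gene_id = "g", count = 0L), models, 1e6)
  expect_equal(e0$rpkmc, 0)
  e2 <- rpkmc(tibble::tibble(gene_id = "g", count = 200L), models, 2e6)
  expect_equal(e2$rpkmc, e$rpkmc)
  expect_error(rpkmc(counts, models, 0), "positive")
  bad <- tibble::tibble(gene_id = "z", reference = "chrT", start = 5L,
                        end = 5L, strand = "+")
  expect_error(validate_gene_models <- riboflux:::validate_gene_models(bad))
})

test_that("rm_ratio averages replicates, forms RP/mRNA, excludes weak mRNA", {
  expr <- function(assay, vals, counts) {
    dplyr::bind_rows(lapply(seq_along(vals), function(k) {
      tibble::tibble(gene_id = c("a", "b", "c"), sample_id = paste0(assay, k),
                     count = counts[[k]], rpkmc = vals[[k]])
    }))
  }
  rp <- expr("rp", list(c(40, 10, 5), c(60, 30, 5)), list(c(40, 10, 5), c(60, 30, 5)))
  mr <- expr("m", list(c(20, 10, 0), c(30, 10, 0)), list(c(20, 10, 0), c(30, 10, 0)))
  rm <- rm_ratio(rp, mr, min_mrna = 10)
  expect_equal(rm$rm_ratio[rm$gene_id == "a"], 50 / 25)
  expect_equal(rm$rm_ratio[rm$gene_id == "b"], 20 / 10)
  expect_true(is.na(rm$rm_ratio[rm$gene_id == "c"]))
  expect_match(rm$excluded_reason[rm$gene_id == "c"], "mrna_reads")
  # scaling all rp samples by c scales every ratio by c
  rp2 <- dplyr::mutate(rp, rpkmc = rpkmc * 3)
  rm2 <- rm_ratio(rp2, mr, min_mrna = 10)
  expect_equal(rm2$rm_ratio, rm$rm_ratio * 3)
  # geometric averaging available
  rmg <- rm_ratio(rp, mr, min_mrna = 10, average = "geometric")
  expect_equal(rmg$mean_rp[rmg$gene_id == "a"], sqrt(40 * 60))
})

test_that("central fold range matches an independent quantile oracle", {
  expect_equal(central_fold_range(rep(1, 50), 0.8), 1)
  set.seed(21)
  v <- exp(runif(1000, 0, log(100)))       # log-uniform on [1, 100]
  # oracle: direct quantile ratio computed here, independently
  expect_equal(central_fold_range(v, 1.0),
               max(v) / min(v))
  expect_equal(central_fold_range(v, 0.8),
               unname(quantile(v, 0.9) / quantile(v, 0.1)))
  expect_lt(abs(central_fold_range(v, 0.8) - 100^0.8), 8)
  # scale invariance
  expect_equal(central_fold_range(v * 17, 0.8), central_fold_range(v, 0.8))
  expect_error(central_fold_range(c(1, -1)), "positive")
  expect_error(central_fold_range(numeric(0)), "empty")
})

test_that("quantile binning partitions near-equally and detects monotone trends", {
  rm <- tibble::tibble(gene_id = sprintf("g%04d", 1:4331),
                       mean_rp = 1, mean_mrna = 1, mrna_reads = 100L,
                       rm_ratio = exp(stats::rnorm(4331)),
                       excluded_reason = NA_character_)
  bins <- quantile_bin_summary(rm, stats::setNames(rm$rm_ratio, rm$gene_id),
                               n_bins = 20)
  expect_true(max(bins$bins$n) - min(bins$bins$n) <= 1)
  expect_equal(sum(bins$bins$n), 4331)
  expect_true(all(diff(bins$bins$mean_rm) > 0))   # covariate == rm: monotone
  expect_gt(glance(bins)$tau, 0.99)
  # independent covariate: tau near 0, p not tiny
  set.seed(2)
  cov2 <- stats::setNames(sample(rm$rm_ratio), rm$gene_id)
  b2 <- quantile_bin_summary(rm, cov2, n_bins = 20)
  expect_lt(abs(b2$tau), 0.05)
  expect_error(quantile_bin_summary(rm[1:5, ], cov2, n_bins = 20), "fewer genes")
})

test_that("Kendall test p-values are uniform under the null", {
  set.seed(31)
  n <- 300
  ps <- replicate(40, {
    rm <- tibble::tibble(gene_id = sprintf("g%03d", 1:n),
                         mean_rp = 1, mean_mrna = 1, mrna_reads = 100L,
                         rm_ratio = exp(stats::rnorm(n)),
                         excluded_reason = NA_character_)
    cov <- stats::setNames(stats::rnorm(n), rm$gene_id)
    quantile_bin_summary(rm, cov, n_bins = 5)$p_value
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("tm association recovers a planted slope and handles degenerates", {
  set.seed(41)
  n <- 400
  dens <- runif(n, 0, 0.02)
  rmv <- 3 - 40 * dens + stats::rnorm(n, sd = 0.15)
  models <- tibble::tibble(gene_id = sprintf("g%03d", 1:n), reference = "c",
                           start = 0L, end = 999L, strand = "+",
                           tm_segments = dens * 999)
  rm <- tibble::tibble(gene_id = models$gene_id, mean_rp = 1, mean_mrna = 1,
                       mrna_reads = 100L, rm_ratio = rmv,
                       excluded_reason = NA_character_)
  fit <- tm_association(rm, models)
  expect_lt(abs(fit$slope - (-40)), 4)
  expect_lt(fit$rho, -0.4)
  expect_equal(fit$x_intercept, -coef(lm(rmv ~ dens))[1] / fit$slope,
               ignore_attr = TRUE, tolerance = 1e-6)
  # constant predictor -> rho 0 by convention
  models0 <- dplyr::mutate(models, tm_segments = 0)
  fit0 <- tm_association(rm, models0)
  expect_equal(fit0$rho, 0)
  expect_true(fit0$constant_predictor)
  expect_error(tm_association(rm[1, ], models), "insufficient")
})
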