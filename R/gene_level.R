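# Gene-level depth: RPKMc normalization, the R/m translation-efficiency
# ratio, fold-range summaries, covariate binning, and the transmembrane
# association of Fig-1D style.

#' Count reads per gene and total CDS reads
#'
#' A read counts for a gene iff its aligned interval overlaps the gene's
#' CDS by at least 1 nt on the gene's strand. `total_cds_reads` is the
#' number of distinct reads overlapping at least one CDS: a read spanning
#' two overlapping genes increments both genes but the total once.
#'
#' @param records Alignment tibble.
#' @param models Gene-model tibble.
#' @return Tibble with `gene_id` and `count` (one row per model, zeros
#'   kept), with attribute `total_cds_reads`; see also [total_cds_reads()].
#' @export
count_gene_reads <- function(records, models) {
  validate_gene_models(models)
  counts <- integer(nrow(models))
  in_cds <- logical(nrow(records))
  for (s in c("+", "-")) {
    ri <- which(records$strand == s)
    mi <- which(models$strand == s)
    if (!length(ri) || !length(mi)) next
    lo <- pmin(records$five_prime[ri], records$three_prime[ri])
    hi <- pmax(records$five_prime[ri], records$three_prime[ri])
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(lo + 1L, hi + 1L),
      IRanges::IRanges(models$start[mi] + 1L, models$end[mi]),
      minoverlap = 1L)
    counts[mi] <- counts[mi] + tabulate(S4Vectors::subjectHits(hits),
                                        nbins = length(mi))
    in_cds[ri[unique(S4Vectors::queryHits(hits))]] <- TRUE
  }
  out <- tibble(gene_id = models$gene_id, count = counts)
  attr(out, "total_cds_reads") <- sum(in_cds)
  out
}

#' @rdname count_gene_reads
#' @param counts A tibble returned by [count_gene_reads()].
#' @export
total_cds_reads <- function(counts) attr(counts, "total_cds_reads")

#' RPKMc: reads per kilobase per million CDS reads
#'
#' `RPKMc = count / (CDS length / 1000 nt) / total_cds_reads * 1e6`. The
#' length is the annotated CDS span `end - start`.
#'
#' @param counts Tibble from [count_gene_reads()] (columns `gene_id`,
#'   `count`).
#' @param models Gene-model tibble.
#' @param total_cds_reads Total distinct CDS-overlapping reads; defaults to
#'   the attribute carried by `counts`.
#' @param sample_id Optional label stored in the output.
#' @return Tibble `gene_id`, `sample_id`, `count`, `length_nt`, `rpkmc`,
#'   with attribute `total_cds_reads`.
#' @export
rpkmc <- function(counts, models, total_cds_reads = NULL, sample_id = "s1") {
  if (is.null(total_cds_reads)) total_cds_reads <- attr(counts, "total_cds_reads")
  if (is.null(total_cds_reads) || total_cds_reads <= 0) {
    abort("total_cds_reads must be a positive number")
  }
  len <- unname(setNames(models$end - models$start,
                         models$gene_id)[counts$gene_id])
  if (any(is.na(len) | len <= 0)) abort("zero-length or unknown gene in counts")
  out <- tibble(gene_id = counts$gene_id, sample_id = sample_id,
                count = counts$count, length_nt = as.integer(len),
                rpkmc = counts$count / (len / 1000) / total_cds_reads * 1e6)
  attr(out, "total_cds_reads") <- total_cds_reads
  out
}

#' One-call expression table for several samples
#'
#' Convenience wrapper: counts and RPKMc-normalizes each read set against a
#' shared annotation and binds the per-sample rows.
#'
#' @param read_sets Named list of alignment tibbles (names become
#'   `sample_id`).
#' @param models Gene-model tibble.
#' @return Long expression tibble as from [rpkmc()].
#' @export
expression_table <- function(read_sets, models) {
  stopifnot(length(read_sets) >= 1, !is.null(names(read_sets)))
  bind_rows(lapply(names(read_sets), function(s) {
    cnt <- count_gene_reads(read_sets[[s]], models)
    rpkmc(cnt, models, sample_id = s)
  }))
}

#' R/m ratio: RP depth over mRNA depth per gene
#'
#' Averages RPKMc over replicate samples within each assay (arithmetic by
#' default, geometric optionally), then forms rm = mean RP / mean mRNA.
#' Genes whose summed mRNA read count is below `min_mrna` (or whose mean
#' mRNA RPKMc is 0) are excluded with a recorded reason: a ratio over a
#' near-empty denominator is noise, not a measurement.
#'
#' @param rp,mrna Long expression tibbles ([rpkmc()] format) for the RP and
#'   mRNA assays.
#' @param min_mrna Minimum total mapped mRNA reads per gene (default 10).
#' @param average `"arithmetic"` or `"geometric"` replicate averaging.
#' @return Tibble `gene_id`, `mean_rp`, `mean_mrna`, `mrna_reads`,
#'   `rm_ratio`, `excluded_reason` (NA when retained).
#' @export
rm_ratio <- function(rp, mrna, min_mrna = 10, average = c("arithmetic", "geometric")) {
  average <- match.arg(average)
  avg <- if (average == "arithmetic") mean else function(x) exp(mean(log(x)))
  summarise_assay <- function(x, nm) {
    x |>
      group_by(.data$gene_id) |>
      summarise("{nm}" := avg(.data$rpkmc), reads = sum(.data$count),
                .groups = "drop")
  }
  a <- summarise_assay(rp, "mean_rp") |> select(-"reads")
  b <- summarise_assay(mrna, "mean_mrna") |> rename(mrna_reads = "reads")
  out <- inner_join(a, b, by = "gene_id") |>
    mutate(excluded_reason = dplyr::case_when(
      .data$mrna_reads < min_mrna ~ sprintf("mrna_reads < %g", min_mrna),
      .data$mean_mrna == 0 ~ "mean_mrna == 0",
      TRUE ~ NA_character_),
      rm_ratio = ifelse(is.na(.data$excluded_reason),
                        .data$mean_rp / .data$mean_mrna, NA_real_))
  out[, c("gene_id", "mean_rp", "mean_mrna", "mrna_reads", "rm_ratio",
          "excluded_reason")]
}

#' Fold difference spanned by the central fraction of a distribution
#'
#' Ratio of the upper to the lower quantile that bound the central
#' `central_fraction` of the values, e.g. `central_fraction = 0.8` is the
#' 90th/10th percentile ratio ("80% of the genes fall within an x-fold
#' range").
#'
#' @param values Strictly positive numeric vector.
#' @param central_fraction Fraction in (0, 1].
#' @return A single fold value.
#' @export
central_fold_range <- function(values, central_fraction = 0.8) {
  if (!length(values)) abort("values is empty")
  if (any(values <= 0)) abort("values must be strictly positive")
  if (central_fraction <= 0 || central_fraction > 1) {
    abort("central_fraction must be in (0, 1]")
  }
  lo <- (1 - central_fraction) / 2
  q <- quantile(values, c(lo, 1 - lo), names = FALSE)
  q[2] / q[1]
}

#' Bin genes by a covariate and summarise the R/m ratio per bin
#'
#' Genes are ranked by the covariate (ties broken by gene id so the
#' partition is deterministic) and split into `n_bins` near-equal groups;
#' per-bin mean covariate, mean and SD of rm are returned, together with a
#' Kendall rank-correlation test of the per-gene covariate against rm.
#'
#' @param rm [rm_ratio()] output (excluded genes dropped).
#' @param covariate Named numeric vector (names = gene ids) or a tibble
#'   with columns `gene_id` and `value`.
#' @param n_bins Number of groups (default 20).
#' @return An object of class `rm_bin_summary`; see [tidy.rm_bin_summary()]
#'   and [glance.rm_bin_summary()].
#' @export
quantile_bin_summary <- function(rm, covariate, n_bins = 20) {
  if (n_bins < 2) abort("n_bins must be >= 2")
  cov_tbl <- if (is_tibble(covariate) || is.data.frame(covariate)) {
    tibble(gene_id = covariate$gene_id, value = covariate$value)
  } else {
    tibble(gene_id = names(covariate), value = unname(covariate))
  }
  d <- rm |>
    filter(is.na(.data$excluded_reason)) |>
    inner_join(cov_tbl, by = "gene_id") |>
    filter(!is.na(.data$value), !is.na(.data$rm_ratio)) |>
    arrange(.data$value, .data$gene_id)
  if (nrow(d) < n_bins) abort("covariate available for fewer genes than bins")
  d$bin <- dplyr::ntile(seq_len(nrow(d)), n_bins)
  bins <- d |>
    group_by(.data$bin) |>
    summarise(n = dplyr::n(), mean_covariate = mean(.data$value),
              mean_rm = mean(.data$rm_ratio), sd_rm = sd(.data$rm_ratio),
              .groups = "drop")
  kt <- suppressWarnings(cor.test(d$value, d$rm_ratio, method = "kendall"))
  structure(list(bins = bins, n_bins = n_bins, n_genes = nrow(d),
                 tau = unname(kt$estimate), statistic = unname(kt$statistic),
                 p_value = kt$p.value),
            class = "rm_bin_summary")
}

#' @export
print.rm_bin_summary <- function(x, ...) {
  cat(sprintf("<rm_bin_summary> %d genes in %d bins; Kendall tau = %.3f, p = %.3g\n",
              x$n_genes, x$n_bins, x$tau, x$p_value))
  print(x$bins, n = 5)
  invisible(x)
}

#' Association between membrane-segment density and the R/m ratio
#'
#' Predictor = transmembrane segments per nt of ORF. Returns the Spearman
#' correlation with rm and a least-squares line `rm ~ predictor` (slope and
#' x-intercept). A constant predictor is flagged and given rho = 0 by
#' convention.
#'
#' @param rm [rm_ratio()] output.
#' @param models Gene-model tibble carrying a `tm_segments` column.
#' @return Object of class `tm_association` with `rho`, `slope`,
#'   `x_intercept`, `n`, `constant_predictor`.
#' @export
tm_association <- function(rm, models) {
  if (!"tm_segments" %in% names(models)) abort("models lack tm_segments")
  d <- rm |>
    filter(is.na(.data$excluded_reason)) |>
    inner_join(select(models, "gene_id", "tm_segments", "start", "end"),
               by = "gene_id") |>
    mutate(tm_density = .data$tm_segments / (.data$end - .data$start)) |>
    filter(!is.na(.data$tm_density), !is.na(.data$rm_ratio))
  if (nrow(d) < 3) abort("insufficient genes for association (need >= 3)")
  constant <- sd(d$tm_density) == 0
  if (constant) {
    res <- list(rho = 0, slope = NA_real_, x_intercept = NA_real_,
                n = nrow(d), constant_predictor = TRUE)
  } else {
    rho <- suppressWarnings(cor(d$tm_density, d$rm_ratio, method = "spearman"))
    fit <- lm(rm_ratio ~ tm_density, data = d)
    slope <- unname(coef(fit)[2]); icpt <- unname(coef(fit)[1])
    res <- list(rho = rho, slope = slope, x_intercept = -icpt / slope,
                n = nrow(d), constant_predictor = FALSE)
  }
  structure(res, class = "tm_association")
}

#' @export
print.tm_association <- function(x, ...) {
  cat(sprintf("<tm_association> n = %d, Spearman rho = %.3f, slope = %.3f, x-intercept = %.3f\n",
              x$n, x$rho, x$slope, x$x_intercept))
  invisible(x)
}
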