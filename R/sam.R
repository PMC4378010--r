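# SAM-style (significance analysis of microarrays) selection of genes whose
# RP and mRNA depths are discordant: two-class unpaired d-statistic on
# log2(RPKMc + 1) with a small positive fudge constant, permutation-derived
# expected order statistics, and a delta band in the quantile-quantile plot.

#' Select genes with discordant RP and mRNA depth (SAM permutation test)
#'
#' Computes the moderated two-class d-statistic per gene,
#' `d = (mean(RP) - mean(mRNA)) / (s + s0)` on `log2(RPKMc + 1)`, where `s`
#' is the pooled standard error and `s0` the 5th percentile of the per-gene
#' `s` values. Expected order statistics come from `n_permutations` random
#' label permutations; a gene is selected when its ordered d departs from
#' the expected ordered d by more than `delta`. The false discovery rate is
#' the median permutation count of statistics beyond the implied cut
#' points, divided by the number of selected genes.
#'
#' @param rp,mrna Long expression tibbles ([rpkmc()] format), each with at
#'   least 2 samples.
#' @param delta Non-negative half-width of the selection band.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Seed for the permutations.
#' @param s0_quantile Quantile of per-gene standard errors used as the
#'   fudge constant (default 0.05).
#' @return Object of class `sam_selection`; `tidy()` gives the per-gene
#'   table (d, expected d, selected, direction), `glance()` the summary.
#' @export
sam_select <- function(rp, mrna, delta, n_permutations = 1000, seed = 1L,
                       s0_quantile = 0.05) {
  if (delta < 0) abort("delta must be >= 0")
  wide <- function(x) {
    m <- tidyr::pivot_wider(x[, c("gene_id", "sample_id", "rpkmc")],
                            names_from = "sample_id", values_from = "rpkmc")
    mat <- as.matrix(m[, -1, drop = FALSE])
    rownames(mat) <- m$gene_id
    mat
  }
  a <- wide(rp); b <- wide(mrna)
  if (ncol(a) < 2 || ncol(b) < 2) abort("need >= 2 samples per assay")
  genes <- intersect(rownames(a), rownames(b))
  x <- cbind(log2(a[genes, , drop = FALSE] + 1),
             log2(b[genes, , drop = FALSE] + 1))
  n1 <- ncol(a); n2 <- ncol(b); grp <- c(rep(1L, n1), rep(2L, n2))
  d_stat <- function(x, grp) {
    m1 <- rowMeans(x[, grp == 1L, drop = FALSE])
    m2 <- rowMeans(x[, grp == 2L, drop = FALSE])
    v1 <- apply(x[, grp == 1L, drop = FALSE], 1, stats::var)
    v2 <- apply(x[, grp == 2L, drop = FALSE], 1, stats::var)
    k1 <- sum(grp == 1L); k2 <- sum(grp == 2L)
    s <- sqrt(((k1 - 1) * v1 + (k2 - 1) * v2) / (k1 + k2 - 2) * (1 / k1 + 1 / k2))
    list(diff = m1 - m2, s = s)
  }
  obs <- d_stat(x, grp)
  s0 <- quantile(obs$s, s0_quantile, names = FALSE)
  d <- obs$diff / (obs$s + s0)
  withr_seed(seed)
  perm_sorted <- matrix(NA_real_, nrow = length(d), ncol = n_permutations)
  for (p in seq_len(n_permutations)) {
    pg <- sample(grp)
    ps <- d_stat(x, pg)
    perm_sorted[, p] <- sort(ps$diff / (ps$s + s0))
  }
  d_expected_sorted <- rowMeans(perm_sorted)
  ord <- order(d)
  d_sorted <- d[ord]
  # displacement beyond delta, with sign consistency: a gene called
  # RP-high must itself have d > 0 (guards the degenerate all-zero-d case)
  disp <- d_sorted - d_expected_sorted
  sel_sorted <- (disp > delta & d_sorted > 0) | (disp < -delta & d_sorted < 0)
  # cut points in d-space implied by the band
  up_idx <- which(sel_sorted & disp > 0)
  lo_idx <- which(sel_sorted & disp < 0)
  cut_up <- if (length(up_idx)) min(d_sorted[up_idx]) else Inf
  cut_lo <- if (length(lo_idx)) max(d_sorted[lo_idx]) else -Inf
  n_selected <- sum(sel_sorted)
  fdr <- if (n_selected == 0) 0 else {
    false_per_perm <- colSums(perm_sorted >= cut_up | perm_sorted <= cut_lo)
    min(1, median(false_per_perm) / n_selected)
  }
  per_gene <- tibble(gene_id = genes[ord], d = d_sorted,
                     d_expected = d_expected_sorted,
                     selected = sel_sorted,
                     direction = ifelse(disp > 0, "high_rp", "low_rp"))
  per_gene$direction[!per_gene$selected] <- NA_character_
  structure(list(per_gene = per_gene, delta = delta, s0 = s0,
                 n_permutations = n_permutations, n_selected = n_selected,
                 fdr = fdr, cut_up = cut_up, cut_lo = cut_lo),
            class = "sam_selection")
}

#' @export
print.sam_selection <- function(x, ...) {
  cat(sprintf("<sam_selection> delta = %.3g: %d genes selected, FDR = %.4f (%d permutations, s0 = %.4f)\n",
              x$delta, x$n_selected, x$fdr, x$n_permutations, x$s0))
  invisible(x)
}
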