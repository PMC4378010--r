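# broom-style tidiers for the fitted/selected objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a SAM selection
#' @param x A `sam_selection`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene_id`, `d`, `d_expected`, `selected`,
#'   `direction`.
#' @export
tidy.sam_selection <- function(x, ...) x$per_gene

#' Summarise a SAM selection
#' @param x A `sam_selection`.
#' @param ... Unused.
#' @return One-row tibble: `delta`, `n_selected`, `fdr`, `s0`,
#'   `n_permutations`.
#' @export
glance.sam_selection <- function(x, ...) {
  tibble(delta = x$delta, n_selected = x$n_selected, fdr = x$fdr,
         s0 = x$s0, n_permutations = x$n_permutations)
}

#' Tidy a covariate bin summary
#' @param x An `rm_bin_summary`.
#' @param ... Unused.
#' @return Per-bin tibble: `bin`, `n`, `mean_covariate`, `mean_rm`,
#'   `sd_rm`.
#' @export
tidy.rm_bin_summary <- function(x, ...) x$bins

#' Summarise a covariate bin summary
#' @param x An `rm_bin_summary`.
#' @param ... Unused.
#' @return One-row tibble: `n_genes`, `n_bins`, `tau`, `statistic`,
#'   `p_value`, `bin_fold` (highest over lowest bin mean).
#' @export
glance.rm_bin_summary <- function(x, ...) {
  tibble(n_genes = x$n_genes, n_bins = x$n_bins, tau = x$tau,
         statistic = x$statistic, p_value = x$p_value,
         bin_fold = max(x$bins$mean_rm) / min(x$bins$mean_rm))
}

#' Tidy a transmembrane association fit
#' @param x A `tm_association`.
#' @param ... Unused.
#' @return One-row tibble: `rho`, `slope`, `x_intercept`, `n`,
#'   `constant_predictor`.
#' @export
tidy.tm_association <- function(x, ...) {
  tibble(rho = x$rho, slope = x$slope, x_intercept = x$x_intercept,
         n = x$n, constant_predictor = x$constant_predictor)
}

#' @rdname tidy.tm_association
#' @export
glance.tm_association <- tidy.tm_association

#' Tidy an A-site summary
#' @param x An `asite_summary`.
#' @param ... Unused.
#' @return Per-codon tibble: `codon`, `aa`, `mean`, `sd`, `norm_mean`.
#' @export
tidy.asite_summary <- function(x, ...) x$codon
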