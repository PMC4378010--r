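# ggplot2 quick-look figures for the main result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar geom_vline labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot a metagene profile
#' @param object A [metagene_profile()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  ggplot(object, aes(x = .data$position, y = .data$mean_depth)) +
    geom_line() +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    labs(x = "position from gene 5' end (nt)", y = "mean normalized depth",
         title = sprintf("metagene profile (%d genes, %s)",
                         object$n_genes[1], attr(object, "depth_mode"))) +
    theme_minimal()
}

#' Plot per-bin R/m means against the covariate
#' @param object An [quantile_bin_summary()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rm_bin_summary <- function(object, ...) {
  b <- object$bins
  ggplot(b, aes(x = .data$mean_covariate, y = .data$mean_rm)) +
    geom_errorbar(aes(ymin = .data$mean_rm - .data$sd_rm,
                      ymax = .data$mean_rm + .data$sd_rm), width = 0) +
    geom_point() +
    labs(x = "bin mean covariate", y = "bin mean R/m ratio",
         subtitle = sprintf("Kendall tau = %.3f, p = %.2g",
                            object$tau, object$p_value)) +
    theme_minimal()
}

#' Plot A-site densities of the 61 sense codons
#' @param object An [asite_summary()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asite_summary <- function(object, ...) {
  d <- arrange(object$codon, .data$aa, .data$codon)
  d$codon <- factor(d$codon, levels = d$codon)
  ggplot(d, aes(x = .data$codon, y = .data$mean, fill = .data$aa)) +
    geom_col() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0) +
    labs(x = NULL, y = "relative A-site ribosome density") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, size = 6),
                   legend.position = "none")
}

#' Plot a positional coefficient-of-variation profile
#' @param cv Tibble from [position_cv_profile()] (an extra `group` column
#'   facets/colours, e.g. drug mode).
#' @return A ggplot.
#' @export
plot_cv_profile <- function(cv) {
  p <- if ("group" %in% names(cv)) {
    ggplot(cv, aes(x = .data$position, y = .data$value,
                   colour = .data$group, linetype = .data$group))
  } else {
    ggplot(cv, aes(x = .data$position, y = .data$value))
  }
  p + geom_line(na.rm = TRUE) +
    geom_vline(xintercept = c(-15, -6, 0, 12), linetype = "dotted",
               colour = "grey60") +
    labs(x = "position relative to A-site first base (nt)",
         y = "CV of codon densities") +
    theme_minimal()
}
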