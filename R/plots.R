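#' @importFrom ggplot2 ggplot aes geom_line geom_ribbon geom_point geom_hline
#'   labs facet_wrap theme_minimal autoplot
NULL

#' @export
ggplot2::autoplot

#' Plot an allele accumulation curve
#'
#' Mean cumulative alleles as a percentage of the extrapolated total, with
#' a +/- 1 SD ribbon where the resampling SD is available, and horizontal
#' reference lines at the capture targets.
#'
#' @param object An [accumulation_curve()].
#' @param targets Target percentages drawn as reference lines.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accumulation_curve <- function(object, targets = c(70, 90), ...) {
  df <- tidy(object)
  s_hat <- attr(object, "S_hat")
  p <- ggplot(df, aes(x = .data$k, y = .data$pct))
  if (!all(is.na(df$sd))) {
    p <- p + geom_ribbon(aes(ymin = 100 * (.data$mean - .data$sd) / s_hat,
                             ymax = 100 * (.data$mean + .data$sd) / s_hat),
                         alpha = 0.25)
  }
  p + geom_line() + geom_point() +
    geom_hline(yintercept = targets, linetype = "dashed") +
    labs(x = paste0("cumulative ", attr(object, "unit_type"), " units"),
         y = "% of extrapolated total alleles") +
    theme_minimal()
}

#' Plot the allele frequency spectrum
#'
#' Density of allele relative frequencies per group, the standard view of
#' how rare-allele-heavy populations and seed collections are.
#'
#' @param spectrum Output of [allele_frequency_spectrum()].
#' @param by Grouping columns of the spectrum (facetted).
#' @return A ggplot.
#' @export
plot_allele_spectrum <- function(spectrum, by = "role") {
  spectrum$group <- interaction(spectrum[by], drop = TRUE, sep = "/")
  ggplot(spectrum, aes(x = .data$freq, fill = .data$group)) +
    ggplot2::geom_density(alpha = 0.4, bounds = c(0, 1)) +
    labs(x = "allele relative frequency", y = "density", fill = NULL) +
    theme_minimal()
}
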