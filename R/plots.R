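# ggplot2 displays for spectra and pseudo-allele ratios.

#' Plot an error spectrum
#'
#' Bar chart of the 12 substitution rates; multiple samples are dodged.
#'
#' @param object A `tm_spectrum` (or several stacked ones).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tm_spectrum <- function(object, ...) {
  multi <- length(unique(object$sample_id)) > 1L
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$substitution, y = .data$rate))
  if (multi) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$sample_id),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col(fill = "grey30")
  }
  p +
    ggplot2::labs(x = "substitution (transcript space)",
                  y = "error rate (bp⁻¹)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.tm_spectrum
#' @param spectra Stacked spectra with a grouping column.
#' @param group Grouping column name used for fill.
#' @export
plot_spectrum_groups <- function(spectra, group = "group") {
  ggplot2::ggplot(spectra,
                  ggplot2::aes(x = .data$substitution, y = .data$rate,
                               fill = .data[[group]])) +
    ggplot2::stat_summary(fun = mean, geom = "col", position = "dodge") +
    ggplot2::labs(x = "substitution (transcript space)",
                  y = "mean error rate (bp⁻¹)") +
    ggplot2::theme_minimal()
}

#' Plot the pseudo-allele mutant:WT ratio histogram
#'
#' @param histogram Output of [ratio_histogram()].
#' @return A ggplot object.
#' @export
plot_ratio_histogram <- function(histogram) {
  ggplot2::ggplot(histogram,
                  ggplot2::aes(x = (.data$bin_low + .data$bin_high) / 2,
                               y = .data$n)) +
    ggplot2::geom_col(width = 0.045, fill = "grey30") +
    ggplot2::labs(x = "mutant mRNA fraction", y = "pseudo-alleles") +
    ggplot2::theme_minimal()
}
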