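#' Manhattan-style plot of a sweep scan
#'
#' Window midpoints against the chosen statistic, colored by chromosome,
#' with the realized top-quantile threshold as a dashed line.
#'
#' @param object a `sweep_scan`
#' @param field `"fst"` or `"log2_ratio"`
#' @param ... unused
#' @return a ggplot object.
#' @export
autoplot.sweep_scan <- function(object, field = c("fst", "log2_ratio"), ...) {
  field <- match.arg(field)
  df <- dplyr::mutate(object$windows, mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(df, ggplot2::aes(.data$mid / 1e6, .data[[field]],
                                   color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = object$thresholds[[field]],
                        linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)",
                  y = if (field == "fst") expression(F[st])
                      else expression(log[2] * "(" * theta * pi * "-ratio)"),
                  color = "chrom") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' PCA scatter of the first two components
#'
#' @param object a `geno_pca`
#' @param ... unused
#' @return a ggplot object.
#' @export
autoplot.geno_pca <- function(object, ...) {
  ggplot2::ggplot(object$scores,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               color = .data$population,
                               shape = .data$cohort)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_frac[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_frac[2])
    ) +
    ggplot2::theme_minimal()
}

#' LD-decay curves
#'
#' @param curves output of [ld_decay_by_population()] (or
#'   [ld_decay_curve()] with an optional `population` column)
#' @return a ggplot object.
#' @export
plot_ld_decay <- function(curves) {
  has_pop <- "population" %in% names(curves)
  mapping <- if (has_pop) {
    ggplot2::aes((.data$bin_start + .data$bin_end) / 2e3, .data$mean_r2,
                 color = .data$population)
  } else {
    ggplot2::aes((.data$bin_start + .data$bin_end) / 2e3, .data$mean_r2)
  }
  ggplot2::ggplot(dplyr::filter(curves, .data$n_pairs > 0), mapping) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2)) +
    ggplot2::theme_minimal()
}
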