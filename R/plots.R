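#' Forest plot of adjusted odds ratios
#'
#' @param object A `delay_fit` from [fit_delay_model()].
#' @param ... Unused.
#' @return A ggplot: one row per model term, AOR with confidence interval on
#'   a log scale, reference line at 1.
#' @exportS3Method ggplot2::autoplot
autoplot.delay_fit <- function(object, ...) {
  res <- object$results[object$results$term != "(Intercept)", ]
  res$label <- factor(paste0(res$variable, ": ", res$level),
                      levels = rev(paste0(res$variable, ": ", res$level)))
  ggplot2::ggplot(res, ggplot2::aes(x = .data$estimate, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(
      x = "Adjusted odds ratio (log scale)", y = NULL,
      title = "Adjusted odds of a 30-day treatment delay",
      subtitle = sprintf("C = %.2f; N = %d", object$c_statistic, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' ECDF comparison behind a Kolmogorov-Smirnov result
#'
#' @param object A `ks_result` from [ks_two_sample()].
#' @param labels Length-2 group labels for the two samples.
#' @param ... Unused.
#' @return A ggplot of the two empirical CDFs.
#' @exportS3Method ggplot2::autoplot
autoplot.ks_result <- function(object, labels = c("PSN", "non-PSN"), ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(value = object$sample1, group = labels[1]),
    tibble::tibble(value = object$sample2, group = labels[2])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, colour = .data$group)) +
    ggplot2::stat_ecdf(linewidth = 0.7) +
    ggplot2::labs(
      x = "Days to treatment initiation", y = "Cumulative proportion treated",
      colour = NULL,
      title = "Time to treatment initiation by patient-sharing status",
      subtitle = sprintf("Kolmogorov-Smirnov D = %.3f, p = %.3g",
                         object$D_statistic, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Histogram of time to treatment initiation
#'
#' @param analytic Analytic rows with `tti_days` (and optionally `psn`).
#' @param by_psn Facet by PSN membership.
#' @return A ggplot histogram with the 30-day delay cut marked.
#' @export
plot_tti <- function(analytic, by_psn = FALSE) {
  p <- ggplot2::ggplot(analytic, ggplot2::aes(x = .data$tti_days)) +
    ggplot2::geom_histogram(binwidth = 7, boundary = 0, fill = "steelblue",
                            colour = "white", linewidth = 0.2) +
    ggplot2::geom_vline(xintercept = 30.5, linetype = "dashed",
                        colour = "firebrick") +
    ggplot2::labs(x = "Days from diagnosis to first treatment",
                  y = "Patients",
                  title = "Time to treatment initiation",
                  subtitle = "Dashed line: 30-day delay cut point") +
    ggplot2::theme_minimal()
  if (by_psn) p <- p + ggplot2::facet_wrap(~psn, scales = "free_y")
  p
}
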