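#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line
#'   geom_pointrange geom_hline scale_fill_viridis_c labs theme_minimal
#'   facet_wrap
NULL

#' @export
ggplot2::autoplot

#' Long-format comodulogram
#' @param x a [comodulogram()].
#' @param ... unused.
#' @return Tibble with `phase_freq`, `amp_freq`, `mi`.
#' @export
#' @exportS3Method generics::tidy
tidy.comodulogram <- function(x, ...) {
  tidyr::expand_grid(phase_freq = x$phase_freqs, amp_freq = x$amp_freqs) |>
    dplyr::mutate(mi = as.vector(t(x$mi)))
}

#' Comodulogram heatmap
#' @param object a [comodulogram()].
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.comodulogram <- function(object, ...) {
  ggplot(tidy(object), aes(.data$phase_freq, .data$amp_freq,
                           fill = .data$mi)) +
    geom_raster() +
    scale_fill_viridis_c(name = "MI") +
    labs(x = "phase frequency (Hz)", y = "amplitude frequency (Hz)",
         title = sprintf("Tort comodulogram (%s, %d epochs)",
                         object$channel %||% "", object$n_epochs)) +
    theme_minimal()
}

#' Animal-average log power spectrum plot
#'
#' @param spectrum tibble with `freq` and `log_power` ([animal_average()]),
#'   optionally a `channel` column for faceting.
#' @param fmax upper frequency limit, default 100 Hz.
#' @return A ggplot.
#' @export
plot_power_spectrum <- function(spectrum, fmax = 100) {
  dat <- dplyr::filter(spectrum, .data$freq >= 1, .data$freq <= fmax)
  p <- ggplot(dat, aes(.data$freq, .data$log_power)) +
    geom_line() +
    labs(x = "frequency (Hz)", y = "log power (ln uV^2/Hz)") +
    theme_minimal()
  if ("channel" %in% names(dat)) p <- p + facet_wrap(~channel)
  p
}

#' Contrast-table forest plot
#' @param object a `contrast_table` from [marginal_contrasts()].
#' @param q_threshold significance line, default 0.05.
#' @param ... unused.
#' @return A ggplot.
#' @export
#' @exportS3Method ggplot2::autoplot
autoplot.contrast_table <- function(object, q_threshold = 0.05, ...) {
  dat <- dplyr::mutate(tibble::as_tibble(object),
                       significant = .data$q < q_threshold)
  ggplot(dat, aes(.data$estimate, .data$comparison,
                  xmin = .data$estimate - .data$se,
                  xmax = .data$estimate + .data$se,
                  color = .data$significant)) +
    geom_pointrange() +
    geom_hline(yintercept = 0, linetype = 0) +
    labs(x = "estimated difference", y = NULL,
         color = sprintf("q < %g", q_threshold)) +
    theme_minimal()
}
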