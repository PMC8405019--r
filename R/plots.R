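#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a spectrogram
#'
#' @param object A `spectrogram`.
#' @param ... Unused.
#' @return A ggplot heatmap of power (dB) over time and frequency.
#' @export
autoplot.spectrogram <- function(object, ...) {
  df <- tidyr::expand_grid(time = object$window_times,
                           frequency = object$frequencies)
  df$power_db <- as.vector(t(object$power_db))
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$frequency,
                                   fill = .data$power_db)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "power (dB)") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)") +
    ggplot2::theme_minimal()
}

#' Plot the state-specific beta emission densities of a fit
#'
#' One panel per frequency band, one curve per state: the fitted beta
#' densities over scaled power.
#'
#' @param object A `beta_hmm_fit` or `beta_hmm`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.beta_hmm_fit <- function(object, ...) {
  autoplot.beta_hmm(object$model, ...)
}

#' @rdname autoplot.beta_hmm_fit
#' @export
autoplot.beta_hmm <- function(object, ...) {
  y <- seq(0.001, 0.999, length.out = 200)
  df <- tidy.beta_hmm(object) |>
    dplyr::rowwise() |>
    dplyr::reframe(state = .data$state, band = .data$band, y = y,
                   density = stats::dbeta(y, .data$a, .data$b))
  df$band <- factor(df$band, levels = object$bands$band)
  ggplot2::ggplot(df, ggplot2::aes(.data$y, .data$density,
                                   color = factor(.data$state))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~band, scales = "free_y") +
    ggplot2::labs(x = "scaled power", y = "density", color = "state") +
    ggplot2::theme_minimal()
}

#' Plot a decoded state path
#'
#' @param path Tibble from [viterbi()].
#' @return A ggplot step plot of state versus time.
#' @export
plot_state_path <- function(path) {
  x <- if ("time" %in% names(path)) path$time else path$window
  ggplot2::ggplot(dplyr::mutate(path, .x = x),
                  ggplot2::aes(.data$.x, .data$state)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_continuous(breaks = sort(unique(path$state))) +
    ggplot2::labs(x = if ("time" %in% names(path)) "time (s)" else "window",
                  y = "state") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
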