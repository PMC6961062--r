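# ggplot2 displays for each result type. These mirror the conventional
# tremor-study figures: per-channel traces, FFT spectra, coherence with the
# null limit as a dashed line and the CI as a ribbon, and a time-frequency
# power raster.

#' Plot the channels of a recording in the time domain
#'
#' @param rec A `tremor_recording`.
#' @param max_seconds Show at most this many seconds (default 10) so long
#'   recordings stay legible.
#' @return A ggplot object, channels in facets.
#' @export
plot_recording <- function(rec, max_seconds = 10) {
  fs <- rec_fs(rec)
  keep <- seq_len(min(nrow(rec), round(max_seconds * fs)))
  long <- tibble::as_tibble(rec[keep, ]) |>
    dplyr::mutate(time = (keep - 1) / fs) |>
    tidyr::pivot_longer(-"time", names_to = "channel", values_to = "value") |>
    dplyr::mutate(channel = factor(.data$channel, rec_channels(rec)$name))
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "amplitude (a.u.)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tremor_spectrum <- function(object, xlim = c(0, 30), ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$freq >= xlim[[1L]], .data$freq <= xlim[[2L]])
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power",
                  title = attr(object, "channel")) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tremor_spectra <- function(object, xlim = c(0, 30), ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$freq >= xlim[[1L]], .data$freq <= xlim[[2L]])
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$channel), scales = "free_y") +
    ggplot2::labs(x = "frequency (Hz)", y = "power") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tremor_coherence <- function(object, xlim = c(0, 30), ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$freq >= xlim[[1L]], .data$freq <= xlim[[2L]])
  lim <- attr(object, "confidence_limit")
  ggplot2::ggplot(d, ggplot2::aes(.data$freq, .data$coherence)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = lim, linetype = "dashed", colour = "red") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude-squared coherence",
                  subtitle = sprintf("L = %d segments, 95%% limit = %.3f",
                                     attr(object, "L"), lim)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.tremor_spectrogram <- function(object, ylim = c(0, 30), ...) {
  d <- dplyr::filter(tibble::as_tibble(object),
                     .data$freq >= ylim[[1L]], .data$freq <= ylim[[2L]])
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$freq, fill = .data$power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)", fill = "power",
                  title = attr(object, "channel")) +
    ggplot2::theme_minimal()
}
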