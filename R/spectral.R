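# One-sided power scaling: after demeaning, power is |X(f)|^2 folded onto
# the non-negative frequencies and scaled so the sum over bins equals the
# signal's sum of squared deviations (a discrete Parseval identity). The DC
# bin is exactly zero by construction.
onesided_power <- function(X, n) {
  nfreq <- n %/% 2L + 1L
  p <- Mod(X[seq_len(nfreq)])^2 / n
  if (nfreq > 2L) {
    last_paired <- if (n %% 2L == 0L) nfreq - 1L else nfreq
    p[2L:last_paired] <- 2 * p[2L:last_paired]
  } else if (nfreq == 2L && n %% 2L != 0L) {
    p[2L] <- 2 * p[2L]
  }
  p[[1L]] <- 0
  p
}

#' Full-segment FFT power spectrum
#'
#' Computes the one-sided power spectrum of the entire segment by a single
#' FFT — no windowing, no averaging — which gives the finest possible
#' frequency resolution `fs/N` for reading off a tremor peak. The mean is
#' removed first (otherwise the DC term of a rectified EMG envelope would
#' dominate), and power is scaled so that the bin sum equals the signal's
#' sum of squared deviations (Parseval).
#'
#' @param x Numeric sample vector, length >= 16.
#' @param fs Sampling rate, Hz.
#' @param channel Optional channel label carried into the result.
#' @return A `tremor_spectrum` tibble with columns `freq` (Hz, 0 … fs/2 in
#'   steps of fs/N) and `power` (>= 0), plus attributes `fs`, `n_samples`
#'   and `channel`.
#' @examples
#' sp <- power_spectrum(sin(2 * pi * 5 * seq(0, 30, by = 1e-3)), fs = 1000)
#' peak_frequency(sp)
#' @export
power_spectrum <- function(x, fs, channel = NA_character_) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 16L) {
    abort("Need at least 16 samples for a spectrum.",
          class = "tremorkit_insufficient_data")
  }
  if (!all(is.finite(x))) {
    abort("Samples must be finite.", class = "tremorkit_parse_error")
  }
  X <- stats::fft(x - mean(x))
  p <- onesided_power(X, n)
  out <- tibble::tibble(freq = (seq_along(p) - 1) * fs / n, power = p)
  attr(out, "fs") <- fs
  attr(out, "n_samples") <- n
  attr(out, "channel") <- channel
  class(out) <- c("tremor_spectrum", class(out))
  out
}

#' Per-channel power spectra of a recording
#'
#' @param rec A `tremor_recording` (typically after
#'   [preprocess_recording()]).
#' @return A long tibble with columns `channel`, `role`, `freq`, `power`
#'   (class `tremor_spectra`, attribute `fs`).
#' @export
recording_spectra <- function(rec) {
  ch <- rec_channels(rec)
  fs <- rec_fs(rec)
  out <- purrr::map2_dfr(ch$name, ch$role, function(nm, role) {
    sp <- power_spectrum(rec[[nm]], fs, channel = nm)
    dplyr::mutate(tibble::as_tibble(sp), channel = nm, role = role,
                  .before = 1L)
  })
  attr(out, "fs") <- fs
  class(out) <- c("tremor_spectra", class(out))
  out
}

#' Tremor-band peak frequency of a spectrum
#'
#' Returns the frequency of the maximum-power bin inside the search band.
#' The default band, 3–18 Hz, spans all organic tremors (cerebellar tremor
#' at the slow end to orthostatic tremor at the fast end). Ties are broken
#' toward the lower frequency so results are reproducible.
#'
#' @param spec A spectrum: any data frame with `freq` and `power` columns
#'   (e.g. from [power_spectrum()]).
#' @param band Numeric `c(lo, hi)` in Hz.
#' @return A one-row tibble with `frequency`, `power`, `band_lo`, `band_hi`.
#'   If every in-band bin has zero power there is no peak and `frequency`
#'   and `power` are `NA` (a distinct no-peak result, not an error).
#' @export
peak_frequency <- function(spec, band = c(3, 18)) {
  if (band[[2L]] < band[[1L]]) {
    abort("Band must satisfy lo <= hi.", class = "tremorkit_band_error")
  }
  sel <- spec$freq >= band[[1L]] & spec$freq <= band[[2L]]
  if (!any(sel)) {
    abort(sprintf("Band [%g, %g] Hz contains no frequency bins.",
                  band[[1L]], band[[2L]]),
          class = "tremorkit_band_error")
  }
  f <- spec$freq[sel]
  p <- spec$power[sel]
  if (all(p == 0)) {
    return(tibble::tibble(frequency = NA_real_, power = NA_real_,
                          band_lo = band[[1L]], band_hi = band[[2L]]))
  }
  i <- which.max(p)  # which.max takes the first maximum: lower-frequency tie-break
  tibble::tibble(frequency = f[[i]], power = p[[i]],
                 band_lo = band[[1L]], band_hi = band[[2L]])
}

#' Peak frequencies for every channel of a spectra table
#'
#' @param spectra A `tremor_spectra` tibble from [recording_spectra()].
#' @inheritParams peak_frequency
#' @return One row per channel: `channel`, `role`, `frequency`, `power`,
#'   `band_lo`, `band_hi`.
#' @export
peak_frequencies <- function(spectra, band = c(3, 18)) {
  spectra |>
    dplyr::group_by(.data$channel, .data$role) |>
    dplyr::group_modify(~ peak_frequency(.x, band)) |>
    dplyr::ungroup()
}
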