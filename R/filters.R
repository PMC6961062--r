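# Zero-phase Butterworth filtering.
#
# Filters are designed in pole-zero form and run as cascaded second-order
# sections (see sos.R), applied forward-backward so the net response has
# zero phase (attenuation |H(f)|^2 at each frequency, i.e. -6 dB at the
# nominal cutoffs). Edge transients are suppressed by odd-reflection
# padding with steady-state initial conditions, so a step at the signal
# boundary does not ring into the data.

# Steady-state initial filter state for a unit-amplitude input
# (direct-form II transposed), solved from the state recursion fixed point.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, numeric(n - length(b)))
  a <- c(a, numeric(n - length(a)))
  b <- b / a[[1L]]
  a <- a / a[[1L]]
  if (n == 1L) return(numeric(0))
  comp <- matrix(0, n - 1L, n - 1L)          # companion matrix of a
  comp[1L, ] <- -a[-1L]
  if (n > 2L) comp[cbind(2:(n - 1L), 1:(n - 2L))] <- 1
  B <- b[-1L] - a[-1L] * b[[1L]]
  solve(diag(n - 1L) - t(comp), B)
}

check_band <- function(low, high, fs, order) {
  if (!is.finite(low) || !is.finite(high) || low <= 0 || high <= low) {
    abort("Band edges must satisfy 0 < low < high.", class = "tremorkit_spec_error")
  }
  if (high >= fs / 2) {
    abort(sprintf("High cutoff %g Hz is at or above the Nyquist frequency %g Hz.",
                  high, fs / 2),
          class = "tremorkit_nyquist_error")
  }
  if (order < 1L) abort("Filter order must be >= 1.", class = "tremorkit_spec_error")
}

#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass (default third order, the standard choice
#' for tremor work) and applies it forward-backward, so the output has no
#' phase distortion — this preserves the temporal alignment between EMG and
#' accelerometry on which coherence analysis depends. Nyquist violations are
#' hard errors, never silent clamping.
#'
#' @param x Numeric sample vector.
#' @param fs Sampling rate, Hz.
#' @param low,high Band edges in Hz, `0 < low < high < fs/2`.
#' @param order Filter order (of each pass), default 3.
#' @return Filtered samples, same length as `x`.
#' @export
butter_bandpass <- function(x, fs, low, high, order = 3L) {
  check_band(low, high, fs, order)
  sos <- zpk2sos(butter_zpk(order, fs, low, high, type = "pass"))
  sos_filtfilt_refl(sos, as.numeric(x))
}

#' Zero-phase Butterworth low-pass filter
#'
#' @inheritParams butter_bandpass
#' @param cutoff Cutoff frequency in Hz, `0 < cutoff < fs/2`.
#' @return Filtered samples, same length as `x`.
#' @export
butter_lowpass <- function(x, fs, cutoff, order = 3L) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2) {
    abort(sprintf("Cutoff %g Hz must lie in (0, fs/2 = %g) Hz.", cutoff, fs / 2),
          class = "tremorkit_nyquist_error")
  }
  sos <- zpk2sos(butter_zpk(order, fs, cutoff, type = "low"))
  sos_filtfilt_refl(sos, as.numeric(x))
}

#' Full-wave rectification
#'
#' Takes the absolute value of the EMG, exposing the burst envelope: the
#' burst-rate (tremor-frequency) power that interference-pattern EMG hides
#' at high frequency is shifted into the low-frequency band.
#'
#' @param x Numeric sample vector.
#' @return `abs(x)`.
#' @export
rectify <- function(x) abs(x)

#' Envelope smoothing after rectification
#'
#' Third-order zero-phase Butterworth low-pass at `cutoff` Hz (default
#' 30 Hz, the upper edge of the organic tremor analysis band and of the
#' accelerometry band-pass).
#'
#' @inheritParams butter_bandpass
#' @param cutoff Smoothing cutoff in Hz; requires `fs > 2 * cutoff`.
#' @return Smoothed samples. Slight undershoot below zero is possible — a
#'   low-pass applied to a rectified signal is not sign-constrained.
#' @export
smooth_signal <- function(x, fs, cutoff = 30, order = 3L) {
  butter_lowpass(x, fs, cutoff, order)
}

#' Preprocess an accelerometry channel
#'
#' Band-pass 2–30 Hz (third-order Butterworth, zero-phase), spanning all
#' known organic tremors from cerebellar (~3 Hz) to orthostatic (~18 Hz)
#' tremor. The high-pass removes DC and slow postural drift, so the output
#' is zero-mean.
#'
#' @inheritParams butter_bandpass
#' @param band Band edges in Hz, default `c(2, 30)`.
#' @return Filtered samples.
#' @export
preprocess_acc <- function(x, fs, band = c(2, 30), order = 3L) {
  butter_bandpass(x, fs, band[[1L]], band[[2L]], order)
}

#' Preprocess a surface-EMG channel
#'
#' Band-pass 20–300 Hz (third-order Butterworth, zero-phase) to retain the
#' bulk of the surface-EMG frequency content, then full-wave rectification
#' and low-pass envelope smoothing — the standard demodulation chain that
#' turns burst-patterned EMG into an envelope whose spectral peak sits at
#' the tremor frequency.
#'
#' @inheritParams butter_bandpass
#' @param band Band edges in Hz, default `c(20, 300)`; requires
#'   `fs > 2 * band[2]`.
#' @param smooth_cutoff Envelope smoothing cutoff in Hz, default 30.
#' @return Preprocessed samples (rectified, smoothed envelope).
#' @export
preprocess_emg <- function(x, fs, band = c(20, 300), order = 3L,
                           smooth_cutoff = 30) {
  if (fs <= 2 * band[[2L]]) {
    abort(sprintf("fs = %g Hz too low for a %g Hz EMG low-pass (need fs > %g).",
                  fs, band[[2L]], 2 * band[[2L]]),
          class = "tremorkit_nyquist_error")
  }
  y <- butter_bandpass(x, fs, band[[1L]], band[[2L]], order)
  smooth_signal(rectify(y), fs, smooth_cutoff, order)
}

#' Preprocess every channel of a recording by its role
#'
#' Applies [preprocess_acc()] to ACC channels and [preprocess_emg()] to EMG
#' channels, returning a recording of the same shape.
#'
#' @param rec A `tremor_recording`.
#' @param acc_band,emg_band Band edges in Hz.
#' @param order Butterworth order, default 3.
#' @param smooth_cutoff EMG envelope smoothing cutoff in Hz.
#' @return A preprocessed `tremor_recording`.
#' @examples
#' \donttest{
#' rec <- simulate_recording(tremor_sim_params(duration_s = 4, seed = 1))
#' pre <- preprocess_recording(rec)
#' }
#' @export
preprocess_recording <- function(rec, acc_band = c(2, 30),
                                 emg_band = c(20, 300), order = 3L,
                                 smooth_cutoff = 30) {
  ch <- rec_channels(rec)
  fs <- rec_fs(rec)
  out <- rec
  for (i in seq_len(nrow(ch))) {
    x <- rec[[ch$name[[i]]]]
    out[[ch$name[[i]]]] <- if (ch$role[[i]] == "ACC") {
      preprocess_acc(x, fs, acc_band, order)
    } else {
      preprocess_emg(x, fs, emg_band, order, smooth_cutoff)
    }
  }
  out
}
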