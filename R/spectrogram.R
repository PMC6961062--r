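#' Power-of-two window length approximating one second
#'
#' Chooses the FFT window for the spectrogram as the power of two nearest
#' to the number of samples in one second (`round(fs)`), so windows are
#' ~1 s long and the FFT length is fast. Exact geometric-midpoint ties
#' resolve to the larger power.
#'
#' @param fs Sampling rate, Hz (>= 16).
#' @return Integer window length W.
#' @examples
#' pow2_window(1000)  # 1024
#' pow2_window(600)   # 512
#' @export
pow2_window <- function(fs) {
  if (!is.finite(fs) || fs < 16) {
    abort("`fs` must be >= 16 Hz.", class = "tremorkit_spec_error")
  }
  target <- round(fs)
  lo <- 2^floor(log2(target))
  hi <- 2^ceiling(log2(target))
  if (hi - target < target - lo) as.integer(hi)  # ties go to the larger power
  else if (target - lo < hi - target) as.integer(lo)
  else as.integer(hi)
}

#' Short-time Fourier spectrogram
#'
#' Time-resolved power spectra from sliding ~1 s windows with 50% overlap:
#' frames of `W = pow2_window(fs)` samples advance by `W/2`, each frame is
#' demeaned, Hann-windowed, and transformed with the same one-sided power
#' scaling as [power_spectrum()]. The number of frames is exactly
#' `floor((N - W) / (W/2)) + 1`; an incomplete trailing frame is dropped.
#'
#' @param x Numeric sample vector of length >= the window.
#' @param fs Sampling rate, Hz.
#' @param window_samples Window length override (even integer >= 16);
#'   default `pow2_window(fs)`.
#' @param channel Optional channel label carried into the result.
#' @return A `tremor_spectrogram` tibble in long format with columns
#'   `time` (window-centre seconds), `freq` (Hz, step `fs/W`) and `power`,
#'   plus attributes `window_samples`, `hop_samples`, `fs`, `n_frames`.
#' @export
spectrogram <- function(x, fs, window_samples = pow2_window(fs),
                        channel = NA_character_) {
  x <- as.numeric(x)
  n <- length(x)
  w <- as.integer(window_samples)
  if (is.na(w) || w < 16L || w %% 2L != 0L) {
    abort("`window_samples` must be an even integer >= 16.",
          class = "tremorkit_spec_error")
  }
  if (n < w) {
    abort(sprintf("Signal of %d samples is shorter than one %d-sample window.",
                  n, w),
          class = "tremorkit_insufficient_data")
  }
  hop <- w %/% 2L
  n_frames <- (n - w) %/% hop + 1L
  hann <- 0.5 - 0.5 * cos(2 * pi * (0:(w - 1L)) / w)
  nfreq <- w %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1) * fs / w
  frames <- purrr::map_dfr(seq_len(n_frames), function(i) {
    start0 <- (i - 1L) * hop
    seg <- x[(start0 + 1L):(start0 + w)]
    X <- stats::fft((seg - mean(seg)) * hann)
    tibble::tibble(time = (start0 + w / 2) / fs, freq = freqs,
                   power = onesided_power(X, w))
  })
  attr(frames, "window_samples") <- w
  attr(frames, "hop_samples") <- hop
  attr(frames, "fs") <- fs
  attr(frames, "n_frames") <- n_frames
  attr(frames, "channel") <- channel
  class(frames) <- c("tremor_spectrogram", class(frames))
  frames
}
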