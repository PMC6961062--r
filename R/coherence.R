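# Segmented, split-cosine-tapered magnitude-squared coherence with the
# Halliday null confidence limit and per-frequency confidence intervals.
#
# The estimator averages cross- and auto-spectra over L non-overlapping
# segments BEFORE forming the ratio (the Welch/Halliday estimator);
# averaging per-segment coherence would be identically 1 and is rejected.

#' Split a signal into non-overlapping segments
#'
#' @param x Numeric sample vector of length N.
#' @param window_samples Segment length W (>= 16).
#' @return A list of `floor(N / W)` contiguous segments in temporal order;
#'   the trailing `N %% W` samples are discarded.
#' @export
segment_signal <- function(x, window_samples) {
  n <- length(x)
  w <- as.integer(window_samples)
  if (is.na(w) || w < 16L) {
    abort("`window_samples` must be an integer >= 16.",
          class = "tremorkit_spec_error")
  }
  if (w > n) {
    abort(sprintf("Window of %d samples exceeds signal length %d.", w, n),
          class = "tremorkit_window_error")
  }
  L <- n %/% w
  lapply(seq_len(L), function(l) x[((l - 1L) * w + 1L):(l * w)])
}

# Split-cosine-bell weights: raised-cosine ramps over the first and last
# ceiling(p * W) samples, 1 in between. The half-sample offset makes the
# first/last weights positive (the ramp's endpoint values, not 0).
cosine_bell <- function(w, p) {
  if (!is.finite(p) || p < 0 || p > 0.5) {
    abort("Taper fraction `p` must lie in [0, 0.5].",
          class = "tremorkit_spec_error")
  }
  weights <- rep(1, w)
  r <- ceiling(p * w)
  if (r > 0L) {
    ramp <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
    weights[seq_len(r)] <- weights[seq_len(r)] * ramp
    tail_idx <- (w - r + 1L):w
    weights[tail_idx] <- weights[tail_idx] * rev(ramp)
  }
  weights
}

#' Apply a split-cosine taper to a segment
#'
#' Multiplies the segment by a cosine-bell window that ramps the first and
#' last `ceiling(p * length(segment))` samples with raised-cosine lobes and
#' leaves the middle untouched, reducing spectral leakage from the segment
#' edges. `p = 0` is the identity; `p = 0.5` degenerates to a full
#' Hann-type bell.
#'
#' @param segment Numeric sample vector.
#' @param p Taper fraction per end, in `[0, 0.5]`.
#' @return Tapered samples, same length.
#' @export
split_cosine_taper <- function(segment, p = 0.1) {
  segment * cosine_bell(length(segment), p)
}

#' Halliday 95% confidence limit for magnitude-squared coherence
#'
#' The null threshold for coherence estimated from L independent segments:
#' under independence, estimated coherence exceeds
#' `1 - alpha^(1 / (L - 1))` with probability `alpha` at each frequency.
#' Coherence above the limit is deemed significant.
#'
#' @param L Number of segments (>= 2).
#' @param alpha Significance level, default 0.05.
#' @return The scalar limit in (0, 1); strictly decreasing in L.
#' @examples
#' coherence_confidence_limit(2)   # 0.95
#' coherence_confidence_limit(58)
#' @export
coherence_confidence_limit <- function(L, alpha = 0.05) {
  if (L < 2) {
    abort("Need L >= 2 segments (with L = 1 the estimator is identically 1).",
          class = "tremorkit_degenerate_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort("`alpha` must lie in (0, 1).", class = "tremorkit_spec_error")
  }
  1 - alpha^(1 / (L - 1))
}

#' Confidence interval for an estimated coherence value
#'
#' Variance-stabilising construction: on the inverse-hyperbolic-tangent
#' scale of the coherency magnitude, `g = atanh(sqrt(C))` has approximate
#' variance `1 / (2L)`, so a normal interval of half-width
#' `qnorm(1 - alpha/2) / sqrt(2L)` is back-transformed and squared. The
#' lower bound is floored at 0 on the transformed scale (the coherency
#' magnitude cannot be negative), which keeps `low <= C <= high` in [0, 1].
#'
#' @param C Estimated magnitude-squared coherence, in `[0, 1]` (vectorised).
#' @param L Number of segments (>= 2).
#' @param alpha Significance level, default 0.05.
#' @return A tibble with columns `ci_low`, `ci_high`.
#' @export
coherence_ci <- function(C, L, alpha = 0.05) {
  if (L < 2) {
    abort("Need L >= 2 segments.", class = "tremorkit_degenerate_error")
  }
  if (any(C < 0 | C > 1)) {
    abort("Coherence values must lie in [0, 1].", class = "tremorkit_spec_error")
  }
  g <- atanh(sqrt(pmin(C, 1)))
  h <- stats::qnorm(1 - alpha / 2) / sqrt(2 * L)
  low <- pmax(tanh(g - h), 0)^2
  high <- pmin(tanh(g + h), 1)^2
  tibble::tibble(ci_low = low, ci_high = high)
}

#' Magnitude-squared coherence between two channels
#'
#' Both signals are cut into `L = floor(N / W)` non-overlapping segments;
#' each segment is demeaned, tapered with a split-cosine bell
#' ([split_cosine_taper()]), and Fourier-transformed. Cross- and
#' auto-spectra are averaged across segments and combined as
#' \deqn{C(f) = \frac{|\sum_l X_l(f)\,\overline{Y_l(f)}|^2}
#'   {\sum_l |X_l(f)|^2 \; \sum_l |Y_l(f)|^2}}
#' which lies in \[0, 1\] by the Cauchy–Schwarz inequality. No taper
#' renormalisation is applied — the window's scale cancels in the ratio.
#' The Halliday null limit and per-frequency confidence intervals are
#' attached (see [coherence_confidence_limit()], [coherence_ci()]).
#'
#' @param x,y Numeric sample vectors of equal length.
#' @param fs Sampling rate, Hz.
#' @param window_samples Segment length W; `floor(N / W)` must be >= 2.
#' @param alpha Significance level for limit and intervals, default 0.05.
#' @param p Taper fraction per end, default 0.1.
#' @return A `tremor_coherence` tibble with columns `freq`, `coherence`,
#'   `ci_low`, `ci_high`, and attributes `L`, `alpha`, `confidence_limit`,
#'   `window_samples`, `fs`.
#' @examples
#' set.seed(1)
#' x <- rnorm(4096)
#' co <- msc(x, x, fs = 1000, window_samples = 256)
#' all(co$coherence > 0.999)
#' @export
msc <- function(x, y, fs, window_samples, alpha = 0.05, p = 0.1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) {
    abort("`x` and `y` must have the same length.",
          class = "tremorkit_input_error")
  }
  w <- as.integer(window_samples)
  segs_x <- segment_signal(x, w)
  L <- length(segs_x)
  if (L < 2L) {
    abort(sprintf(
      "Only %d full segment(s) of %d samples fit; need at least 2 (with one segment coherence is identically 1).",
      L, w), class = "tremorkit_degenerate_error")
  }
  segs_y <- segment_signal(y, w)[seq_len(L)]
  weights <- cosine_bell(w, p)
  nfreq <- w %/% 2L + 1L
  sxx <- syy <- numeric(nfreq)
  sxy <- complex(real = numeric(nfreq), imaginary = numeric(nfreq))
  for (l in seq_len(L)) {
    X <- stats::fft((segs_x[[l]] - mean(segs_x[[l]])) * weights)[seq_len(nfreq)]
    Y <- stats::fft((segs_y[[l]] - mean(segs_y[[l]])) * weights)[seq_len(nfreq)]
    sxx <- sxx + Mod(X)^2
    syy <- syy + Mod(Y)^2
    sxy <- sxy + X * Conj(Y)
  }
  denom <- sxx * syy
  coh <- ifelse(denom > 0, Mod(sxy)^2 / denom, 0)
  coh <- pmin(pmax(coh, 0), 1)
  ci <- coherence_ci(coh, L, alpha)
  out <- tibble::tibble(freq = (seq_len(nfreq) - 1) * fs / w,
                        coherence = coh,
                        ci_low = ci$ci_low, ci_high = ci$ci_high)
  attr(out, "L") <- L
  attr(out, "alpha") <- alpha
  attr(out, "confidence_limit") <- coherence_confidence_limit(L, alpha)
  attr(out, "window_samples") <- w
  attr(out, "fs") <- fs
  class(out) <- c("tremor_coherence", class(out))
  out
}

#' Coherence between two channels of a recording
#'
#' Convenience verb over [msc()]. The analysis window may be given in
#' seconds (converted as `round(window_s * fs)` samples) or directly in
#' samples; samples take precedence.
#'
#' @param rec A `tremor_recording`.
#' @param x,y Channel names.
#' @param window_s Window length in seconds, default 1.
#' @param window_samples Window length in samples (overrides `window_s`).
#' @inheritParams msc
#' @return A `tremor_coherence` tibble (see [msc()]).
#' @export
coherence_between <- function(rec, x, y, window_s = 1, window_samples = NULL,
                              alpha = 0.05, p = 0.1) {
  ch <- rec_channels(rec)$name
  for (nm in c(x, y)) {
    if (!nm %in% ch) {
      abort(sprintf("No channel named '%s' in the recording.", nm),
            class = "tremorkit_input_error")
    }
  }
  w <- if (!is.null(window_samples)) window_samples else round(window_s * rec_fs(rec))
  msc(rec[[x]], rec[[y]], rec_fs(rec), w, alpha = alpha, p = p)
}
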