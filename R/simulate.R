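# Seedable generator of physiologically structured synthetic tremor
# recordings: a central oscillator with slow frequency drift drives the
# accelerometer trace directly and gates the EMG as bursts of broadband
# noise, one burst per tremor cycle per muscle, antagonists alternating.

#' Parameters of the synthetic tremor generator
#'
#' The defaults emulate the standard clinical protocol: 30 s recordings at
#' 1000 Hz with a tremor oscillation in the organic band (default 5 Hz, a
#' typical rest/postural tremor frequency), coherent EMG burst modulation
#' and broadband EMG noise.
#'
#' @param fs Sampling rate, Hz.
#' @param duration_s Recording length in seconds (>= 2).
#' @param f0 Tremor frequency in Hz; constrained to the organic tremor band
#'   \[3, 18\] Hz unless `enforce_band = FALSE` (for negative controls).
#' @param freq_jitter_sd Per-sample random-walk scale of the instantaneous
#'   frequency, Hz; the walk is clipped to `f0` ± 0.5 Hz.
#' @param acc_amp Amplitude of the accelerometer oscillation (arbitrary
#'   acceleration units).
#' @param acc_noise_sd SD of the additive ACC noise, band-shaped to
#'   2–30 Hz so preprocessing cannot trivially remove it.
#' @param emg_burst_depth Modulation depth m in \[0, 1\] of the EMG noise
#'   power by the oscillator; 0 = unmodulated noise, 1 = full gating.
#' @param emg_noise_sd SD of the broadband EMG noise.
#' @param antagonist_phase Phase offset (radians) between extensor and
#'   flexor bursts; the default pi gives the alternating antagonist pattern.
#' @param coupling Fraction in \[0, 1\] of the oscillator shared between
#'   the ACC trace and the EMG drive; below 1 the ACC mixes in an
#'   independent second oscillator (two-oscillator negative control).
#' @param seed Integer RNG seed; all randomness flows from it through one
#'   deterministic substream per noise source and channel.
#' @return A `tremor_sim_params` list.
#' @export
tremor_sim_params <- function(fs = 1000, duration_s = 30, f0 = 5,
                              freq_jitter_sd = 0.002, acc_amp = 1,
                              acc_noise_sd = 0.3, emg_burst_depth = 0.7,
                              emg_noise_sd = 1, antagonist_phase = pi,
                              coupling = 1, seed = 1L,
                              enforce_band = TRUE) {
  if (enforce_band && (f0 < 3 || f0 > 18)) {
    abort("`f0` must lie in the organic tremor band [3, 18] Hz (set `enforce_band = FALSE` for negative controls).",
          class = "tremorkit_spec_error")
  }
  if (duration_s < 2) {
    abort("`duration_s` must be at least 2 seconds.",
          class = "tremorkit_insufficient_data")
  }
  stopifnot(fs > 0, freq_jitter_sd >= 0, acc_noise_sd >= 0, emg_noise_sd >= 0,
            emg_burst_depth >= 0, emg_burst_depth <= 1,
            coupling >= 0, coupling <= 1)
  structure(list(fs = fs, duration_s = duration_s, f0 = f0,
                 freq_jitter_sd = freq_jitter_sd, acc_amp = acc_amp,
                 acc_noise_sd = acc_noise_sd,
                 emg_burst_depth = emg_burst_depth,
                 emg_noise_sd = emg_noise_sd,
                 antagonist_phase = antagonist_phase, coupling = coupling,
                 seed = as.integer(seed)),
            class = "tremor_sim_params")
}

# One substream seed per randomness source, all derived from the master
# seed. Uses a private RNG scope so callers' RNG state is untouched.
stream_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# Instantaneous phase of the central oscillator: frequency f0 plus a
# mean-reverting Gaussian random walk (AR(1) with a 1 s reversion time
# constant) clipped to f0 +/- 0.5 Hz, random initial phase. Mean reversion
# keeps the frequency wandering around f0 instead of diffusing to the clip
# boundary, which is the observed behaviour of organic tremor.
oscillator_phase <- function(params, seed) {
  n <- round(params$duration_s * params$fs)
  with_seed(seed, {
    phi0 <- runif(1, 0, 2 * pi)
    f <- if (params$freq_jitter_sd > 0) {
      rho <- exp(-1 / params$fs)  # 1 s time constant
      jit <- stats::filter(rnorm(n, 0, params$freq_jitter_sd), rho,
                           method = "recursive")
      params$f0 + pmin(pmax(as.numeric(jit), -0.5), 0.5)
    } else {
      rep(params$f0, n)
    }
    phi0 + 2 * pi * cumsum(f) / params$fs
  })
}

#' Simulate the central tremor oscillator
#'
#' Unit-amplitude drive `sin(phi[t])` whose instantaneous frequency wanders
#' around `f0` as a clipped random walk (within ± 0.5 Hz), mimicking the
#' slow frequency drift of organic tremor. Deterministic for a fixed seed.
#'
#' @param params A [tremor_sim_params()] object.
#' @return Numeric vector of `round(duration_s * fs)` samples.
#' @export
simulate_oscillator <- function(params) {
  sin(oscillator_phase(params, stream_seeds(params$seed, 1L)[[1L]]))
}

#' Simulate a six-channel tremor recording
#'
#' Generates the standard montage (L-ACC, L-ECR, L-FCR, R-ACC, R-ECR,
#' R-FCR). Per limb, an independent central oscillator drives
#' \itemize{
#'   \item the ACC trace: `acc_amp * (coupling * d + (1 - coupling) * d')`
#'     plus 2–30 Hz band-shaped noise, where `d'` is a second independent
#'     oscillator used when `coupling < 1`;
#'   \item the EMG traces: broadband Gaussian noise amplitude-modulated as
#'     `1 + m * max(0, sin(phase + shift))` — half-wave gating that
#'     produces one burst per tremor cycle, so rectification and smoothing
#'     demodulate the envelope back to `f0`; the flexor is shifted by
#'     `antagonist_phase` so antagonists alternate.
#' }
#' Both limbs use independent oscillators and noise; everything is
#' deterministic for a fixed seed.
#'
#' @param params A [tremor_sim_params()] object.
#' @return A `tremor_recording` with the six montage channels.
#' @examples
#' rec <- simulate_recording(tremor_sim_params(duration_s = 4, seed = 42))
#' rec
#' @export
simulate_recording <- function(params) {
  fs <- params$fs
  n <- round(params$duration_s * fs)
  seeds <- stream_seeds(params$seed, 10L)
  mat <- matrix(0, n, 6L)
  for (limb in 1:2) {
    base <- (limb - 1L) * 5L
    phi <- oscillator_phase(params, seeds[[base + 1L]])
    phi_alt <- oscillator_phase(params, seeds[[base + 2L]])
    d <- sin(phi)
    d_alt <- sin(phi_alt)
    acc_noise <- with_seed(seeds[[base + 3L]], rnorm(n))
    if (params$acc_noise_sd > 0) {
      acc_noise <- butter_bandpass(acc_noise, fs, 2, 30)
      acc_noise <- acc_noise * params$acc_noise_sd / stats::sd(acc_noise)
    } else {
      acc_noise <- numeric(n)
    }
    acc <- params$acc_amp *
      (params$coupling * d + (1 - params$coupling) * d_alt) + acc_noise
    m <- params$emg_burst_depth
    ecr <- with_seed(seeds[[base + 4L]], rnorm(n, 0, params$emg_noise_sd)) *
      (1 + m * pmax(sin(phi), 0))
    fcr <- with_seed(seeds[[base + 5L]], rnorm(n, 0, params$emg_noise_sd)) *
      (1 + m * pmax(sin(phi + params$antagonist_phase), 0))
    mat[, (limb - 1L) * 3L + 1:3] <- cbind(acc, ecr, fcr)
  }
  recording(mat, fs = fs, channels = default_montage())
}
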