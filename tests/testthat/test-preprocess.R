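fs <- 1000

design_band <- function(low, high, order = 3) {
  signal::butter(order, c(low, high) / (fs / 2), type = "pass")
}

test_that("empirical band-pass gain matches the analytic squared magnitude response", {
  for (band in list(c(2, 30), c(20, 300))) {
    flt <- design_band(band[1], band[2])
    probe <- c(1, 2, 3, 5, 8, 10, 15, 25, 40, 60, 100, 150, 250, 350)
    for (f in probe) {
      expected <- analytic_gain2(flt$b, flt$a, f, fs)
      if (expected < 0.01) next  # deep stopband measured separately
      got <- empirical_gain(function(x) butter_bandpass(x, fs, band[1], band[2]),
                            f, fs)
      expect_lt(abs(got - expected) / expected, 0.05)
    }
  }
})

test_that("deep stopband frequencies are strongly attenuated", {
  # 0.5 Hz and 50 Hz against the ACC band; amplitudes relative to input
  g_low <- empirical_gain(function(x) preprocess_acc(x, fs), 0.5, fs, seconds = 40)
  g_mains <- empirical_gain(function(x) preprocess_acc(x, fs), 50, fs)
  expect_lt(g_low, 0.1)
  expect_lt(g_mains, 0.05)
  g_200 <- empirical_gain(function(x) smooth_signal(x, fs), 200, fs)
  expect_lt(g_200, 0.01)
})

test_that("passband sines pass with ~unit amplitude and no phase lag", {
  expect_equal(empirical_gain(function(x) preprocess_acc(x, fs), 10, fs), 1,
               tolerance = 0.02)
  expect_equal(empirical_gain(function(x) preprocess_acc(x, fs), 5, fs), 1,
               tolerance = 0.02)
  expect_equal(empirical_gain(function(x) smooth_signal(x, fs), 5, fs), 1,
               tolerance = 0.02)
  # zero-phase: peak cross-correlation of a passband sine with its filtered
  # version sits at lag 0
  x <- sine_at(8, fs, 10)
  y <- butter_bandpass(x, fs, 2, 30)
  cc <- stats::ccf(x, y, lag.max = 25, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("DC is rejected by the band-passes and preserved by the smoother", {
  dc <- rep(5, 4000)
  expect_lt(max(abs(preprocess_acc(dc, fs))), 1e-6 * 5)
  expect_lt(max(abs(butter_bandpass(dc, fs, 20, 300))), 1e-6 * 5)
  sm <- smooth_signal(dc, fs)
  expect_equal(sm, dc, tolerance = 1e-6)
  # residual mean is edge-transient leakage only: < 0.2% of the removed DC
  expect_lt(abs(mean(preprocess_acc(sine_at(5, fs, 10) + 3, fs))) / 3, 2e-3)
})

test_that("butter_bandpass is linear", {
  set.seed(4)
  x <- rnorm(3000); y <- rnorm(3000)
  lhs <- butter_bandpass(2.5 * x - 1.25 * y, fs, 2, 30)
  rhs <- 2.5 * butter_bandpass(x, fs, 2, 30) - 1.25 * butter_bandpass(y, fs, 2, 30)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

test_that("Nyquist violations and too-short inputs are hard errors", {
  expect_error(butter_bandpass(rnorm(1000), fs, 2, 500),
               class = "tremorkit_nyquist_error")
  expect_error(preprocess_emg(rnorm(1000), fs = 600),
               class = "tremorkit_nyquist_error")
  expect_error(butter_bandpass(rnorm(10), fs, 2, 30),
               class = "tremorkit_insufficient_data")
})

test_that("rectify is |x| with the analytic mean and frequency doubling", {
  expect_equal(rectify(c(-1, 2, -3)), c(1, 2, 3))
  x <- sine_at(10, fs, 10, amp = 2)        # 100 cycles
  expect_equal(mean(rectify(x)), 2 * 2 / pi, tolerance = 0.01)
  sp <- power_spectrum(rectify(x), fs)
  pk <- sp$freq[which.max(sp$power)]
  expect_equal(pk, 20)                      # doubled fundamental
})

test_that("the EMG chain demodulates an amplitude-modulated carrier to the modulation rate", {
  t <- (0:(30 * fs - 1)) / fs
  carrier <- sin(2 * pi * 100 * t) * (1 + 0.8 * sin(2 * pi * 5 * t))
  env <- preprocess_emg(carrier, fs)
  pk <- peak_frequency(power_spectrum(env, fs), c(3, 18))
  expect_equal(pk$frequency, 5, tolerance = 0.05)
})

test_that("degenerate EMG inputs behave: zero in, zero out; DC killed", {
  expect_equal(preprocess_emg(numeric(2000), fs), numeric(2000))
  out <- preprocess_emg(rep(2, 2000), fs)
  expect_lt(max(abs(out)), 1e-6 * 2)
})
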