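test_that("segmentation arithmetic: counts, remainder, ordering, errors", {
  x <- seq_len(30000)
  segs <- segment_signal(x, 1024)
  expect_length(segs, 29L)
  expect_equal(29 * 1024 + 304, 30000)            # 304 trailing samples dropped
  expect_equal(segs[[1]], 1:1024)
  expect_equal(segs[[29]], (28 * 1024 + 1):(29 * 1024))

  expect_length(segment_signal(seq_len(1000), 1000), 1L)
  expect_error(segment_signal(seq_len(1000), 1100),
               class = "tremorkit_window_error")
})

test_that("split-cosine taper: flat middle, identity at p = 0, window energy", {
  w <- 1000; p <- 0.1
  x <- rep(1, w)
  y <- split_cosine_taper(x, p)
  r <- ceiling(p * w)
  expect_equal(y[(r + 1):(w - r)], rep(1, w - 2 * r))
  expect_lt(y[1], y[r])                            # ramp endpoint below maximum
  expect_gt(y[1], 0)
  # direct evaluation of the window formula
  ramp <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
  expect_equal(sum(y^2), 2 * sum(ramp^2) + (w - 2 * r))

  expect_identical(split_cosine_taper(x, 0), x)
  expect_error(split_cosine_taper(x, 0.6), class = "tremorkit_spec_error")

  # agreement with the classic split-cosine-bell of stats::spec.taper
  expect_equal(y, as.numeric(stats::spec.taper(x, p)), tolerance = 1e-12)
})

test_that("Halliday confidence limit: exact L=2 value, closed form, monotone", {
  expect_identical(coherence_confidence_limit(2, 0.05), 0.95)
  expect_equal(coherence_confidence_limit(21, 0.05), 1 - 0.05^(1 / 20))
  expect_equal(coherence_confidence_limit(21, 0.05), 0.1391, tolerance = 1e-4)
  lims <- vapply(2:200, coherence_confidence_limit, numeric(1), alpha = 0.05)
  expect_true(all(diff(lims) < 0))
  expect_lt(coherence_confidence_limit(58), coherence_confidence_limit(29))
  expect_error(coherence_confidence_limit(1), class = "tremorkit_degenerate_error")
})

test_that("coherence CI: bounds bracket the estimate, C=0 floor, width shrinks in L", {
  ci0 <- coherence_ci(0, 10)
  expect_equal(ci0$ci_low, 0)
  # direct arithmetic evaluation at C = 0.5, L = 29
  g <- atanh(sqrt(0.5)); h <- qnorm(0.975) / sqrt(2 * 29)
  ci <- coherence_ci(0.5, 29)
  expect_equal(ci$ci_low, tanh(g - h)^2, tolerance = 1e-12)
  expect_equal(ci$ci_high, tanh(g + h)^2, tolerance = 1e-12)

  widths <- vapply(c(5, 10, 20, 40, 80), function(L) {
    ci <- coherence_ci(0.5, L); ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  set.seed(21)
  C <- runif(50)
  ci <- coherence_ci(C, 12)
  expect_true(all(ci$ci_low <= C + 1e-12 & C <= ci$ci_high + 1e-12))
  expect_true(all(ci$ci_low >= 0 & ci$ci_high <= 1))
})

test_that("self-coherence is 1 and is invariant to scaling and sign", {
  set.seed(6)
  x <- rnorm(4096) + sine_at(7, 1000, 4096 / 1000)
  co <- msc(x, x, 1000, 512)
  expect_true(all(abs(co$coherence - 1) < 1e-9))
  co2 <- msc(x, -2 * x, 1000, 512)
  expect_true(all(abs(co2$coherence - 1) < 1e-9))
})

test_that("msc matches a brute-force evaluation of the defining formula (L=2, W=64)", {
  set.seed(7)
  fs <- 128; w <- 64
  x <- rnorm(128); y <- 0.5 * x + rnorm(128)
  weights <- {
    r <- ceiling(0.1 * w)
    ramp <- 0.5 * (1 - cos(pi * (seq_len(r) - 0.5) / r))
    c(ramp, rep(1, w - 2 * r), rev(ramp))
  }
  nf <- w / 2 + 1
  sxx <- syy <- numeric(nf); sxy <- complex(nf)
  for (l in 1:2) {
    idx <- ((l - 1) * w + 1):(l * w)
    X <- brute_dft((x[idx] - mean(x[idx])) * weights)[1:nf]
    Y <- brute_dft((y[idx] - mean(y[idx])) * weights)[1:nf]
    sxx <- sxx + Mod(X)^2; syy <- syy + Mod(Y)^2; sxy <- sxy + X * Conj(Y)
  }
  expected <- Mod(sxy)^2 / (sxx * syy)
  co <- msc(x, y, fs, w)
  expect_equal(attr(co, "L"), 2L)
  expect_equal(co$coherence, expected, tolerance = 1e-9)
})

test_that("coherence stays in [0,1] and carries a correct limit attribute", {
  set.seed(8)
  for (rep in 1:5) {
    x <- rnorm(3000); y <- rnorm(3000) + 0.3 * x
    co <- msc(x, y, 1000, 256)
    expect_true(all(co$coherence >= 0 & co$coherence <= 1 + 1e-12))
    expect_true(all(co$ci_low <= co$coherence & co$coherence <= co$ci_high))
    L <- attr(co, "L")
    expect_equal(attr(co, "confidence_limit"), 1 - 0.05^(1 / (L - 1)))
  }
})

test_that("a shared 5 Hz oscillator is detected above the null limit", {
  params <- tremor_sim_params(seed = 30, coupling = 1, emg_burst_depth = 0.7)
  # coherence is computed on preprocessed channels: rectification is what
  # demodulates the EMG burst train so a linear coupling at f0 exists
  rec <- preprocess_recording(simulate_recording(params))
  co <- coherence_between(rec, "R-ACC", "R-ECR", window_samples = 1024)
  at5 <- which.min(abs(co$freq - 5))
  expect_gt(co$coherence[at5], attr(co, "confidence_limit"))
})

test_that("degenerate inputs error: mismatched lengths, fewer than 2 segments", {
  expect_error(msc(rnorm(100), rnorm(99), 100, 32),
               class = "tremorkit_input_error")
  expect_error(msc(rnorm(100), rnorm(100), 100, 80),
               class = "tremorkit_degenerate_error")
  expect_error(coherence_between(
    simulate_recording(tremor_sim_params(duration_s = 2, seed = 1)),
    "R-ACC", "nope"), class = "tremorkit_input_error")
})
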