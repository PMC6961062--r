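test_that("identical columns give ICC exactly 1 with excellent reliability", {
  m <- cbind(c(4, 5, 6, 7, 9, 10), c(4, 5, 6, 7, 9, 10))
  fit <- icc_a1(m)
  expect_equal(fit$estimate, 1)
  expect_equal(fit$ci_low, 1)
  expect_equal(fit$category, "excellent")
})

test_that("absolute agreement penalises a constant offset; consistency does not", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- cbind(x, x + 10)
  fit <- icc_a1(m)
  expect_lt(fit$estimate, 1)
  expect_lt(fit$estimate, consistency_icc(m))
})

test_that("the packaged integer fixture matches the sums-of-squares oracle and a frozen reference", {
  m <- cbind(c(1, 3, 5, 2, 8, 4), c(2, 4, 7, 2, 6, 5))
  fit <- icc_a1(m)
  oracle <- brute_icc_a1(m)
  expect_equal(fit$estimate, oracle$estimate, tolerance = 1e-10)
  expect_equal(fit$ci_low, oracle$ci_low, tolerance = 1e-10)
  expect_equal(fit$ci_high, oracle$ci_high, tolerance = 1e-10)
  # frozen from an independent implementation of ICC(A,1) on this matrix
  expect_equal(fit$estimate, 0.823151125401929, tolerance = 1e-9)
})

test_that("estimate and CI match the oracle on 100 random matrices", {
  set.seed(31)
  for (i in 1:100) {
    n <- sample(5:30, 1); k <- sample(2:3, 1)
    subj <- rnorm(n, sd = runif(1, 0.5, 3))
    m <- outer(subj, rep(1, k)) + matrix(rnorm(n * k, sd = 0.5), n, k) +
      matrix(rep(rnorm(k, sd = 0.3), each = n), n, k)
    fit <- icc_a1(m)
    oracle <- brute_icc_a1(m)
    expect_equal(fit$estimate, oracle$estimate, tolerance = 1e-10)
    expect_equal(fit$ci_low, oracle$ci_low, tolerance = 1e-10)
    expect_equal(fit$ci_high, oracle$ci_high, tolerance = 1e-10)
    expect_true(fit$ci_low <= fit$estimate && fit$estimate <= fit$ci_high)
  }
})

test_that("ICC is invariant to common shifts and positive scalings", {
  set.seed(32)
  m <- cbind(rnorm(10, 5), rnorm(10, 5))
  f0 <- icc_a1(m)
  expect_equal(icc_a1(m + 100)$estimate, f0$estimate, tolerance = 1e-10)
  expect_equal(icc_a1(m * 7)$estimate, f0$estimate, tolerance = 1e-10)
})

test_that("CI width decreases with n on average", {
  set.seed(33)
  width_at <- function(n) {
    mean(vapply(1:30, function(i) {
      subj <- rnorm(n)
      m <- outer(subj, rep(1, 2)) + matrix(rnorm(n * 2, sd = 0.4), n, 2)
      fit <- icc_a1(m)
      fit$ci_high - fit$ci_low
    }, numeric(1)))
  }
  expect_gt(width_at(6), width_at(30))
})

test_that("reliability categories follow the published thresholds", {
  expect_identical(reliability_category(c(0.45, 0.6, 0.8, 0.95)),
                   c("poor", "moderate", "good", "excellent"))
  expect_identical(reliability_category(c(0.5, 0.75, 0.9)),
                   c("moderate", "good", "excellent"))  # closed on the left
  expect_identical(reliability_category(-0.2), "poor")
})

test_that("categorisation basis is the CI lower bound by default, estimate on request", {
  set.seed(34)
  subj <- rnorm(8, sd = 1)
  m <- outer(subj, rep(1, 2)) + matrix(rnorm(16, sd = 0.45), 8, 2)
  fit_ci <- icc_a1(m)
  fit_est <- icc_a1(m, categorize_on = "estimate")
  expect_identical(fit_ci$category, reliability_category(fit_ci$ci_low))
  expect_identical(fit_est$category, reliability_category(fit_est$estimate))
})

test_that("degenerate and malformed ratings are rejected", {
  expect_error(icc_a1(matrix(3, 6, 2)), class = "tremorkit_degenerate_error")
  expect_error(icc_a1(matrix(1:4, 1, 4)), class = "tremorkit_input_error")
  expect_error(icc_a1(cbind(c(1, NA, 3), c(1, 2, 3))),
               class = "tremorkit_input_error")
})

test_that("tidy and glance return one-row summaries", {
  fit <- icc_a1(cbind(c(1, 3, 5, 2, 8, 4), c(2, 4, 7, 2, 6, 5)))
  td <- tidy(fit)
  expect_equal(nrow(td), 1L)
  expect_named(td, c("estimate", "ci_low", "ci_high", "category"))
  gl <- glance(fit)
  expect_equal(gl$n, 6L)
  expect_equal(gl$estimate, fit$estimate)
})

test_that("compare_extractors: identical extractors give ICC 1; jitter stays excellent; a constant rater collapses", {
  recs <- lapply(1:6, function(s) {
    simulate_recording(tremor_sim_params(
      duration_s = 8, f0 = 3 + 0.8 * s, seed = 40 + s))
  })
  ext <- function(x, fs, role, band) extract_peak_direct(x, fs, role, band)
  same <- compare_extractors(recs, ext, ext)
  expect_setequal(same$label, c("ACC", "ECR", "FCR"))
  expect_true(all(same$estimate == 1))
  expect_equal(same$n_subjects, rep(12L, 3))  # 6 recordings x 2 limbs

  jittered <- function(x, fs, role, band) {
    f <- extract_peak_direct(x, fs, role, band)
    f + 0.03 * sin(1000 * f)   # deterministic sub-resolution perturbation
  }
  jit <- compare_extractors(recs, ext, jittered)
  expect_true(all(jit$estimate >= 0.9))

  const <- function(x, fs, role, band) 5.0
  flat <- compare_extractors(recs, ext, const)
  expect_true(all(flat$estimate < 0.5))
})
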