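# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: the DFT oracle is the O(N^2) defining sum,
# the filter oracle evaluates the designed transfer function as complex
# polynomials, and the ICC oracle works from raw sums of squares.

# O(N^2) discrete Fourier transform by the defining sum.
brute_dft <- function(x) {
  n <- length(x)
  idx <- 0:(n - 1)
  vapply(idx, function(k) sum(x * exp(-2i * pi * k * idx / n)),
         complex(1))
}

# One-sided power from the brute DFT, folded and Parseval-scaled.
brute_power <- function(x) {
  n <- length(x)
  X <- brute_dft(x - mean(x))
  nf <- n %/% 2 + 1
  p <- Mod(X[1:nf])^2 / n
  for (k in 2:nf) {
    if (!(n %% 2 == 0 && k == nf)) p[k] <- 2 * p[k]
  }
  p[1] <- 0
  p
}

# Net gain of a zero-phase (forward-backward) filter at frequency f:
# |H(e^{j 2 pi f / fs})|^2, H evaluated directly from the coefficients.
analytic_gain2 <- function(b, a, f, fs) {
  z <- exp(-2i * pi * f / fs)
  H <- sum(b * z^(seq_along(b) - 1)) / sum(a * z^(seq_along(a) - 1))
  Mod(H)^2
}

# Steady-state amplitude gain of a filtering function at frequency f,
# measured on the central half of a long probe sine.
empirical_gain <- function(filter_fun, f, fs, seconds = 20) {
  t <- seq(0, seconds, by = 1 / fs)
  x <- sin(2 * pi * f * t)
  y <- filter_fun(x)
  mid <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  sqrt(mean(y[mid]^2) / mean(x[mid]^2))
}

# ICC(A,1) with F-based CI, from raw sums of squares (machine formulas,
# no mean-centering) -- an arithmetic path independent of the package's.
brute_icc_a1 <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  corr <- sum(m)^2 / (n * k)
  ss_total <- sum(m^2) - corr
  ssr <- sum(rowSums(m)^2) / k - corr
  ssc <- sum(colSums(m)^2) / n - corr
  sse <- ss_total - ssr - ssc
  msr <- ssr / (n - 1); msc <- ssc / (k - 1); mse <- sse / ((n - 1) * (k - 1))
  est <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  a <- k * est / (n * (1 - est))
  b <- 1 + k * est * (n - 1) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) / (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (fu * msr - mse) / (k * msc + (k * n - k - n) * mse + n * fu * msr)
  list(estimate = est, ci_low = lower, ci_high = min(upper, 1),
       msr = msr, msc = msc, mse = mse)
}

# Consistency-form single-rater ICC (for the absolute-vs-consistency
# comparison property).
consistency_icc <- function(m) {
  o <- brute_icc_a1(m)
  (o$msr - o$mse) / (o$msr + (ncol(as.matrix(m)) - 1) * o$mse)
}

sine_at <- function(f, fs, seconds, amp = 1, phase = 0) {
  amp * sin(2 * pi * f * (0:(round(seconds * fs) - 1)) / fs + phase)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
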