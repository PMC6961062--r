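# Butterworth design in pole-zero form and zero-phase filtering through
# cascaded second-order sections (biquads). Narrow low-frequency bands put
# tightly clustered poles on the unit circle; expanding them into one
# high-order polynomial (direct form) squanders precision, while biquad
# cascades keep each factor well conditioned. Design follows the textbook
# route: analog Butterworth prototype -> frequency prewarp -> lowpass-to-
# bandpass (or lowpass) transform on poles/zeros -> bilinear transform ->
# conjugate-pair grouping into sections.

butter_proto_poles <- function(order) {
  k <- seq_len(order)
  exp(1i * pi * (2 * k + order - 1) / (2 * order))  # left-half-plane poles
}

# Digital Butterworth band-pass as {z, p, k}.
butter_zpk <- function(order, fs, low = NULL, high = NULL,
                       type = c("pass", "low")) {
  type <- match.arg(type)
  p <- butter_proto_poles(order)
  fs2 <- 2 * fs
  if (type == "pass") {
    wl <- fs2 * tan(pi * low / fs)
    wh <- fs2 * tan(pi * high / fs)
    bw <- wh - wl
    w0sq <- wl * wh
    pa <- unlist(lapply(p, function(pp) {
      half <- pp * bw / 2
      disc <- sqrt(half^2 - w0sq)
      c(half + disc, half - disc)
    }))
    za <- rep(0 + 0i, order)
    ka <- bw^order
  } else {
    wc <- fs2 * tan(pi * low / fs)
    pa <- wc * p
    za <- complex(0)
    ka <- wc^order
  }
  zd <- (fs2 + za) / (fs2 - za)
  pd <- (fs2 + pa) / (fs2 - pa)
  kd <- Re(ka * prod(fs2 - za) / prod(fs2 - pa))
  # analog zeros at infinity land at z = -1 under the bilinear transform
  zd <- c(zd, rep(-1 + 0i, length(pa) - length(za)))
  list(z = zd, p = pd, k = kd)
}

poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (rt in r) coef <- c(coef, 0) - c(0, coef * rt)
  Re(coef)
}

# Group {z, p, k} into second-order sections (rows: b0 b1 b2 a0 a1 a2).
# Poles are taken as conjugate pairs (upper-half-plane pole with its
# conjugate; real poles paired together); each section receives two zeros,
# mixing one z = +1 with one z = -1 where both kinds exist so no section is
# left with a double zero it cannot damp. The overall gain goes into the
# first section.
zpk2sos <- function(zpk) {
  p <- zpk$p
  up <- p[Im(p) > 1e-14]
  realp <- sort(Re(p[abs(Im(p)) <= 1e-14]))
  pairs <- c(lapply(up, function(pp) c(pp, Conj(pp))),
             if (length(realp)) split(realp, ceiling(seq_along(realp) / 2)))
  z <- zpk$z
  n_sec <- length(pairs)
  sos <- matrix(0, n_sec, 6L)
  zeros_plus <- sum(abs(z - 1) < 1e-9)
  zeros_minus <- sum(abs(z + 1) < 1e-9)
  for (s in seq_len(n_sec)) {
    zz <- complex(0)
    if (zeros_plus > 0) { zz <- c(zz, 1 + 0i); zeros_plus <- zeros_plus - 1 }
    if (zeros_minus > 0) { zz <- c(zz, -1 + 0i); zeros_minus <- zeros_minus - 1 }
    while (length(zz) < 2 && zeros_minus > 0) {
      zz <- c(zz, -1 + 0i); zeros_minus <- zeros_minus - 1
    }
    b <- poly_from_roots(zz)
    a <- poly_from_roots(pairs[[s]])
    b <- c(b, numeric(3 - length(b)))
    a <- c(a, numeric(3 - length(a)))
    sos[s, ] <- c(b, a)
  }
  sos[1, 1:3] <- sos[1, 1:3] * zpk$k
  sos
}

# One cascade pass with steady-state initial conditions per section,
# scaled through the accumulated DC gain (the input to section s starts,
# in steady state, at x[1] times the DC gain of the sections before it).
sos_filter_pass <- function(sos, x) {
  x0 <- x[[1L]]
  for (s in seq_len(nrow(sos))) {
    b <- sos[s, 1:3]; a <- sos[s, 4:6]
    zi <- lfilter_zi(b, a)
    x <- df2t_filter(b, a, x, zi * x0)
    x0 <- x0 * sum(b) / sum(a)
  }
  x
}

# Zero-phase (forward-backward) SOS filtering with odd-reflection padding.
sos_filtfilt_refl <- function(sos, x) {
  order_equiv <- 2L * nrow(sos) + 1L
  pad <- 3L * order_equiv
  n <- length(x)
  if (n <= pad) {
    abort(sprintf("Signal too short to filter: %d samples, need more than %d.",
                  n, pad),
          class = "tremorkit_insufficient_data")
  }
  ext <- c(2 * x[[1L]] - x[(pad + 1L):2L], x, 2 * x[[n]] - x[(n - 1L):(n - pad)])
  y <- sos_filter_pass(sos, ext)
  y <- rev(sos_filter_pass(sos, rev(y)))
  y[(pad + 1L):(pad + n)]
}
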