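Package: tremorkit
Title: Tremor Electrophysiology Analysis from Accelerometry and Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scriptable analysis of multi-channel tremor recordings
    (wrist accelerometry plus surface EMG of antagonist forearm muscles).
    Reads plain-text recordings at any sampling rate, applies role-specific
    third-order Butterworth band-limiting with EMG rectification and
    smoothing, computes full-segment FFT power spectra and tremor-band peak
    frequencies, segmented split-cosine-tapered magnitude-squared coherence
    with Halliday 95% confidence limits and per-frequency confidence
    intervals, and short-time Fourier spectrograms.  Includes a seedable
    generator of physiologically structured synthetic tremor recordings and
    an agreement-validation harness based on the two-way absolute-agreement
    single-rater intraclass correlation coefficient with Koo-Li reliability
    categories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    signal,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
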