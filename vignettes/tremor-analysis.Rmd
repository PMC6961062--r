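---
title: "Methods: tremor spectra, EMG–ACC coherence and agreement validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tremor spectra, EMG–ACC coherence and agreement validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorkit)
```

## The measurement problem

Organic tremor is an involuntary rhythmic oscillation in the 3–18 Hz band —
cerebellar tremor at the slow end, orthostatic tremor at the fast end, with
parkinsonian rest tremor (~3–6 Hz) and essential tremor (~4–8 Hz) in
between. The standard electrophysiological study records, per upper limb, a
wrist accelerometer (ACC) and surface EMG over the antagonist forearm
muscles (extensor and flexor carpi radialis; ECR, FCR), usually 30 s at
1000 Hz. Three quantities carry most of the diagnostic information:

1. the **peak frequency** of each channel's power spectrum within 3–18 Hz;
2. the **EMG–ACC coherence** at that frequency — frequency-specific linear
   coupling distinguishes centrally driven tremor (muscle bursts phase-locked
   to limb oscillation) from a purely mechanical resonance;
3. the **time course** of the rhythm (spectrogram), e.g. frequency drift or
   intermittency.

`tremorkit` implements this chain plus the agreement machinery used to
validate one implementation of it against another.

## Preprocessing

Each channel is filtered by role with third-order Butterworth filters:

| role | band | rationale |
|------|------|-----------|
| ACC  | 2–30 Hz | brackets every organic tremor; the 2 Hz high-pass removes gravity/posture drift |
| EMG  | 20–300 Hz | retains the bulk of surface-EMG power while rejecting movement artefact below 20 Hz |

EMG is then full-wave rectified and smoothed. Rectification is the crucial
nonlinearity: interference-pattern EMG carries tremor information as
*amplitude modulation* of high-frequency activity, and |·| shifts the
burst-repetition rate into the low-frequency band where it can be read as a
spectral peak. The smoothing operator is a third-order low-pass Butterworth
at 30 Hz — the literature this chain follows recommends smoothing without
fixing a cutoff, so we chose the upper edge of the tremor analysis band
(also the ACC low-pass edge), which keeps every envelope component that
could be tremor and discards rectification ripple. The cutoff is a config
knob (`smooth_cutoff`).

**Zero-phase application.** All filters run forward–backward, so the net
response is |H(f)|² with no phase distortion (−6 dB rather than −3 dB at the
nominal cutoffs). We chose zero-phase because coherence between EMG and ACC
depends on their temporal alignment; a causal filter bank with different
group delays per band would bias the cross-spectrum. Whether a single-pass
or two-pass convention is used elsewhere is rarely documented; the
magnitude-squared coherence itself is insensitive to any *common* phase
response, so this choice mainly affects peak amplitudes, not locations.

**Numerics.** Filters are designed in pole–zero form (analog Butterworth
prototype, frequency prewarping, lowpass-to-bandpass transform, bilinear
transform) and applied as cascaded second-order sections. This matters: the
order-6 2–30 Hz band-pass at fs = 1000 Hz has poles clustered near the unit
circle, and expanding them into a single direct-form polynomial loses about
eight significant digits (linearity of the filter, an exact property, held
only to ~10⁻⁸ in direct form; it holds to ~10⁻¹⁴ in sections). Edge
transients are suppressed by odd-reflection padding (3 × the equivalent
coefficient count) with steady-state initial conditions per section; inputs
not longer than the pad are rejected rather than filtered badly. Band edges
at or above the Nyquist frequency are hard errors — silently clamping a
clinical band would corrupt interpretation.

## Spectra and peak extraction

The full-segment spectrum is a single FFT of the demeaned signal — no
windowing, no averaging — maximising frequency resolution (fs/N, i.e.
1/30 Hz for a 30 s record), which is what one wants for reading off a peak
frequency. Demeaning is essential for rectified EMG, whose mean otherwise
dominates every display and search; the DC bin is reported as exactly 0.
Power is one-sided and Parseval-normalised (bin sum = sum of squared
deviations), a convention fixed so that amplitude-squared ratios of tones
are exact and tests can assert against an independent O(N²) Fourier oracle.

`peak_frequency()` returns the argmax bin within the search band
(default 3–18 Hz). Exact power ties break toward the lower frequency, for
reproducibility. A band whose bins are all zero yields a typed "no peak"
result (`NA`), distinct from an error; a band containing no bins at all is
an error.

## Magnitude-squared coherence

Both channels are segmented into L = ⌊N/W⌋ non-overlapping windows
(trailing remainder dropped), each window demeaned and tapered with a
split-cosine bell (raised-cosine ramps over the first and last ⌈pW⌉
samples, p = 0.1 per end by default; p = 0.5 degenerates to a full
Hann-type bell). Cross- and auto-spectra are averaged across windows
*before* the ratio:

$$C(f) = \frac{\left|\sum_l X_l(f)\overline{Y_l(f)}\right|^2}
{\sum_l |X_l(f)|^2 \sum_l |Y_l(f)|^2}.$$

Averaging per-window coherence instead would give identically 1 at every
frequency (each single-window ratio is 1), which is why the estimator must
average spectra first. Segments are non-overlapping because the null
distribution used next assumes independent segments. No taper power
renormalisation is applied — the window's scale cancels in the ratio.

**Null limit.** For independent Gaussian channels, the estimator at each
frequency satisfies P(C > c) = (1 − c)^{L−1}, so coherence exceeds

$$c_{1-\alpha} = 1 - \alpha^{1/(L-1)}$$

with probability α. This is the dashed "95% confidence limit" of
conventional coherence displays; with L = 2 it is 0.95 and it decreases
strictly toward 0 as L grows. Our Monte-Carlo calibration (50 independent
noise pairs, 60 s at 1000 Hz, W = 1024, so L = 58 and 512 bins) reproduces
the nominal 5% exceedance within ±2 percentage points.

**Per-frequency intervals.** The coherency magnitude √C is
variance-stabilised by atanh with approximate variance 1/(2L); a normal
interval of half-width z₀.₉₇₅/√(2L) on that scale is back-transformed and
squared. The lower bound is floored at 0 *on the transformed scale* (the
coherency magnitude cannot be negative), which guarantees
0 ≤ low ≤ C ≤ high ≤ 1; naively squaring tanh(g − h) would place the lower
bound above a near-zero estimate. The cited framework for these limits
admits more than one interval construction; this transform is our reading
and is documented as such.

Coherence in the full pipeline is computed between **preprocessed**
channels. This is not cosmetic: raw burst-modulated EMG has no *linear*
component at the tremor frequency (its expectation is zero), so coherence
between raw EMG and ACC is null by construction; rectification is what
demodulates the burst train into an envelope that can cohere with the
accelerometer.

## Spectrogram

Sliding windows of W = `pow2_window(fs)` samples — the power of two nearest
to one second of samples, ties to the larger power (1024 at 1000 Hz; the
"nearest vs next" reading is ambiguous in common usage and both agree at
1000 Hz; `window_samples` overrides it for exact parity with any other
tool) — advance by W/2 (50% overlap). Each frame is demeaned,
Hann-windowed, and transformed with the same one-sided scaling as the
full-segment spectrum. Frame count is exactly ⌊(N − W)/(W/2)⌋ + 1; a
partial trailing frame is dropped, consistent with the coherence module's
remainder policy. Timestamps are window-centre seconds, so a frequency step
in the signal moves the per-frame peak within one hop of the true change
point.

## Agreement validation: ICC(A,1)

To validate one peak-frequency extractor against another, peak frequencies
from both methods on the same subjects form an n × 2 ratings matrix, and
agreement is summarised by the two-way random-effects, single-rater,
**absolute-agreement** intraclass correlation:

$$ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with MS_R, MS_C, MS_E the subject, rater and residual mean squares of the
two-way ANOVA. Absolute agreement (not consistency) is the right form here:
a method that reads every tremor 0.5 Hz high would correlate perfectly but
agree poorly. The 95% CI is the standard F-distribution construction for
this form (Satterthwaite denominator degrees of freedom). Reliability
categories follow the published thresholds on the CI lower bound — poor
< 0.5 ≤ moderate < 0.75 ≤ good < 0.9 ≤ excellent — with intervals closed on
the left (0.9 itself is "excellent"; the prose convention leaves the
boundary ambiguous, so we fixed it and documented it). A flag allows
categorising on the point estimate instead. Negative estimates are reported
as computed, category "poor". An all-identical matrix has zero
between-subject variance and the ICC is undefined — a typed error, not a
number.

`validate_agreement()` runs the in-silico analog of a software-vs-software
validation study: 20 simulated recordings (10 "postural" with f0 ~ U(4, 8)
Hz, 10 "rest" with f0 ~ U(3, 6) Hz, mirroring the essential-tremor and
parkinsonian ranges), peak frequencies per channel from the full pipeline
and from a deliberately minimal direct-FFT extractor (demean, rectify if
EMG, FFT, in-band argmax — no Butterworth stages), pooled over limbs into
one ratings matrix per channel label (ACC, ECR, FCR). Both extractors land
within about one frequency bin of the true f0, while f0 varies by several
Hz across subjects, so the ICCs come out ≈ 1 — the structural analog of an
"excellent agreement" validation, not a reproduction of any particular
cohort's numbers.

## The synthetic tremor generator

`simulate_recording()` produces the six-channel montage from a small
generative model, all randomness flowing from one seed through a
deterministic substream per noise source:

- **Central oscillator.** Unit drive sin φ(t) with instantaneous frequency
  f0 plus a *mean-reverting* Gaussian random walk (AR(1), per-sample
  innovation SD 0.002 Hz, 1 s reversion time constant, clipped to
  f0 ± 0.5 Hz), giving the slow ±0.05 Hz wander seen in organic tremor. A
  non-reverting walk at the same innovation scale would drift ~0.35 Hz in
  30 s and saturate at the clip, smearing the spectral peak far beyond what
  real tremor does — with mean reversion the recovered peak stays within
  one FFT bin of f0, which is the regime the validation analog assumes.
- **ACC channel.** acc_amp · (coupling · d + (1 − coupling) · d′) plus
  noise band-shaped to 2–30 Hz (SD 0.3 by default). The noise is shaped
  *into* the analysis band deliberately, so preprocessing cannot trivially
  remove it and tests stay honest. d′ is an independent second oscillator,
  enabling two-oscillator negative controls at coupling < 1.
- **EMG channels.** Broadband Gaussian noise (SD 1) amplitude-modulated by
  1 + m · max(0, sin(φ + shift)), m = 0.7 by default: *half-wave* gating,
  one burst per tremor cycle per muscle, with the flexor shifted by π so
  antagonists alternate — the textbook burst pattern. Half-wave (not
  full-wave) gating is a deliberate modelling choice: |sin| has its
  fundamental at 2·f0 and identical phase for both antagonists, which would
  put the rectified-EMG envelope peak at twice the tremor frequency and
  erase the alternating pattern.

Default sizes are the standard protocol: 30 s at 1000 Hz, f0 = 5 Hz.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: mechanical-reflex components and their
loading behaviour, re-emergent rest tremor latency, amplitude
nonstationarity and intermittency, ECG and movement artefacts, electrode
noise spectra, mains interference, and harmonics of non-sinusoidal limb
motion. Results on patient recordings additionally depend on acquisition
details (gain, saturation, montage errors) that no simulation covers.

## Sizes, tolerances and degenerate inputs

The test suite and the acceptance script size their simulations to what the
statistics need rather than more: 50 replicates × 512 bins for the null
calibration of the coherence limit (Monte-Carlo SE ≈ 0.001 on an expected
rate of 0.05), 20 seeds for peak recovery, 20 recordings (40 limb-subjects)
for the agreement analog, 8–10 seeds for dose–response and negative-control
properties. Exact identities (Parseval, the O(N²) Fourier oracle, ICC vs a
raw sums-of-squares ANOVA oracle, linearity of filtering) are asserted at
1e-9–1e-10; empirical filter gains match the analytic |H(f)|² response
within 5% where the response exceeds 10⁻³.

Degenerate inputs are typed conditions, not silent results: non-numeric or
missing samples (never imputed — the spectral estimators assume contiguous
sampling), Nyquist violations, windows longer than the signal, fewer than
two coherence segments (the estimator is identically 1 at L = 1), zero
between-subject variance in the ICC. A constant signal has a valid all-zero
spectrum, and an all-zero band yields the distinct no-peak result.

## Known limitations

- The coherence CI construction is one defensible reading of the cited
  framework; others exist (e.g. intervals on the coherency rather than its
  square).
- The EMG smoothing cutoff (30 Hz) is a documented stand-in for an
  under-specified recommendation; results for peak *frequency* are
  insensitive to it, peak *power* is not.
- ICC p-values are not reported (the CI carries the inferential content
  here); only the single-rater absolute-agreement form is implemented.
- No notch filtering, artefact rejection or resampling: recordings are
  assumed clean and uniformly sampled.
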