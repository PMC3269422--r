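---
title: "Decoding speech from auditory cortical responses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding speech from auditory cortical responses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cortical surface recordings over the superior temporal gyrus carry enough
information about heard speech that the stimulus can be partially
reconstructed from population activity. This package implements that
analysis end to end: auditory stimulus representations, neural band-power
preprocessing, linear reconstruction (decoding) and STRF encoding models
with early-stopping regularization under Monte Carlo cross-validation,
accuracy resolved by acoustic frequency and temporal modulation rate, and
word identification from reconstructed spectrograms. Because no patient
recordings are distributable, a synthetic-data module generates ground-truth
populations with the statistical structure the analysis assumes, so every
stage is testable at desk scale.

## Stimulus representations

**Auditory spectrogram.** A bank of 128 constant-Q bandpass filters
(Gaussian on the log-frequency axis, FWHM 1/12 octave) with log-spaced
centers over 180-7,000 Hz mimics peripheral frequency analysis. Per-channel
Hilbert envelopes are cube-root compressed and averaged into 10 ms frames
(100 Hz). For modeling, the 128 channels are reduced to 32 by non-overlapping
4-channel arithmetic means (geometric-mean center frequencies), the simplest
energy-preserving reduction. The floor is 0; no dB conversion is applied in
the analysis path. The exact compression and integration constants of the
peripheral model this emulates are not uniquely determined; cube-root
compression and rectangular 10 ms integration are this package's documented
choices, not a claim of equivalence to any particular implementation.

**Modulation energy.** The spectrogram is analyzed by a bank of causal
spectro-temporal filters spanning scales 0.5-8 cyc/oct and rates 1-32 Hz.
Temporal kernels are gamma-windowed complex sinusoids,
$h_r(t) \propto (rt)^2 e^{-3.5rt} e^{i2\pi rt}$; spectral profiles are
Gaussian-derivative magnitude transfers $(\Omega/s)^2 e^{1-(\Omega/s)^2}$,
one-sided so that each signed rate selects one spectro-temporal quadrant
(negative rates = upward sweeps, positive = downward). Filtering is done in
the 2-D Fourier domain with zero padding (2x in frequency, +2 s in time).
Two implementation details matter numerically:

* the filters are exactly zero-DC, and each frequency channel is centered
  over the signal support before filtering — otherwise the static envelope
  level leaks through the low-frequency skirts and spoils the phase
  invariance of the magnitude output;
* the full form keeps one complex image per (scale, rate) pair and takes
  magnitudes per frequency and frame (5 x 12 x 32 = 1,920 channels at
  defaults); the rate-scale form averages the complex outputs over frequency
  *before* the magnitude (60 channels); the rate-only form applies the
  (non-directional) analytic temporal filters to the frequency-averaged
  envelope, giving 6 unsigned-rate channels. Quadrature magnitude is assumed
  for the rate-only filters.

**Inversions.** Both inversions are iterative-projection (Griffin-Lim style)
phase retrievals. Spectrogram-to-waveform alternates envelope substitution
on the analytic subbands with least-squares resynthesis through the
filterbank. Modulation-to-spectrogram iterates on the mean-centered image
(channel magnitudes are blind to per-channel means), substitutes magnitudes
only over the signal support (causal filter tails ring into the padding,
which must stay unconstrained), resynthesizes with the Hermitian-symmetrized
least-squares inverse, resolves the global sign by the positive skewness of
envelope fluctuations, averages a configurable number of random
initializations (100 by default), and restores per-channel floors at 0.
Magnitude-only recovery is fundamentally limited here: images reproducing
all 1,920 channel magnitudes to well under 1% can correlate weakly with the
source, because relative phase across bands is what encodes fine structure,
and for strictly periodic inputs modulation timing is unidentifiable in
principle. Round trips on smooth spectrograms reach r of roughly 0.4-0.6;
harmonically fine-structured inputs do worse. The package therefore treats
this inversion as a visualization aid, and quantitative model comparisons
are made in the modulation space itself.

## Neural preprocessing

Raw multichannel recordings are re-montaged to a common average reference
over good channels (bad channels are input metadata, passed through).
Band power uses a zero-phase FIR bandpass (Blackman window, ~74 dB stopband;
order set from a transition width of min(10 Hz, band low edge / 2) and
recorded on the output), the squared analytic envelope, frame averaging to
100 Hz, and per-electrode z-scoring over the whole session. Squared
envelope ("power") is the default, with amplitude as a configuration
switch; the standardization window is the session, not the trial. The
default high-gamma band is 70-150 Hz (configurable, since analyses of
band-specific accuracy use a ~70-170 Hz description of the same band). The
30-band analysis splits 1-300 Hz into 30 contiguous ~10 Hz bands; the
printed range is not an exact multiple of the width, so band edges are
`seq(lo, hi, length.out = 31)` and a width that is genuinely incompatible
with the range is rejected.

## Decoding and encoding models

The reconstruction model maps the lagged population response linearly onto
each stimulus channel,
$\hat S_f(t) = \sum_n \sum_{\tau=0}^{99} g_f(\tau, n)\, R(t+\tau, n)$,
with 100 lags at 10 ms; each channel's filter (N electrodes x 100 lags) is
estimated independently. The lag sign convention — the decoder reads the
response at and after the stimulus frame — is a documented choice. Within a
trial, lag windows that cross the trial end are zero-padded (the mean, in
standardized units) and flagged.

Fitting is greedy coordinate descent: at each iteration the coordinate with
the largest gradient magnitude takes a fixed step of $10^{-3}$ SD-ratio
units, validation MSE is monitored, and fitting stops after 50 consecutive
non-improving iterations, returning the best-validation iterate. This
yields sparse filters (most weights exactly zero on short fits) and
performs variable selection implicitly. Run to convergence (patience
disabled) it matches ridge regression with a small penalty to prediction
r > 0.99 on small problems, which the tests verify. STRF encoding models
use the same scaffolding with full-gradient descent (dense solutions), the
step size set from the leading curvature eigenvalue.

Cross-validation is repeated random subsampling over whole trials
(80/10/10), never frames, so no word contributes to both training and test.
Weights and accuracies are averaged over resamples; per-weight SE is the SD
of resampled estimates (n-1 denominator) and significance is screened by
the t-ratio. Paired model comparisons reuse byte-identical partitions.
Informative electrodes require |t| > 2.5 surviving Benjamini-Hochberg FDR
at 0.05, two-sided p from a t distribution with resamples-1 df. Accuracy is
Pearson r per stimulus channel, averaged through Fisher's z; zero-variance
test channels are excluded with a logged count. Rate-resolved accuracy
projects spectrogram-space reconstructions through the modulation
filterbank into the 60-channel rate-scale space, correlates per channel,
and Fisher-averages over scale and over signed-rate pairs.

Tuning curves zero inhibitory weights and sum over lags; SEs are propagated
by recomputing the transform per resample and taking the SD across
resamples (exact, no delta-method approximation). Peaks require t > 2.0 and
half-octave separation (log2 of the axis ratio for both frequency and rate
axes); merged peaks keep the larger amplitude, exact ties the lower
position. Linear rate tuning by filterbank projection integrates total
(Parseval) channel energy — causal low-rate filters ring past the short
STRF support — and the 2-D Fourier (MTF) estimator marginalizes onto the
same log-spaced rate grid by integrating half an octave each side, which is
what makes the two estimators agree (r > 0.9 on smooth random STRFs).

## Word identification

Reconstructions and candidates are smoothed with a 2-D box filter (500 ms,
2 octaves; edge-truncated). Dynamic time warping with local cost
1 - r between frequency columns, symmetric steps, and no band constraint
aligns each pair; similarity is the Pearson correlation of the aligned,
vectorized spectrograms. The identification rank is the fraction of
incorrect candidates scoring strictly below the correct word, ties counting
one half (unbiased under ties); chance mean is 0.5. Significance uses a
10,000-shuffle null of the median rank; the plug-in p (proportion of null
medians at or above the true median) can be exactly 0, so the conservative
(k+1)/(n+1) variant is attached to randomization outputs as metadata. The
ROC sweeps a rank threshold, with chance false-positive rate 1 - threshold.
Pairwise similarity matrices are computed before smoothing, and their
correlation is taken over distinct word pairs. Full-sequence alignment is
assumed (no subsequence matching); words are at most ~1 s, so no global
band constraint is needed.

## The synthetic populations

Units come in two kinds, mirroring the dual coding scheme for temporal
fluctuations. *Envelope-locked* units respond linearly to the 32-channel
spectrogram: 1-5 Gaussian frequency peaks (most units 2-5) placed uniformly
on the log-frequency axis, convolved with a causal second-order lowpass lag
kernel with an 8 Hz corner, emulating the loss of envelope-locking above
~8 Hz; the steep (12 dB/oct) rolloff is what pushes fast-rate envelope
information under the trial noise. *Modulation-energy* units respond
linearly to the 60-channel rate-scale modulation energy, with a Gaussian
rate profile (log2 axis, peak log-uniform over 1-32 Hz) — hence nonlinearly
and phase-invariantly to the spectrogram. Trial noise is white Gaussian in
z-units (AR(1) available); responses are z-scored. Each trial carries a
250 ms post-stimulus silence margin, as in a continuous recording, so that
late-lag response energy is observed rather than truncated.

Stimuli: AM tones, AM broadband noise (which excites every frequency
channel at a controlled rate — without it, test splits dominated by tones
leave most spectrogram channels silent and undecodable), exponential
sweeps, and formant words (2-3 noise-excited formant resonances under a
syllabic envelope at <= 4 Hz with ~15 ms onsets, 0.3-1 s). The benchmark
batteries are: fixture (a) 16 mixed units over 47 words at noise 0.3;
fixtures (b)/(c) 12 envelope-locked / modulation-energy units over a
24-trial battery (6 AM tones, 6 AM noises at 1-32 Hz, 4 sweeps, 8 words;
1.5 s trials) at noise 0.2. Fixture noise levels are chosen once for test
discriminability, not biological realism; realistic per-trial high-gamma
SNR is not quantified in the source literature.

What the synthetic data does *not* emulate: correlated noise across
electrodes, non-Gaussian and nonstationary artifacts, imperfect trial
alignment, spatial leakage between neighboring contacts, and any nonlinear
response component beyond the modulation-energy transform. Passing tests
therefore show that the estimators recover the structure they assume, at
the assumed noise levels — not that real cortical data satisfies those
assumptions.

## Problem sizes and numerical choices

The test and analysis runs use reduced problem sizes chosen to keep the
full suite in the minutes range on one CPU: 20 decoding lags instead of
100 (the 100-lag default is asserted structurally), 2-3 Monte Carlo
resamples for decoders and 8-20 for STRFs, 24-47 trials, and a few hundred
Monte Carlo draws for calibration checks (1,000 in the acceptance script).
Iterative-projection inversions run 2-6 initializations in tests against
the 100-initialization default. Convergence defaults: coordinate descent
patience 50 and step 1e-3 (per the estimation scheme), projection
iterations capped at 200 with a 1e-4 successive-correlation tolerance.
Degenerate inputs: zero-variance channels are excluded from accuracy
averages; all-zero magnitude inversions return the floor spectrogram;
zero-SE weights have undefined (flagged) t-ratios; p values of exactly 0
are reported under the plug-in rule with the conservative variant attached.
All randomness flows from explicit seeds through a single seed-derivation
helper, and generators are pure functions of (configuration, seed).

## Known limitations

Magnitude-only modulation inversion is approximate by nature (see above).
The chance-level and calibration checks are Monte Carlo and hold to their
stated tolerances, not exactly. The coordinate-descent step size trades
accuracy against iteration count; pathological conditioning (strongly
correlated electrodes at 100 lags) may need more iterations than the
default cap. The full 1,920-channel modulation decoder and the
192,000-parameter modulation STRF are supported surfaces but are not
exercised at full scale in the tests, in line with the reduced-dimension
rationale that motivates the rate-scale and rate-only forms.
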