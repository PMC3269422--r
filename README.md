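# speechdecode

Reconstructing speech from population recordings of human auditory cortex,
as a tested R pipeline. Cortical surface field potentials over the superior
temporal gyrus track heard speech closely enough that the stimulus can be
partially reconstructed from multichannel high-gamma (70–150 Hz) band
power. This package implements that analysis for computational
neuroscientists who want to run, probe, or extend it without access to
patient data: audio-to-representation frontends, neural preprocessing,
decoding and encoding model fits, accuracy analyses, word identification,
and a synthetic ground-truth generator that stands in for ECoG recordings.

## The models

**Stimulus representations.** The auditory spectrogram `S(f, t)` is a
128-channel constant-Q (~1/12 octave) log-frequency envelope representation
over 180–7,000 Hz, framed at 100 Hz and downsampled to 32 channels for
modeling. The modulation representation `M(s, r, f, t)` is the magnitude of
a bank of causal 2-D spectro-temporal filters applied to the spectrogram,
over spectral scales s ∈ {0.5, 1, 2, 4, 8} cyc/oct and signed temporal
rates r ∈ ±{1, 2, 4, 8, 16, 32} Hz (negative = upward sweeps): 1,920
channels in full, 60 in the reduced rate–scale form, 6 rate-only.

**Decoding (stimulus reconstruction).** A multi-input, multi-output linear
map from lagged neural responses to each stimulus channel,

    Ŝ_f(t) = Σ_n Σ_τ g_f(τ, n) R(t + τ, n),   τ = 0 … 99 lags at 10 ms,

fit per channel by greedy coordinate descent with early-stopping
regularization (patience 50 on a validation set), which yields sparse
filters and implicit electrode selection. Monte Carlo cross-validation
(random 80/10/10 trial splits) supplies resampled weight statistics
(SE = SD over resamples, t-ratios, BH-FDR electrode screening) and
accuracy as per-channel Pearson r, Fisher-z averaged. Accuracy is also
resolved by temporal modulation rate by projecting reconstructions through
the modulation filterbank.

**Encoding (STRFs).** Per-electrode linear maps `r(t) = Σ_{x,u} h(x, u)
s(x, t − u) + e(t)` fit by dense gradient descent with early stopping
(3,200 parameters in spectrogram space, 600 rate-only, 192,000 full).
Frequency and rate tuning curves come from the excitatory weights; peaks
require t > 2.0 and half-octave separation.

**Word identification.** Reconstructed spectrograms are smoothed (2-D box,
500 ms × 2 octaves), aligned to each candidate word by dynamic time
warping, and scored by aligned correlation; the percentile rank of the
correct word (chance 0.5) is tested against a 10,000-shuffle null of the
median.

## Worked example

Simulate a modulation-energy population (the nonlinear coding scheme),
decode it in both stimulus spaces with identical data partitions, and
compare accuracy by modulation rate:

```r
library(speechdecode)

ds <- make_benchmark("c", seed = 7)       # 12 energy-coding units, 24 trials
plan  <- list(n_resamples = 3, seed = 11)
hyper <- fit_config(n_lags = 20, max_iter = 6000)

cv_rs <- run_monte_carlo_cv(ds$stim_rate_scale,  ds$resp, plan, hyper)
cv_sp <- run_monte_carlo_cv(ds$stim_spectrogram, ds$resp, plan, hyper,
                            partitions = cv_rs$partitions)
cv_rs$report$mean_r
#> [1] 0.8585768
cv_sp$report$mean_r
#> [1] 0.2493380
```

Rate-resolved accuracy (`analysis/03_decode.R` prints the full table)
shows the dual-coding signature: on this population the rate–scale space
wins decisively at fast rates — r = 0.83 vs 0.58 at 8 Hz, 0.98 vs 0.29 at
16 Hz, 0.90 vs 0.46 at 32 Hz — while both routes succeed at 1–2 Hz
(all ≥ 0.68). On the envelope-locked population (fixture "b") the linear
spectrogram model is sufficient at slow rates, declining from r ≈ 0.93 at
1–4 Hz to ≈ 0.57–0.74 at 16–32 Hz under the 8 Hz envelope-locking corner.

End-to-end identification on the 47-word fixture:

```r
dsa <- make_benchmark("a", seed = 7)
cv  <- run_monte_carlo_cv(dsa$stim_spectrogram, dsa$resp, plan, hyper)
pr  <- predict_stimulus(cv$model, dsa$resp)
recons <- lapply(dsa$trial_table$trial_id, function(tr)
  auditory_spectrogram(pmax(t(pr[dsa$resp$trial_index == tr, ]), 0),
                       dsa$spectrograms[[1]]$freq_hz, 100))
res <- identification_suite(recons, dsa$trial_table$label,
                            word_set(dsa$labels, dsa$spectrograms),
                            n_shuffles = 10000, seed = 3)
res
#> <identification_result> median rank 1.000 (p = 0, 47 words)
res$similarity_correlation
#> [1] 0.8117537
```

A median rank of 1.0 means at least half the reconstructions matched their
own word best of all 47 candidates (the mean rank here is 0.956); the
shuffle null puts the p value below the 1/10,000 resolution of the test,
reported as 0 under the plug-in rule with the conservative (k+1)/(n+1)
variant attached. The similarity correlation says that word pairs that
sound alike are also confusable in reconstruction.

The numbered scripts under `analysis/` run the full narrative —
representations, population simulation, decoding, STRF tuning, word
identification — and write their tables under `results/`.

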