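#' Synthetic coding unit
#'
#' Ground-truth unit for simulated populations. `envelope_locked` units
#' respond linearly to the spectrogram envelope (synchronized coding, with a
#' corner-rate lowpass emulating the loss of envelope-locking at fast
#' rates); `modulation_energy` units respond linearly to modulation energy
#' (phase-invariant amplitude coding), hence nonlinearly to the spectrogram.
#'
#' @param kind `"envelope_locked"` or `"modulation_energy"`.
#' @param freq_peaks_hz tuned frequencies (1-5 peaks) for envelope units.
#' @param corner_or_peak_rate_hz lowpass corner (envelope units) or peak
#'   rate (energy units), Hz.
#' @param noise_sd trial noise SD in units of the noiseless response SD.
#' @param gain response gain.
#' @return object of class `synthetic_unit`.
#' @export
synthetic_unit <- function(kind = c("envelope_locked", "modulation_energy"),
                           freq_peaks_hz = 1000, corner_or_peak_rate_hz = 8,
                           noise_sd = 0.3, gain = 1) {
  kind <- match.arg(kind)
  if (noise_sd < 0) stop_invalid_input("noise_sd must be >= 0")
  structure(list(kind = kind, freq_peaks_hz = freq_peaks_hz,
                 corner_or_peak_rate_hz = corner_or_peak_rate_hz,
                 noise_sd = noise_sd, gain = gain),
            class = "synthetic_unit")
}

#' Sample a population of synthetic units
#'
#' Frequency tuning has 1-5 peaks (most units 2-5, matching complex tuning
#' profiles of auditory cortical sites), peak positions uniform on the
#' log-frequency axis. Envelope-locked units default to an 8 Hz corner rate;
#' modulation-energy units get peak rates spread over the log-rate axis.
#'
#' @param n number of units.
#' @param kind unit type, recycled.
#' @param noise_sd trial noise level.
#' @param seed integer seed.
#' @param fmin,fmax frequency range (Hz).
#' @return list of [synthetic_unit]s.
#' @export
make_units <- function(n, kind = "envelope_locked", noise_sd = 0.3, seed = 1,
                       fmin = 180, fmax = 7000) {
  kind <- rep(kind, length.out = n)
  with_seed(derive_seed(seed, "units"), {
    lapply(seq_len(n), function(i) {
      n_peaks <- sample(1:5, 1, prob = c(0.15, 0.25, 0.25, 0.2, 0.15))
      peaks <- exp(runif(n_peaks, log(fmin), log(fmax)))
      rate <- if (kind[i] == "envelope_locked") 8
              else 2^runif(1, 0, 5)        # 1-32 Hz, log-uniform
      synthetic_unit(kind[i], peaks, rate, noise_sd,
                     gain = runif(1, 0.5, 1.5))
    })
  })
}

#' Generate synthetic stimulus waveforms
#'
#' Four families: `am_tone` (sinusoidally amplitude-modulated pure tone),
#' `am_noise` (amplitude-modulated broadband noise, exciting every frequency
#' channel at a controlled rate), `sweep` (exponential frequency glide), and
#' `formant_word` (2-3 formant resonances excited by noise, shaped by a
#' syllabic envelope at <= 4 Hz with fast onsets, 0.3-1 s duration,
#' word-like).
#'
#' @param kind stimulus family.
#' @param n number of stimuli.
#' @param seed integer seed.
#' @param sample_rate_hz sample rate (16 kHz).
#' @param params list of family parameters; per-stimulus vectors allowed.
#'   am_tone: `f0_hz`, `rate_hz`, `depth`, `dur_s`. sweep: `f_start_hz`,
#'   `f_end_hz`, `dur_s`. formant_word: `dur_range_s`, `n_formants`.
#' @return list of [waveform]s with `labels` attribute.
#' @export
generate_stimuli <- function(kind = c("am_tone", "am_noise", "sweep",
                                      "formant_word"),
                             n = 1, seed = 1, sample_rate_hz = 16000,
                             params = list()) {
  kind <- match.arg(kind)
  sr <- sample_rate_hz
  out <- with_seed(derive_seed(seed, paste0("stim_", kind)), {
    lapply(seq_len(n), function(i) {
      pick <- function(name, default) {
        v <- params[[name]] %||% default
        v[((i - 1) %% length(v)) + 1]
      }
      if (kind == "am_tone") {
        f0 <- pick("f0_hz", 1000); rate <- pick("rate_hz", 4)
        depth <- pick("depth", 0.9); dur <- pick("dur_s", 1)
        if (f0 <= 0 || f0 >= sr / 2 || rate <= 0 || depth < 0 || depth > 1)
          stop_invalid_config("invalid am_tone parameters")
        t <- seq(0, dur - 1 / sr, by = 1 / sr)
        x <- sin(2 * pi * f0 * t) * (1 + depth * sin(2 * pi * rate * t)) /
          (1 + depth)
        w <- waveform(x, sr)
        attr(w, "label") <- sprintf("am_%gHz_r%g_%d", f0, rate, i)
        w
      } else if (kind == "am_noise") {
        rate <- pick("rate_hz", 4); depth <- pick("depth", 0.9)
        dur <- pick("dur_s", 1)
        if (rate <= 0 || depth < 0 || depth > 1)
          stop_invalid_config("invalid am_noise parameters")
        t <- seq(0, dur - 1 / sr, by = 1 / sr)
        x <- rnorm(length(t)) * (1 + depth * sin(2 * pi * rate * t)) /
          (1 + depth)
        w <- waveform(x / max(abs(x)), sr)
        attr(w, "label") <- sprintf("amnoise_r%g_%d", rate, i)
        w
      } else if (kind == "sweep") {
        f1 <- pick("f_start_hz", 300); f2 <- pick("f_end_hz", 3000)
        dur <- pick("dur_s", 1)
        if (min(f1, f2) <= 0 || max(f1, f2) >= sr / 2)
          stop_invalid_config("invalid sweep parameters")
        t <- seq(0, dur - 1 / sr, by = 1 / sr)
        k <- log(f2 / f1) / dur
        phase <- 2 * pi * f1 * (exp(k * t) - 1) / k
        w <- waveform(sin(phase), sr)
        attr(w, "label") <- sprintf("sweep_%g_%g_%d", f1, f2, i)
        w
      } else {
        dr <- params$dur_range_s %||% c(0.3, 1)
        dur <- runif(1, dr[1], dr[2])
        nt <- round(dur * sr)
        t <- (seq_len(nt) - 1) / sr
        n_form <- params$n_formants %||% sample(2:3, 1)
        f1 <- exp(runif(1, log(300), log(900)))
        f2 <- exp(runif(1, log(max(2 * f1, 1000)), log(2600)))
        f3 <- exp(runif(1, log(max(1.3 * f2, 2800)), log(6500)))
        formants <- c(f1, f2, f3)[seq_len(n_form)]
        n_syl <- sample(1:3, 1)
        syl_rate <- runif(1, 1.5, min(4, n_syl / dur + 2))
        env <- numeric(nt)
        starts <- seq(0.02, by = 1 / syl_rate, length.out = n_syl)
        for (s0 in starts) {
          # fast (>= 16 Hz equivalent) onset, slower decay
          seg <- pmax(0, 1 - exp(-(t - s0) / 0.015)) *
            exp(-pmax(0, t - s0) / runif(1, 0.1, 0.25))
          seg[t < s0] <- 0
          env <- pmax(env, seg)
        }
        x <- numeric(nt)
        for (ff in formants) {
          bw <- ff * runif(1, 0.08, 0.18)
          band <- c(max(ff - bw, 60), min(ff + bw, sr / 2 - 100)) / (sr / 2)
          x <- x + runif(1, 0.5, 1) *
            as.numeric(signal::filter(signal::butter(2, band, "pass"),
                                      rnorm(nt)))
        }
        x <- x * env
        mx <- max(abs(x))
        if (mx > 0) x <- x / mx
        w <- waveform(x, sr)
        attr(w, "label") <- sprintf("word_%02d", i)
        attr(w, "formants_hz") <- formants
        w
      }
    })
  })
  attr(out, "labels") <- vapply(out, attr, character(1), "label")
  out
}

# Causal lag kernel at the frame rate: second-order (12 dB/oct) lowpass with
# the given corner frequency (Hz), area-normalized, n_lags long. The steep
# rolloff makes envelope information above the corner rate fall under the
# trial noise, emulating the loss of envelope-locking at fast rates.
corner_lag_kernel <- function(corner_hz, n_lags, frame_rate = 100) {
  u <- (seq_len(n_lags) - 1) / frame_rate
  k <- u * exp(-2 * pi * corner_hz * u)
  k[1] <- k[2] / 2
  k / sum(k)
}

# True decoder-space filter of a unit: weights over representation channels
# and lags, as an [C x L] matrix.
unit_filter <- function(unit, channel_axis, n_lags = 12, frame_rate = 100,
                        scales = c(0.5, 1, 2, 4, 8),
                        rates = c(1, 2, 4, 8, 16, 32)) {
  if (unit$kind == "envelope_locked") {
    freq <- channel_axis
    prof <- rowSums(vapply(unit$freq_peaks_hz, function(p)
      exp(-0.5 * (log2(freq / p) / 0.35)^2), numeric(length(freq))))
    lagk <- corner_lag_kernel(unit$corner_or_peak_rate_hz, n_lags, frame_rate)
  } else {
    signed_rates <- c(-rev(rates), rates)
    grid <- expand.grid(scale = scales, rate_hz = signed_rates)
    prof <- exp(-0.5 * (log2(abs(grid$rate_hz) /
                               unit$corner_or_peak_rate_hz) / 0.6)^2)
    lagk <- corner_lag_kernel(4, n_lags, frame_rate)
  }
  unit$gain * outer(prof, lagk)
}

#' Simulate population responses to stimuli
#'
#' Each unit's noiseless response is its stimulus-space representation
#' (spectrogram for envelope-locked units, rate-scale modulation energy for
#' modulation-energy units) convolved with the unit's true filter over
#' causal lags. White Gaussian noise at `noise_sd` (in units of the
#' noiseless response SD) is drawn independently per trial, and the output
#' is z-scored per unit. Multiple trials per stimulus share the noiseless
#' response and differ only in noise.
#'
#' @param stimuli list of [waveform]s (from [generate_stimuli]).
#' @param units list of [synthetic_unit]s.
#' @param n_trials trials per stimulus (1).
#' @param seed integer seed (noise).
#' @param frame_rate_hz frame rate (100).
#' @param n_freq spectrogram channels for the linear pathway (32).
#' @param n_lags true-filter lag count (12).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise
#'   (0 = white).
#' @param margin_frames post-stimulus silence frames appended to every trial
#'   (25, i.e. 250 ms): recordings are continuous, so responses to the end of
#'   a word persist into the following silence.
#' @return list of class `synthetic_dataset`: `resp` ([neural_response]),
#'   `trial_table`, `spectrograms` (per trial, 32 channels),
#'   `stim_spectrogram` / `stim_rate_scale` (concatenated matrices),
#'   `ground_truth`, `seed`.
#' @export
simulate_population_responses <- function(stimuli, units, n_trials = 1,
                                          seed = 1, frame_rate_hz = 100,
                                          n_freq = 32, n_lags = 12,
                                          ar1 = 0, margin_frames = 25,
                                          precomputed = NULL) {
  if (!is.null(precomputed)) {
    specs <- precomputed$specs
    mods <- precomputed$mods
  } else {
    specs <- lapply(stimuli, function(w)
      downsample_spectrogram(compute_auditory_spectrogram(w), n_freq))
    if (margin_frames > 0) {
      specs <- lapply(specs, function(s) auditory_spectrogram(
        cbind(s$values, matrix(0, nrow(s$values), margin_frames)),
        s$freq_hz, s$frame_rate_hz, s$compression))
    }
    mods <- lapply(specs, function(s)
      compute_modulation_representation(s, reduced_form = "rate_scale"))
  }
  labels <- attr(stimuli, "labels") %||%
    (precomputed$labels %||% paste0("stim", seq_along(specs)))
  frames_per_stim <- vapply(specs, function(s) ncol(s$values), integer(1))
  ord <- rep(seq_along(specs), each = n_trials)
  trial_table <- data.frame(trial_id = seq_along(ord), stimulus = ord,
                            label = labels[ord],
                            n_frames = frames_per_stim[ord])
  S_spec <- do.call(rbind, lapply(ord, function(i) flatten_channels(specs[[i]])))
  S_rs <- do.call(rbind, lapply(ord, function(i) flatten_channels(mods[[i]])))
  trial_index <- rep(trial_table$trial_id, trial_table$n_frames)
  freq_axis <- specs[[1]]$freq_hz
  resp <- with_seed(derive_seed(seed, "responses"), {
    vapply(units, function(u) {
      Srep <- if (u$kind == "envelope_locked") S_spec else S_rs
      H <- unit_filter(u, freq_axis, n_lags, frame_rate_hz)
      X <- lagged_design(Srep, n_lags, trial_index, "backward")
      y <- as.numeric(X %*% as.numeric(t(H)))
      sdy <- sd(y); if (sdy < 1e-12) sdy <- 1
      y <- y / sdy
      eps <- rnorm(length(y))
      if (ar1 > 0) eps <- as.numeric(stats::filter(eps, ar1, "recursive"))
      y <- y + u$noise_sd * eps * (if (ar1 > 0) sqrt(1 - ar1^2) else 1)
      y
    }, numeric(length(trial_index)))
  })
  resp <- zscore_cols(resp)
  structure(list(
    resp = neural_response(resp, frame_rate_hz, c(70, 150),
                           standardized = TRUE, trial_index = trial_index),
    trial_table = trial_table,
    spectrograms = specs,
    stim_spectrogram = S_spec,
    stim_rate_scale = S_rs,
    ground_truth = units,
    labels = labels,
    representations = list(specs = specs, mods = mods, labels = labels),
    seed = seed), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d trials (%d frames) x %d units, kinds: %s\n",
              nrow(x$trial_table), nrow(x$resp$values), ncol(x$resp$values),
              paste(unique(vapply(x$ground_truth, `[[`, "", "kind")),
                    collapse = "/")))
  invisible(x)
}

#' Standard benchmark fixtures
#'
#' Three datasets exercising the pipeline end to end:
#' \describe{
#'   \item{a}{mixed population (half envelope-locked, half
#'     modulation-energy) responding to a 47-word formant-word set; for
#'     end-to-end decoding plus word identification.}
#'   \item{b}{pure envelope-locked population over an AM-tone / sweep /
#'     word battery; linear spectrogram decoding is sufficient.}
#'   \item{c}{pure modulation-energy population over the same battery; the
#'     directional contrast where rate-scale decoding beats spectrogram
#'     decoding at fast rates.}
#' }
#'
#' @param fixture `"a"`, `"b"` or `"c"`.
#' @param seed integer seed.
#' @param config overrides: `n_units`, `noise_sd`, `n_words`.
#' @return a `synthetic_dataset` with a `manifest` attribute recording
#'   ground truth and generation parameters.
#' @export
make_benchmark <- function(fixture = c("a", "b", "c"), seed = 7,
                           config = list()) {
  fixture <- match.arg(fixture)
  cfg <- utils::modifyList(list(
    n_units = if (fixture == "a") 16 else 12,
    noise_sd = if (fixture == "a") 0.3 else 0.2,
    n_words = 47), config)
  if (fixture == "a") {
    stimuli <- generate_stimuli("formant_word", n = cfg$n_words, seed = seed)
    kinds <- rep(c("envelope_locked", "modulation_energy"),
                 length.out = cfg$n_units)
  } else {
    tones <- generate_stimuli("am_tone", n = 6, seed = seed,
                              params = list(f0_hz = rep(c(500, 2000), 3),
                                            rate_hz = c(1, 2, 4, 8, 16, 32),
                                            dur_s = 1.5))
    noises <- generate_stimuli("am_noise", n = 6, seed = seed,
                               params = list(rate_hz = c(1, 2, 4, 8, 16, 32),
                                             dur_s = 1.5))
    sweeps <- generate_stimuli("sweep", n = 4, seed = seed,
                               params = list(f_start_hz = c(300, 3000, 500, 5000),
                                             f_end_hz = c(3000, 300, 5000, 500),
                                             dur_s = 1.5))
    words <- generate_stimuli("formant_word", n = 8, seed = seed,
                              params = list(dur_range_s = c(0.8, 1.4)))
    stimuli <- c(tones, noises, sweeps, words)
    attr(stimuli, "labels") <- c(attr(tones, "labels"),
                                 attr(noises, "labels"),
                                 attr(sweeps, "labels"),
                                 attr(words, "labels"))
    kinds <- rep(if (fixture == "b") "envelope_locked" else
                   "modulation_energy", cfg$n_units)
  }
  units <- make_units(cfg$n_units, kinds, cfg$noise_sd, seed)
  ds <- simulate_population_responses(stimuli, units, seed = seed)
  attr(ds, "manifest") <- list(fixture = fixture, seed = seed, config = cfg,
                               unit_kinds = kinds,
                               labels = attr(stimuli, "labels"))
  ds
}
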