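#' Raw multichannel recording container
#'
#' Cortical surface field potentials as an electrodes-by-samples matrix with
#' sample-rate metadata. Channels flagged bad (artifacts, poor contact) are
#' carried as metadata and excluded from referencing.
#'
#' @param signal numeric matrix `[n_electrodes x n_samples]`.
#' @param sample_rate_hz sampling rate (1,000-3,052 typical for clinical
#'   systems).
#' @param bad_channels integer indices of excluded electrodes.
#' @param electrode_labels optional character labels.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(signal, sample_rate_hz, bad_channels = integer(0),
                          electrode_labels = NULL) {
  signal <- as.matrix(signal)
  if (!all(is.finite(signal))) stop_invalid_input("signal has non-finite values")
  if (length(bad_channels) && (any(bad_channels < 1) ||
                               any(bad_channels > nrow(signal))))
    stop_invalid_input("bad_channels outside electrode range")
  if (is.null(electrode_labels))
    electrode_labels <- paste0("e", seq_len(nrow(signal)))
  structure(list(signal = signal, sample_rate_hz = sample_rate_hz,
                 bad_channels = as.integer(bad_channels),
                 electrode_labels = electrode_labels),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d electrodes x %d samples @ %g Hz (%d bad)\n",
              nrow(x$signal), ncol(x$signal), x$sample_rate_hz,
              length(x$bad_channels)))
  invisible(x)
}

#' Neural response matrix container
#'
#' Band-power responses at the stimulus frame rate, one column per electrode.
#' When standardized, each electrode has zero mean and unit SD over the
#' standardization window.
#'
#' @param values matrix `[n_frames x n_electrodes]`.
#' @param frame_rate_hz frame rate; must equal the stimulus frame rate.
#' @param band_hz length-2 band edges in Hz.
#' @param standardized logical flag.
#' @param trial_index optional per-frame trial id.
#' @return an object of class `neural_response`.
#' @export
neural_response <- function(values, frame_rate_hz = 100, band_hz = c(70, 150),
                            standardized = FALSE, trial_index = NULL) {
  values <- as.matrix(values)
  if (!is.null(trial_index) && length(trial_index) != nrow(values))
    stop_invalid_input("trial_index length must match n_frames")
  structure(list(values = values, frame_rate_hz = frame_rate_hz,
                 band_hz = band_hz, standardized = standardized,
                 trial_index = trial_index),
            class = "neural_response")
}

#' @export
print.neural_response <- function(x, ...) {
  cat(sprintf("<neural_response> %d frames x %d electrodes @ %g Hz, band %g-%g Hz%s\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              x$band_hz[1], x$band_hz[2],
              if (x$standardized) ", z-scored" else ""))
  invisible(x)
}

#' Re-montage a recording to a common average reference
#'
#' Subtracts the instantaneous mean over good channels from each good
#' channel; bad channels are passed through unchanged and excluded from the
#' mean. Any signal component common to all good channels is removed exactly.
#'
#' @param rec a [raw_recording].
#' @return a [raw_recording] after referencing.
#' @export
common_average_reference <- function(rec) {
  good <- setdiff(seq_len(nrow(rec$signal)), rec$bad_channels)
  if (length(good) < 2) stop_invalid_input("need >= 2 good channels for CAR")
  ref <- colMeans(rec$signal[good, , drop = FALSE])
  out <- rec$signal
  out[good, ] <- sweep(rec$signal[good, , drop = FALSE], 2, ref)
  raw_recording(out, rec$sample_rate_hz, rec$bad_channels,
                rec$electrode_labels)
}

# Zero-phase FIR bandpass: forward-backward FFT convolution with a
# Blackman-window fir1 design (~74 dB stopband per pass, squared by the two
# passes). Order comes from a transition width of min(10 Hz, band_lo / 2),
# capped by the signal length, and is recorded on the output for
# reproducibility.
fir_bandpass <- function(x, sr, band) {
  trans <- min(10, band[1] / 2)
  ord <- 2 * ceiling(5.5 * sr / trans / 2)         # even order
  ord <- min(ord, 2 * floor((length(x) - 1) / 4))
  h <- signal::fir1(ord, band / (sr / 2), type = "pass",
                    window = signal::blackman(ord + 1))
  n <- length(x)
  L <- length(h)
  y1 <- signal::fftfilt(h, c(x, numeric(2 * L)))
  y <- rev(signal::fftfilt(h, rev(y1)))[seq_len(n)]
  attr(y, "filter_order") <- ord
  y
}

#' Extract z-scored band power at the stimulus frame rate
#'
#' Each electrode is band-pass filtered (zero-phase FIR), the analytic-signal
#' envelope is squared to power, averaged into frames at `frame_rate`, and
#' z-scored over the whole session.
#'
#' @param rec a [raw_recording].
#' @param band length-2 band in Hz; default the high-gamma band (70, 150).
#' @param frame_rate output frame rate (100 Hz).
#' @param measure `"power"` (squared envelope, default) or `"amplitude"`.
#' @param standardize z-score per electrode (default TRUE).
#' @return a [neural_response] `[n_frames x n_electrodes]`.
#' @export
extract_band_power <- function(rec, band = c(70, 150), frame_rate = 100,
                               measure = c("power", "amplitude"),
                               standardize = TRUE) {
  measure <- match.arg(measure)
  nyq <- rec$sample_rate_hz / 2
  if (band[2] >= nyq || band[1] <= 0 || band[1] >= band[2])
    stop_invalid_config("band must lie within (0, Nyquist)")
  n_el <- nrow(rec$signal)
  env <- matrix(0, ncol(rec$signal), n_el)
  ord <- NA_integer_
  for (e in seq_len(n_el)) {
    bp <- fir_bandpass(rec$signal[e, ], rec$sample_rate_hz, band)
    ord <- attr(bp, "filter_order")
    a <- Mod(analytic_signal(as.numeric(bp)))
    env[, e] <- if (measure == "power") a^2 else a
  }
  vals <- frame_average(env, rec$sample_rate_hz, frame_rate)
  if (standardize) vals <- zscore_cols(vals)
  out <- neural_response(vals, frame_rate, band, standardized = standardize)
  attr(out, "filter_order") <- ord
  out
}

#' Band-specific response matrices across a range of frequencies
#'
#' Splits `[lo, hi]` into contiguous bands of (approximately) `width` Hz and
#' processes each as [extract_band_power]. With defaults (1-300 Hz, 10 Hz
#' width) this yields 30 response matrices.
#'
#' @param rec a [raw_recording].
#' @param lo,hi range in Hz.
#' @param width band width in Hz.
#' @param ... passed to [extract_band_power].
#' @return list of [neural_response], one per band.
#' @export
multiband_power <- function(rec, lo = 1, hi = 300, width = 10, ...) {
  n_bands <- (hi - lo) / width
  if (abs(n_bands - round(n_bands)) > 0.15)
    stop_invalid_config("band width does not divide the range [lo, hi]")
  n_bands <- round(n_bands)
  edges <- seq(lo, hi, length.out = n_bands + 1)
  lapply(seq_len(n_bands), function(b) {
    extract_band_power(rec, band = c(edges[b], edges[b + 1]), ...)
  })
}

#' Segment a response matrix into stimulus-aligned trials
#'
#' Cuts `stim_frames` frames starting at each trial onset and concatenates
#' the segments in trial-table order, attaching a per-frame trial index.
#'
#' @param resp a [neural_response] covering the whole session.
#' @param events data frame with columns `trial_id` and `onset_s` (and
#'   optionally `offset_s`, `label`).
#' @param stim_frames frames per trial (single value or per-trial vector).
#' @return a [neural_response] of `sum(stim_frames)` frames with
#'   `trial_index` set.
#' @export
align_trials <- function(resp, events, stim_frames) {
  n <- nrow(events)
  if (length(stim_frames) == 1) stim_frames <- rep(stim_frames, n)
  on <- round(events$onset_s * resp$frame_rate_hz) + 1
  off <- on + stim_frames - 1
  ord <- order(on)
  for (i in seq_len(n - 1)) {
    a <- ord[i]; b <- ord[i + 1]
    if (off[a] >= on[b])
      stop_invalid_input("overlapping trials: ", events$trial_id[a], " and ",
                         events$trial_id[b])
  }
  bad <- which(on < 1 | off > nrow(resp$values))
  if (length(bad))
    stop_invalid_input("trial outside recording: ",
                       paste(events$trial_id[bad], collapse = ", "))
  idx <- unlist(lapply(seq_len(n), function(i) on[i]:off[i]))
  trial_index <- rep(events$trial_id, stim_frames)
  neural_response(resp$values[idx, , drop = FALSE], resp$frame_rate_hz,
                  resp$band_hz, resp$standardized, trial_index)
}

#' Read a recording from delimited text
#'
#' Expects a tab- or comma-separated matrix with electrodes in columns and a
#' header of electrode labels; the sample rate is passed explicitly.
#'
#' @param path file path.
#' @param sample_rate_hz sampling rate of the stored signal.
#' @param bad_channels indices of bad channels.
#' @param sep field separator.
#' @return a [raw_recording].
#' @export
read_recording <- function(path, sample_rate_hz, bad_channels = integer(0),
                           sep = "\t") {
  d <- utils::read.table(path, header = TRUE, sep = sep)
  raw_recording(t(as.matrix(d)), sample_rate_hz, bad_channels,
                electrode_labels = colnames(d))
}

#' Read a trial/event table from CSV
#'
#' Columns: `trial_id`, `label`, `onset_s`, `offset_s`.
#'
#' @param path file path.
#' @return data frame.
#' @export
read_trial_table <- function(path) {
  d <- read.csv(path)
  need <- c("trial_id", "label", "onset_s", "offset_s")
  if (!all(need %in% names(d)))
    stop_invalid_input("trial table must have columns: ",
                       paste(need, collapse = ", "))
  d
}
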