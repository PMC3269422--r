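# Lazily built, cached fixtures shared across test files (one R session).
.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, .fx, inherits = FALSE)) assign(name, builder(), .fx)
  get(name, .fx, inherits = FALSE)
}

# 2 s amplitude-modulated 1 kHz tone at 4 Hz, 32-channel spectrogram
fx_am_spec <- function(rate = 4, dur = 2, phase = 0, depth = 0.9) {
  sr <- 16000
  t <- seq(0, dur - 1 / sr, by = 1 / sr)
  x <- sin(2 * pi * 1000 * t) * (1 + depth * sin(2 * pi * rate * t + phase)) /
    (1 + depth)
  downsample_spectrogram(compute_auditory_spectrogram(waveform(x, sr)), 32)
}

# smooth two-blob spectrogram (inversion round trips)
fx_blob_spec <- function() {
  F_ <- 32; T_ <- 100
  v <- outer(exp(-0.5 * ((1:F_ - 10) / 2.5)^2),
             exp(-0.5 * ((1:T_ - 40) / 12)^2)) +
    0.8 * outer(exp(-0.5 * ((1:F_ - 22) / 3)^2),
                exp(-0.5 * ((1:T_ - 55) / 10)^2))
  auditory_spectrogram(v, exp(seq(log(180), log(7000), length.out = F_)), 100)
}

# small word set for identification tests
fx_word_set <- function(n = 12, seed = 21) {
  stims <- generate_stimuli("formant_word", n = n, seed = seed)
  specs <- lapply(stims, function(w)
    downsample_spectrogram(compute_auditory_spectrogram(w), 32))
  word_set(attr(stims, "labels"), specs)
}

# toy decodable dataset: known decoder filters, iid responses
fx_toy_decode <- function(seed = 1, T_ = 600, N = 3, C = 2, L = 8) {
  set.seed(seed)
  R <- matrix(rnorm(T_ * N), T_, N)
  trial_index <- rep(seq_len(T_ / 100), each = 100)
  X <- speechdecode:::lagged_design(R, L, trial_index, "forward")
  W <- matrix(0, N * L, C)
  W[c(3, 10, 20), 1] <- c(1.5, -1, 0.5)
  W[c(1, 12, 22), 2] <- c(1, 0.8, -0.7)
  list(R = R, S = X %*% W, W = W, trial_index = trial_index,
       N = N, C = C, L = L)
}

fx_smoothed_wordset <- function(ws) {
  fixture("smoothed_wordset", function()
    word_set(ws$labels, lapply(ws$spectrograms, smooth_spectrogram)))
}

# brute-force enumeration of all monotone full DTW paths (small grids)
exhaustive_dtw <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + cost[i, j]
    if (acc >= best) return()
    if (i == n && j == m) { best <<- acc; return() }
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
  }
  recurse(1, 1, 0)
  best
}
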