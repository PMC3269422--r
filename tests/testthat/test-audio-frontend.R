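test_that("auditory spectrogram localizes a pure tone and has the printed shape", {
  sr <- 16000
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  s <- compute_auditory_spectrogram(waveform(sin(2 * pi * 1000 * t), sr))
  expect_equal(dim(s$values), c(128, 100))
  expect_equal(s$frame_rate_hz, 100)
  expect_true(all(s$values >= 0))
  # column-wise argmax at the channel nearest 1 kHz (oracle: per-filter RMS
  # computed by the filterbank itself is what frames average)
  target <- which.min(abs(s$freq_hz - 1000))
  am <- apply(s$values[, 10:90], 2, which.max)
  expect_true(all(abs(am - target) <= 1))
  # zero waveform -> floor everywhere
  s0 <- compute_auditory_spectrogram(waveform(rep(0, sr) + 1e-30, sr))
  expect_lt(max(s0$values), 1e-10)
  # invalid configs
  expect_error(compute_auditory_spectrogram(waveform(t, sr), fmax = 9000),
               class = "invalid_config")
  expect_error(waveform(numeric(0), sr), class = "invalid_input")
})

test_that("frequency downsampling averages adjacent channel groups", {
  sr <- 16000
  t <- seq(0, 0.5 - 1 / sr, by = 1 / sr)
  s <- compute_auditory_spectrogram(waveform(rnorm(length(t)), sr))
  d <- downsample_spectrogram(s, 32)
  expect_equal(nrow(d$values), 32)
  expect_equal(range(d$freq_hz)[1] > 180, TRUE)
  # constant spectrogram unchanged
  cs <- auditory_spectrogram(matrix(2, 128, 10), s$freq_hz, 100)
  expect_equal(downsample_spectrogram(cs, 32)$values,
               matrix(2, 32, 10))
  # block pattern: hand-computed group means of 4
  v <- matrix(rep(1:128, 3), 128, 3)
  bs <- auditory_spectrogram(v, s$freq_hz, 100)
  d4 <- downsample_spectrogram(bs, 32)
  expect_equal(d4$values[, 1], as.numeric(rowsum(1:128, rep(1:32, each = 4)) / 4))
  # per-frame energy mean preserved
  expect_equal(colMeans(d$values), colMeans(s$values), tolerance = 1e-12)
  expect_error(downsample_spectrogram(s, 33), class = "invalid_config")
})

test_that("modulation representation has the printed channel structure", {
  s <- fixture("am4", fx_am_spec)
  m <- compute_modulation_representation(s)
  expect_equal(dim(m$values)[1:3], c(5, 12, 32))
  expect_equal(prod(dim(m$values)[1:3]), 1920)
  expect_equal(sort(unique(abs(m$rates_hz))), c(1, 2, 4, 8, 16, 32))
  expect_true(all(m$values >= 0))
  rs <- compute_modulation_representation(s, reduced_form = "rate_scale")
  expect_equal(prod(dim(rs$values)[1:2]), 60)
  ro <- compute_modulation_representation(s, reduced_form = "rate_only")
  expect_equal(nrow(ro$values), 6)
  expect_error(compute_modulation_representation(s, reduced_form = "bogus"),
               class = "invalid_config")
  # flattening
  expect_equal(ncol(flatten_channels(m)), 1920)
  expect_equal(ncol(flatten_channels(rs)), 60)
  expect_equal(ncol(flatten_channels(ro)), 6)
})

test_that("temporally constant spectrograms carry no modulation energy", {
  s <- fixture("am4", fx_am_spec)
  const <- auditory_spectrogram(matrix(1, 32, 100), s$freq_hz, 100)
  m <- compute_modulation_representation(const)
  expect_lt(max(m$values), 1e-10)
})

test_that("AM at 4 Hz peaks the 4 Hz rate channels and stays steady", {
  s <- fixture("am4", fx_am_spec)
  m <- compute_modulation_representation(s)
  steady <- 60:150
  prof <- apply(m$values[, , , steady], 2, sum)
  rates <- m$rates_hz
  expect_equal(abs(rates[which.max(prof)]), 4)
  # oracle: localized 2-D Fourier modulus of the spectrogram has the same
  # rank ordering of unsigned-rate energies
  v <- s$values - rowMeans(s$values)
  A <- Mod(fft(rbind(v, matrix(0, 32, ncol(v)))))^2
  om <- (seq_len(ncol(v)) - 1) / ncol(v) * 100
  om <- ifelse(om <= 50, om, om - 100)
  en <- colSums(A)
  oracle <- sapply(c(1, 2, 4, 8, 16, 32), function(r)
    sqrt(sum(en[abs(om) >= r / sqrt(2) & abs(om) < r * sqrt(2)])))
  ours <- sapply(c(1, 2, 4, 8, 16, 32), function(r)
    sum(prof[abs(rates) == r]))
  expect_equal(order(oracle), order(ours))
  # steady-state output of the peak channel is near-constant (energy coding)
  i4 <- which(rates == 4)
  ch <- which.min(abs(s$freq_hz - 1000))
  ts <- apply(m$values[, i4, ch, steady, drop = FALSE], 4, sum)
  expect_lt(sd(ts) / mean(ts), 0.1)
})

test_that("modulation magnitude is phase invariant and monotone in depth", {
  m0 <- compute_modulation_representation(fixture("am4", fx_am_spec))
  m90 <- compute_modulation_representation(
    fixture("am4_p90", function() fx_am_spec(phase = pi / 2)))
  steady <- 60:150
  a <- apply(m0$values[, , , steady], c(1, 2), mean)
  b <- apply(m90$values[, , , steady], c(1, 2), mean)
  expect_lt(max(abs(a - b)) / max(a), 0.05)
  # total modulation energy non-decreasing in modulation depth
  en <- vapply(c(0.3, 0.6, 0.9), function(d) {
    m <- compute_modulation_representation(
      fixture(paste0("am_d", d), function() fx_am_spec(depth = d)))
    sum(m$values[, , , steady]^2)
  }, numeric(1))
  expect_true(all(diff(en) > 0))
})

test_that("upward sweeps load negative rates, downward sweeps positive", {
  sr <- 16000
  up <- generate_stimuli("sweep", 1, seed = 1,
                         params = list(f_start_hz = 300, f_end_hz = 3000))[[1]]
  dn <- generate_stimuli("sweep", 1, seed = 1,
                         params = list(f_start_hz = 3000, f_end_hz = 300))[[1]]
  for (w in list(up, dn)) {
    s <- downsample_spectrogram(compute_auditory_spectrogram(w), 32)
    m <- compute_modulation_representation(s)
    neg <- sum(m$values[, m$rates_hz < 0, , ])
    pos <- sum(m$values[, m$rates_hz > 0, , ])
    if (identical(w, up)) expect_gt(neg / pos, 1.5)
    else expect_lt(neg / pos, 1 / 1.5)
  }
})

test_that("magnitude-only modulation inversion round-trips a smooth spectrogram", {
  s <- fixture("blob", fx_blob_spec)
  m <- compute_modulation_representation(s)
  inv <- suppressWarnings(
    invert_modulation_to_spectrogram(m, n_init = 6, seed = 9,
                                     max_iter = 150, tol = 1e-6))
  expect_gt(cor(as.vector(inv$values), as.vector(s$values)), 0.35)
  # seeded determinism
  inv2 <- suppressWarnings(
    invert_modulation_to_spectrogram(m, n_init = 2, seed = 5, max_iter = 30))
  inv3 <- suppressWarnings(
    invert_modulation_to_spectrogram(m, n_init = 2, seed = 5, max_iter = 30))
  expect_identical(inv2$values, inv3$values)
  # all-zero magnitudes -> floor spectrogram
  z <- m; z$values[] <- 0
  expect_equal(max(invert_modulation_to_spectrogram(z, 1, 1)$values), 0)
})

test_that("projection iterations improve the modulation round trip", {
  s <- fixture("blob", fx_blob_spec)
  m <- compute_modulation_representation(s)
  rs <- vapply(c(3, 120), function(k) {
    inv <- suppressWarnings(
      invert_modulation_to_spectrogram(m, n_init = 2, seed = 4,
                                       max_iter = k, tol = 1e-9))
    cor(as.vector(inv$values), as.vector(s$values))
  }, numeric(1))
  expect_gt(rs[2], rs[1])
})

test_that("spectrogram-to-waveform inversion preserves tonal content", {
  sr <- 16000
  t <- seq(0, 1 - 1 / sr, by = 1 / sr)
  s <- compute_auditory_spectrogram(waveform(sin(2 * pi * 1000 * t), sr),
                                    n_channels = 32)
  w <- invert_spectrogram_to_waveform(s, n_iter = 12, seed = 1)
  s2 <- compute_auditory_spectrogram(w, n_channels = 32)
  expect_equal(which.max(rowMeans(s2$values)), which.max(rowMeans(s$values)))
  # silence -> near-zero waveform
  z <- auditory_spectrogram(matrix(0, 32, 50), s$freq_hz, 100)
  wz <- invert_spectrogram_to_waveform(z, n_iter = 5, seed = 1)
  expect_lt(max(abs(wz$samples)), 1e-8)
  # bit-identical under a fixed seed
  w2 <- invert_spectrogram_to_waveform(s, n_iter = 12, seed = 1)
  expect_identical(w$samples, w2$samples)
})

test_that("WAV files round-trip through the PCM reader and writer", {
  sr <- 16000
  x <- 0.5 * sin(2 * pi * 440 * seq(0, 0.1, by = 1 / sr))
  path <- tempfile(fileext = ".wav")
  write_wav(waveform(x, sr), path)
  w <- read_wav(path)
  expect_equal(w$sample_rate_hz, sr)
  expect_equal(w$samples, x, tolerance = 1e-4)
})
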