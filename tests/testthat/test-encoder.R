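# smooth random stimulus with trial structure for encoding fits
fx_encode_stim <- function(seed = 2, T_ = 2000, C = 32) {
  set.seed(seed)
  S <- matrix(rnorm(T_ * C), T_, C)
  S <- t(apply(S, 1, function(r)
    as.numeric(stats::filter(r, rep(1, 3) / 3, sides = 2))))
  S[is.na(S)] <- 0
  S <- apply(S, 2, function(cl)
    as.numeric(stats::filter(cl, rep(1, 4) / 4, sides = 1)))
  S[is.na(S)] <- 0
  list(S = S, trial_index = rep(seq_len(T_ / 100), each = 100),
       freq = exp(seq(log(180), log(7000), length.out = C)))
}

test_that("planted STRFs are recovered with the printed parameter count", {
  st <- fixture("encode_stim", fx_encode_stim)
  L <- 15
  H <- matrix(0, 32, L)
  lagk <- exp(-(0:(L - 1)) / 4) * sin(2 * pi * (0:(L - 1)) / 10)
  H[8, ] <- 1.2 * lagk
  H[20, ] <- 0.8 * lagk
  y0 <- as.numeric(speechdecode:::lagged_design(st$S, L, st$trial_index,
                                                "backward") %*%
                     as.numeric(t(H)))
  set.seed(3)
  y <- y0 + 0.1 * sd(y0) * rnorm(length(y0))
  tr <- which(st$trial_index %in% 1:16)
  va <- which(st$trial_index %in% 17:18)
  m <- fit_strf(st$S, y, tr, va, fit_config(n_lags = L, max_iter = 4000),
                st$trial_index)
  expect_equal(length(m$weights), 32 * L)
  expect_gt(cor(as.vector(m$weights), as.vector(H)), 0.9)
  # spectrogram32 space at default lags: 3,200 parameters
  s <- fixture("am4", fx_am_spec)
  m32 <- fit_strf(s, rnorm(ncol(s$values)), 1:150, 151:190,
                  fit_config(max_iter = 5))
  expect_equal(length(m32$weights), 3200)
  # response independent of the stimulus: prediction near zero
  set.seed(4)
  mcv0 <- fit_strf_cv(st$S, rnorm(nrow(st$S)), list(n_resamples = 3, seed = 5),
                      fit_config(n_lags = 6, max_iter = 500), st$trial_index)
  expect_lt(abs(mcv0$prediction_r), 0.15)
})

test_that("prediction obeys the convolution contract", {
  st <- fixture("encode_stim", fx_encode_stim)
  zero <- strf_model(matrix(0, 32, 5), "custom", st$freq)
  p <- predict_response(zero, st$S)
  expect_equal(p$prediction, rep(0, nrow(st$S)))
  # time-shuffled stimulus destroys prediction
  L <- 10
  H <- matrix(rnorm(32 * L, sd = 0.3), 32, L)
  m <- strf_model(H, "custom", st$freq)
  y <- predict_response(m, st$S)$prediction
  set.seed(5)
  shuf <- st$S[sample(nrow(st$S)), ]
  expect_lt(abs(cor(predict_response(m, shuf)$prediction, y)), 0.1)
  expect_error(predict_response(strf_model(H, "rate_only", 1:32),
                                fx_am_spec()), class = "invalid_input")
})

test_that("frequency tuning zeroes inhibition and marginalizes lags", {
  freq <- exp(seq(log(180), log(7000), length.out = 32))
  W <- matrix(0, 32, 10)
  W[5, 3] <- 2
  m <- strf_model(W, "spectrogram32", freq)
  cu <- frequency_tuning(m)
  expect_equal(which(cu$values > 0), 5)
  expect_equal(cu$values[5], 2)
  # all-negative STRF -> all-zero curve
  mneg <- strf_model(-abs(matrix(rnorm(320), 32, 10)), "spectrogram32", freq)
  expect_equal(max(frequency_tuning(mneg)$values), 0)
  expect_error(frequency_tuning(strf_model(W, "rate_only", 1:32)),
               class = "invalid_input")
})

test_that("the two linear rate-tuning estimators agree on smooth STRFs", {
  freq <- exp(seq(log(180), log(7000), length.out = 32))
  set.seed(7)
  agree <- vapply(1:6, function(i) {
    W <- matrix(rnorm(32 * 20), 32, 20)
    W <- t(apply(W, 1, function(r)
      as.numeric(stats::filter(r, rep(1, 5) / 5, sides = 2))))
    W[is.na(W)] <- 0
    W <- apply(W, 2, function(cl)
      as.numeric(stats::filter(cl, rep(1, 3) / 3, sides = 2)))
    W[is.na(W)] <- 0
    ms <- strf_model(W, "spectrogram32", freq)
    cor(rate_tuning(ms, "linear_filterbank")$values,
        rate_tuning(ms, "linear_mtf")$values)
  }, numeric(1))
  expect_true(all(agree > 0.9))
})

test_that("rate tuning localizes modulation kernels and DC content", {
  freq <- exp(seq(log(180), log(7000), length.out = 32))
  u <- (0:59) / 100
  tker <- Re((4 * u)^2 * exp(-3.5 * 4 * u) * exp(2i * pi * 4 * u))
  W4 <- outer(exp(-0.5 * ((1:32 - 16) / 3)^2), tker)
  m4 <- strf_model(W4, "spectrogram32", freq)
  rates <- c(1, 2, 4, 8, 16, 32)
  expect_equal(rates[which.max(rate_tuning(m4, "linear_filterbank")$values)], 4)
  expect_equal(rates[which.max(rate_tuning(m4, "linear_mtf")$values)], 4)
  # constant (DC) STRF concentrates at the lowest rate
  mdc <- strf_model(matrix(1, 32, 40) * exp(-0.5 * ((1:32 - 16) / 5)^2),
                    "spectrogram32", freq)
  expect_equal(rates[which.max(rate_tuning(mdc, "linear_filterbank")$values)], 1)
  # nonlinear method requires a modulation-space model
  expect_error(rate_tuning(m4, "nonlinear"), class = "invalid_input")
  ro <- strf_model(matrix(c(0, 0, 3, 0, 0, 0), 6, 1), "rate_only", rates)
  expect_equal(rates[which.max(rate_tuning(ro, "nonlinear")$values)], 4)
})

test_that("peak finding honors significance and half-octave separation", {
  freq <- exp(seq(log(200), log(6400), length.out = 11))  # 0.5 oct spacing
  v <- c(0, 1, 0, 0, 2, 0, 0, 0, 1.5, 0, 0)
  cu <- tuning_curve(freq, v, se = rep(0.1, 11), axis_type = "frequency")
  # two significant maxima >1 octave apart -> both kept
  pk <- find_tuning_peaks(cu)
  expect_equal(pk$peak_idx, c(2, 5, 9))
  # maxima with t below threshold are excluded
  pk2 <- find_tuning_peaks(cu, t_stats = c(0, 1.9, 0, 0, 30, 0, 0, 0, 30, 0, 0))
  expect_equal(pk2$peak_idx, c(5, 9))
  # close maxima merged keeping the larger
  v3 <- c(0, 2, 1.5, 0, 0, 0, 0, 0, 0, 0, 0)
  freq3 <- exp(seq(log(200), log(800), length.out = 11)) # 0.2 oct spacing
  pk3 <- find_tuning_peaks(tuning_curve(freq3, v3, se = rep(0.01, 11)))
  expect_equal(pk3$peak_idx, 2)
})

test_that("ensemble curves are normalized, filtered and scale-invariant", {
  freq <- exp(seq(log(180), log(7000), length.out = 16))
  mk <- function(peak, amp, r) {
    W <- matrix(0, 16, 5)
    W[peak, 2] <- amp
    m <- strf_model(W, "spectrogram32", freq, prediction_r = r)
    m$resample_weights <- matrix(rep(as.numeric(t(W)), 4), 4, byrow = TRUE) +
      matrix(rnorm(4 * 80, sd = 1e-3), 4)
    m
  }
  models <- list(mk(4, 1, 0.5), mk(4, 10, 0.4), mk(9, 2, 0.3))
  ens <- ensemble_tuning(models, "frequency", min_r = 0.1)
  expect_equal(ens$n_sites, 3)
  # identical sites up to gain: normalized curves contribute equally
  expect_equal(ens$curve$values[4], 2 / 3, tolerance = 0.01)
  expect_equal(ens$curve$values[9], 1 / 3, tolerance = 0.01)
  # site below the accuracy filter is excluded
  ens2 <- ensemble_tuning(c(models, list(mk(12, 5, 0.05))), "frequency")
  expect_equal(ens2$n_sites, 3)
  expect_error(ensemble_tuning(list(mk(4, 1, 0.01)), "frequency"),
               class = "invalid_input")
})

test_that("tuning spread counts covered frequency bins", {
  freq <- exp(seq(log(180), log(7000), length.out = 32))
  mk <- function(peaks) {
    W <- matrix(0, 32, 5)
    W[peaks, 2] <- 5
    m <- strf_model(W, "spectrogram32", freq)
    m$resample_weights <- matrix(rep(as.numeric(t(W)), 4), 4, byrow = TRUE) +
      matrix(rnorm(4 * 160, sd = 1e-4), 4)
    m
  }
  # no peaks anywhere
  expect_equal(tuning_spread(list(mk(integer(0)))), 0)
  # peaks in every bin (peaks within one model spaced > 0.5 octave so none
  # merge: channels 8 apart on a 0.17 oct/channel axis)
  expect_equal(tuning_spread(lapply(1:8, function(i)
    mk(c(i, i + 8, i + 16, i + 24)))), 1)
  # planted peaks covering 8 of 32 bins
  expect_equal(tuning_spread(list(mk(c(1, 5)), mk(c(9, 13)),
                                  mk(c(17, 21)), mk(c(25, 29)))), 0.25)
})
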