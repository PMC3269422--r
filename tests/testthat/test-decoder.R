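test_that("noiseless responses from known filters are recovered", {
  fx <- fixture("toy_decode", fx_toy_decode)
  tr <- which(fx$trial_index %in% 1:4)
  va <- which(fx$trial_index == 5)
  te <- which(fx$trial_index == 6)
  m <- fit_reconstruction(fx$S, fx$R, tr, va,
                          fit_config(n_lags = fx$L, max_iter = 2e4,
                                     patience = 200), fx$trial_index)
  # per-channel filter dimensionality: n_electrodes x n_lags each
  expect_equal(dim(m$weights), c(fx$C, fx$L, fx$N))
  West <- t(matrix(m$weights, fx$C, fx$L * fx$N))
  expect_gt(cor(as.vector(West), as.vector(fx$W)), 0.95)
  pred <- predict_stimulus(m, fx$R, fx$trial_index)
  expect_gt(cor(as.vector(pred[te, ]), as.vector(fx$S[te, ])), 0.95)
})

test_that("pure-noise responses yield near-zero weights and accuracy", {
  fx <- fixture("toy_decode", fx_toy_decode)
  set.seed(11)
  S0 <- matrix(rnorm(nrow(fx$R) * 2), ncol = 2)
  tr <- which(fx$trial_index %in% 1:4)
  va <- which(fx$trial_index == 5)
  te <- which(fx$trial_index == 6)
  m0 <- fit_reconstruction(S0, fx$R, tr, va,
                           fit_config(n_lags = fx$L, max_iter = 5000),
                           fx$trial_index)
  expect_lt(max(abs(m0$weights)), 0.1)
  expect_gt(mean(m0$weights == 0), 0.5)   # sparsity contract
  p0 <- predict_stimulus(m0, fx$R, fx$trial_index)
  expect_lt(abs(cor(as.vector(p0[te, ]), as.vector(S0[te, ]))), 0.15)
})

test_that("prediction follows the linear summation contract", {
  fx <- fixture("toy_decode", fx_toy_decode)
  # all-zero response -> intercept-only (zero for centered stim) prediction
  m <- reconstruction_model(array(0.5, c(1, 3, 2)), intercept = 0)
  z <- predict_stimulus(m, matrix(0, 50, 2))
  expect_equal(as.numeric(z), rep(0, 50))
  # single unit weight: prediction equals the response shifted by the lag
  w <- array(0, c(1, 3, 2)); w[1, 2, 1] <- 1
  md <- reconstruction_model(w, intercept = 0)
  R <- matrix(rnorm(100), 50, 2)
  p <- predict_stimulus(md, R)
  expect_equal(p[1:49, 1], R[2:50, 1])
  # electrode mismatch is refused
  expect_error(predict_stimulus(md, matrix(0, 10, 5)),
               class = "invalid_input")
})

test_that("early-stopped descent run to convergence matches ridge", {
  fx <- fixture("toy_decode", fx_toy_decode)
  set.seed(12)
  # noisy observation so the comparison is non-trivial
  Sn <- fx$S + 0.5 * sd(fx$S) * matrix(rnorm(length(fx$S)), nrow(fx$S))
  tr <- which(fx$trial_index %in% 1:4)
  va <- which(fx$trial_index == 5)
  te <- which(fx$trial_index == 6)
  conv <- fit_reconstruction(Sn, fx$R, tr, va,
                             fit_config(n_lags = fx$L, max_iter = 5e4,
                                        patience = Inf), fx$trial_index)
  X <- speechdecode:::lagged_design(fx$R, fx$L, fx$trial_index, "forward")
  lam <- 1e-6 * length(tr)
  W <- solve(crossprod(X[tr, ]) + lam * diag(ncol(X)),
             crossprod(X[tr, ], Sn[tr, ]))
  pred_cd <- predict_stimulus(conv, fx$R, fx$trial_index)[te, ]
  pred_ls <- X[te, ] %*% W
  expect_gt(cor(as.vector(pred_cd), as.vector(pred_ls)), 0.99)
})

test_that("accuracy evaluation uses per-channel Fisher-averaged correlations", {
  set.seed(13)
  A <- matrix(rnorm(200), 100, 2)
  rep1 <- evaluate_accuracy(A, A)
  expect_equal(rep1$per_channel_r, c(1, 1))
  # hand-computed Fisher average of r = {0.8, 0.2}
  make_pair <- function(r, n = 2000) {
    x <- rnorm(n); y <- r * x + sqrt(1 - r^2) * rnorm(n)
    cbind(x, y)
  }
  p1 <- make_pair(0.8); p2 <- make_pair(0.2)
  rep2 <- evaluate_accuracy(cbind(p1[, 1], p2[, 1]), cbind(p1[, 2], p2[, 2]))
  expect_equal(rep2$mean_r,
               tanh(mean(atanh(rep2$per_channel_r))), tolerance = 1e-12)
  # zero-variance channel excluded and counted
  B <- A; B[, 2] <- 3
  rep3 <- evaluate_accuracy(A, B)
  expect_true(is.na(rep3$per_channel_r[2]))
  expect_equal(rep3$n_dropped_channels, 1)
  expect_equal(rep3$mean_r, rep3$per_channel_r[1])
})

test_that("Monte Carlo CV reuses partitions verbatim and is stable", {
  fx <- fixture("toy_decode", fx_toy_decode)
  plan <- list(n_resamples = 3, seed = 5)
  hy <- fit_config(n_lags = fx$L, max_iter = 4000)
  cv1 <- run_monte_carlo_cv(fx$S, fx$R, plan, hy, fx$trial_index)
  cv2 <- run_monte_carlo_cv(fx$S, fx$R, plan, hy, fx$trial_index,
                            stim_space = "other")
  expect_identical(cv1$partitions, cv2$partitions)
  # supplying partitions reuses them byte-identically
  cv3 <- run_monte_carlo_cv(fx$S, fx$R, plan, hy, fx$trial_index,
                            partitions = cv1$partitions)
  expect_identical(cv3$partitions, cv1$partitions)
  expect_gt(cv1$report$mean_r, 0.95)
  # shuffled-label control: accuracy collapses
  set.seed(14)
  Sshuf <- fx$S[sample(nrow(fx$S)), ]
  cv0 <- run_monte_carlo_cv(Sshuf, fx$R, plan, hy, fx$trial_index)
  expect_lt(cv0$report$mean_r, 0.2)
  expect_error(run_monte_carlo_cv(fx$S, fx$R,
                                  list(n_resamples = 2, seed = 1,
                                       fractions = c(0.5, 0.2, 0.3))),
               class = "invalid_input")
})

test_that("informative electrodes are recovered from planted structure", {
  set.seed(15)
  T_ <- 800; N <- 6; L <- 6
  R <- matrix(rnorm(T_ * N), T_, N)
  trial_index <- rep(1:8, each = 100)
  X <- speechdecode:::lagged_design(R, L, trial_index, "forward")
  W <- matrix(0, N * L, 1)
  W[c(2, 8)] <- c(2, 1.5)                 # electrodes 1 and 2 informative
  S <- X %*% W + 0.3 * matrix(rnorm(T_))
  cv <- run_monte_carlo_cv(S, R, list(n_resamples = 5, seed = 2),
                           fit_config(n_lags = L, max_iter = 4000),
                           trial_index)
  ie <- informative_electrodes(cv$model)
  expect_true(all(c(1, 2) %in% ie$electrodes))
  expect_false(any(4:6 %in% ie$electrodes))
  # all-zero weights give an empty set
  m0 <- cv$model
  m0$weights[] <- 0
  m0$resample_stats$t_ratio[] <- 0
  expect_length(informative_electrodes(m0)$electrodes, 0)
  # |t| at the threshold boundary is excluded
  m1 <- cv$model
  m1$resample_stats$t_ratio[] <- 2.4
  expect_length(informative_electrodes(m1)$electrodes, 0)
  # too few resamples refused
  m2 <- cv$model
  m2$resample_stats$n_resamples <- 2
  expect_error(informative_electrodes(m2), class = "invalid_input")
})

test_that("accuracy grows with electrode count on synthetic populations", {
  set.seed(16)
  T_ <- 800; N <- 8; L <- 4
  R <- matrix(rnorm(T_ * N), T_, N)
  trial_index <- rep(1:8, each = 100)
  X <- speechdecode:::lagged_design(R, L, trial_index, "forward")
  W <- matrix(rnorm(N * L, sd = 0.5), N * L, 1)
  S <- X %*% W + 1.5 * matrix(rnorm(T_))
  plan <- list(n_resamples = 2, seed = 3)
  hy <- fit_config(n_lags = L, max_iter = 3000)
  curve <- electrode_count_curve(S, R, plan, subset_sizes = c(1, 4, 8),
                                 n_draws = 2, seed = 6, hyper = hy,
                                 trial_index = trial_index)
  expect_true(all(diff(curve$mean_r) > -0.02))    # non-decreasing trend
  # full-population subset equals plain CV with the same plan
  cv <- run_monte_carlo_cv(S, R, plan, hy, trial_index)
  expect_equal(curve$mean_r[3], cv$report$mean_r, tolerance = 1e-12)
  expect_error(electrode_count_curve(S, R, plan, subset_sizes = 20,
                                     trial_index = trial_index),
               class = "invalid_config")
})

test_that("accuracy is invariant to per-electrode affine rescaling", {
  fx <- fixture("toy_decode", fx_toy_decode)
  plan <- list(n_resamples = 2, seed = 5)
  hy <- fit_config(n_lags = fx$L, max_iter = 3000)
  cv1 <- run_monte_carlo_cv(fx$S, fx$R, plan, hy, fx$trial_index)
  R2 <- sweep(sweep(fx$R, 2, c(2, 0.5, 7), "*"), 2, c(-1, 3, 0.2), "+")
  R2 <- speechdecode:::zscore_cols(R2)
  cv2 <- run_monte_carlo_cv(fx$S, R2, plan, hy, fx$trial_index)
  # compare on the z scale: near r = 1 the correlation itself is
  # hypersensitive to float-level differences
  expect_equal(atanh(cv1$report$mean_r) > 4, atanh(cv2$report$mean_r) > 4)
  expect_equal(min(cv1$report$mean_r, 0.999),
               min(cv2$report$mean_r, 0.999), tolerance = 1e-4)
})

test_that("rate-resolved accuracy marginalizes the rate-scale space", {
  s <- fixture("am4", fx_am_spec)
  out <- rate_resolved_accuracy(s, s)
  expect_length(out, 6)
  expect_equal(names(out), c("1", "2", "4", "8", "16", "32"))
  expect_true(all(out > 0.999))
  # low-pass degraded copy: slow rates survive, fast rates degrade
  v <- s$values
  k <- 21
  sm <- t(apply(v, 1, function(r) stats::filter(r, rep(1 / k, k), sides = 2)))
  sm[is.na(sm)] <- 0
  slp <- auditory_spectrogram(pmax(sm, 0), s$freq_hz, s$frame_rate_hz)
  out2 <- rate_resolved_accuracy(slp, s)
  expect_gt(mean(out2[c("1", "2")]), mean(out2[c("16", "32")]))
  expect_error(rate_resolved_accuracy(
    compute_modulation_representation(s, rates = c(2, 8),
                                      reduced_form = "rate_scale"), s),
    class = "invalid_config")
})
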