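test_that("box smoothing has the documented impulse and constant behavior", {
  freq <- exp(seq(log(180), log(7000), length.out = 32))
  const <- auditory_spectrogram(matrix(3, 32, 60), freq, 100)
  sm <- smooth_spectrogram(const)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
  # unit impulse -> rectangle of value 1/(window area), away from edges
  v <- matrix(0, 32, 120); v[16, 60] <- 1
  imp <- auditory_spectrogram(v, freq, 100)
  smi <- smooth_spectrogram(imp, t_window = 0.1, f_window_oct = 0.8)
  ht <- 5; hf <- floor(0.4 / mean(diff(log2(freq))))
  area <- (2 * ht + 1) * (2 * hf + 1)
  expect_equal(smi$values[16, 60], 1 / area, tolerance = 1e-12)
  expect_equal(smi$values[16, 60 - ht], 1 / area, tolerance = 1e-12)
  expect_equal(smi$values[16, 60 - ht - 1], 0)
  expect_equal(sum(smi$values > 0), area)
  expect_error(smooth_spectrogram(const, t_window = -1),
               class = "invalid_config")
})

test_that("DTW similarity is maximal for identity and recovers stretches", {
  ws <- fixture("wordset", fx_word_set)
  a <- ws$spectrograms[[1]]
  expect_equal(as.numeric(dtw_similarity(a, a)), 1, tolerance = 1e-9)
  # uniform 1.3x time stretch: DTW recovers at least the linear-time r
  idx <- round(seq(1, ncol(a$values), length.out = round(1.3 * ncol(a$values))))
  b <- auditory_spectrogram(a$values[, idx], a$freq_hz, a$frame_rate_hz)
  sim <- as.numeric(dtw_similarity(a, b))
  lin <- cor(as.vector(a$values),
             as.vector(b$values[, round(seq(1, ncol(b$values),
                                            length.out = ncol(a$values)))]))
  expect_gte(sim, lin - 1e-9)
  expect_gt(sim, 0.95)
  # independent noise -> similarity near zero
  set.seed(8)
  n1 <- auditory_spectrogram(matrix(abs(rnorm(32 * 40)), 32), a$freq_hz, 100)
  n2 <- auditory_spectrogram(matrix(abs(rnorm(32 * 40)), 32), a$freq_hz, 100)
  expect_lt(abs(as.numeric(dtw_similarity(n1, n2))), 0.25)
  # symmetry within tolerance
  c2 <- ws$spectrograms[[2]]
  expect_equal(as.numeric(dtw_similarity(a, c2)),
               as.numeric(dtw_similarity(c2, a)), tolerance = 0.05)
  expect_error(dtw_similarity(a, auditory_spectrogram(matrix(1, 16, 10),
    exp(seq(log(180), log(7000), length.out = 16)), 100)),
    class = "invalid_input")
})

test_that("DTW alignment cost matches the exhaustive-path oracle", {
  set.seed(9)
  freq <- exp(seq(log(180), log(7000), length.out = 8))
  for (i in 1:8) {
    n <- sample(4:7, 1); m <- sample(4:7, 1)
    A <- matrix(abs(rnorm(8 * n)), 8)
    B <- matrix(abs(rnorm(8 * m)), 8)
    cost <- speechdecode:::dtw_cost_matrix(A, B)
    dp <- speechdecode:::dtw_core(cost)
    expect_equal(dp$distance, exhaustive_dtw(cost), tolerance = 1e-10)
  }
})

test_that("identification rank follows the percentile definition", {
  ws <- fixture("wordset", fx_word_set)
  # exact spectrogram of the correct word ranks 1.0
  r <- identification_rank(ws$spectrograms[[3]], ws$labels[3], ws)
  expect_equal(as.numeric(r), 1)
  # hand-set similarity scores: truth second of three
  ws3 <- word_set(c("a", "b", "c"), ws$spectrograms[1:3])
  r2 <- identification_rank(ws$spectrograms[[1]], "b", ws3,
                            scores = c(0.9, 0.5, 0.1))
  expect_equal(as.numeric(r2), 0.5)
  # correct word scoring lowest ranks 0; ties count half
  expect_equal(as.numeric(identification_rank(ws$spectrograms[[1]], "b", ws3,
                                              scores = c(0.9, 0.1, 0.5))), 0)
  expect_equal(as.numeric(identification_rank(ws$spectrograms[[1]], "b", ws3,
                                              scores = c(0.5, 0.5, 0.1))), 0.75)
  expect_error(identification_rank(ws$spectrograms[[1]], "nope", ws),
               class = "invalid_input")
})

test_that("rank is invariant under monotone transforms of similarity", {
  ws <- fixture("wordset", fx_word_set)
  ws3 <- word_set(c("a", "b", "c"), ws$spectrograms[1:3])
  sc <- c(0.9, 0.5, 0.1)
  r1 <- as.numeric(identification_rank(ws$spectrograms[[1]], "b", ws3,
                                       scores = sc))
  r2 <- as.numeric(identification_rank(ws$spectrograms[[1]], "b", ws3,
                                       scores = tanh(3 * sc) + 2))
  expect_equal(r1, r2)
})

test_that("the identification suite separates perfect decoding from chance", {
  ws <- fixture("wordset", fx_word_set)
  res <- identification_suite(ws$spectrograms, ws$labels, ws,
                              n_shuffles = 500, seed = 3)
  expect_equal(res$median_rank, 1)
  expect_lt(res$p_value, 1 / 500 + 1e-12)
  # ROC of the perfect case passes through (0, 1)
  expect_true(any(res$roc$fpr == 0 & res$roc$tpr == 1))
  # pairwise similarity matrices: symmetric actual matrix, unit diagonal
  expect_equal(res$similarity_actual, t(res$similarity_actual))
  expect_equal(unname(diag(res$similarity_actual)), rep(1, ws$n),
               tolerance = 1e-9)
  expect_gt(res$similarity_correlation, 0.9)   # recon == actual here
  expect_error(identification_suite(ws$spectrograms[1:3], ws$labels, ws),
               class = "invalid_input")
})

test_that("random reconstructions sit at chance with the expected spread", {
  ws <- fixture("wordset", fx_word_set)
  set.seed(10)
  n_draw <- 40
  ranks <- vapply(seq_len(n_draw), function(i) {
    fake <- auditory_spectrogram(matrix(abs(rnorm(32 * 50)), 32),
                                 ws$spectrograms[[1]]$freq_hz, 100)
    as.numeric(identification_rank(smooth_spectrogram(fake),
                                   ws$labels[(i %% ws$n) + 1],
                                   fx_smoothed_wordset(ws)))
  }, numeric(1))
  expect_lt(abs(mean(ranks) - 0.5), 3 * sd(ranks) / sqrt(n_draw) + 0.05)
})
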