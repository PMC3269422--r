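#' STRF (encoding) model container
#'
#' Per-electrode spectro-temporal receptive field: a linear filter from a
#' stimulus representation to one electrode's response, over `n_features x
#' n_lags` (3,200 parameters in the 32-channel spectrogram space, 600 in the
#' reduced rate-only space, 192,000 in the full modulation space). Positive
#' weights mark stimulus components associated with increased response.
#'
#' @param weights matrix `[n_features x n_lags]`.
#' @param space `"spectrogram32"`, `"rate_only"`, or `"modulation_full"`.
#' @param axis feature axis values: center frequencies (Hz) for spectrogram
#'   space, rates (Hz) for rate_only, channel grid data frame for the full
#'   space.
#' @param intercept scalar offset.
#' @param prediction_r cross-validated forward prediction accuracy.
#' @param resample_stats per-weight statistics across resamples.
#' @param resample_weights optional matrix `[n_resamples x n_params]` for
#'   exact SE propagation into tuning curves.
#' @return an object of class `strf_model`.
#' @export
strf_model <- function(weights, space, axis, intercept = 0,
                       prediction_r = NA_real_, resample_stats = NULL,
                       resample_weights = NULL) {
  structure(list(weights = weights, space = space, axis = axis,
                 intercept = intercept, prediction_r = prediction_r,
                 resample_stats = resample_stats,
                 resample_weights = resample_weights),
            class = "strf_model")
}

#' @export
print.strf_model <- function(x, ...) {
  cat(sprintf("<strf_model> %s: %d features x %d lags (%d params), prediction r = %.3f\n",
              x$space, nrow(x$weights), ncol(x$weights),
              length(x$weights), x$prediction_r))
  invisible(x)
}

# Full gradient descent with early stopping for a single response channel.
# Dense solution (no sparsity), step size 1/lambda_max(XtX) from power
# iteration. Returns the iterate with best validation MSE.
gradient_descent_channel <- function(XtX, Xty, Xval, yval, max_iter,
                                     patience) {
  P <- length(Xty)
  v <- rnorm(P)
  for (i in 1:30) { v <- XtX %*% v; v <- v / sqrt(sum(v^2)) }
  lmax <- as.numeric(crossprod(v, XtX %*% v))
  eta <- 1 / (lmax + 1e-12)
  w <- numeric(P)
  best_val <- mean(yval^2)
  best_w <- w
  stall <- 0L
  for (it in seq_len(max_iter)) {
    g <- Xty - XtX %*% w
    w <- w + eta * as.numeric(g)
    if (is.finite(patience)) {
      val_mse <- mean((yval - Xval %*% w)^2)
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse; best_w <- w; stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (!is.finite(patience)) best_w <- w
  best_w
}

# Resolve stimulus input to (matrix, space label, feature axis).
strf_stim_matrix <- function(stim, space = NULL) {
  if (is.matrix(stim)) {
    return(list(S = stim, space = space %||% "custom",
                axis = seq_len(ncol(stim))))
  }
  if (inherits(stim, "auditory_spectrogram")) {
    return(list(S = flatten_channels(stim), space = "spectrogram32",
                axis = stim$freq_hz))
  }
  if (inherits(stim, "modulation_representation")) {
    sp <- switch(stim$reduced_form, rate_only = "rate_only",
                 full = "modulation_full", rate_scale = "rate_scale")
    ax <- if (stim$reduced_form == "rate_only") stim$rates_hz
          else attr(flatten_channels(stim), "channel_info")
    return(list(S = flatten_channels(stim), space = sp, axis = ax))
  }
  stop_invalid_input("unsupported stimulus of class ", class(stim)[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a spectro-temporal receptive field (encoding model)
#'
#' Standard full-gradient descent on the MSE between predicted and observed
#' response, with early-stopping regularization (patience 50 on a validation
#' set). Unlike the sparse decoder fit, the solution is dense. The response
#' at frame `t` is modeled from stimulus features at lags `t, t-1, ...,
#' t-n_lags+1`.
#'
#' @param stim stimulus representation (object or `[T x C]` matrix).
#' @param resp_channel numeric vector: one electrode's response.
#' @param train_frames,val_frames frame indices for training / validation.
#' @param hyper a [fit_config] (`step` is ignored; the step size is set from
#'   the curvature).
#' @param trial_index per-frame trial ids.
#' @param space,axis optional space label and feature-axis values (needed
#'   when `stim` is a bare matrix, e.g. frequencies in Hz for a spectrogram
#'   matrix).
#' @return an [strf_model].
#' @export
fit_strf <- function(stim, resp_channel, train_frames, val_frames,
                     hyper = fit_config(), trial_index = NULL,
                     space = NULL, axis = NULL) {
  sm <- strf_stim_matrix(stim)
  if (!is.null(space)) sm$space <- space
  if (!is.null(axis)) sm$axis <- axis
  S <- sm$S
  if (length(resp_channel) != nrow(S))
    stop_invalid_input("stim/resp frame mismatch")
  if (anyNA(S) || anyNA(resp_channel)) stop_invalid_input("NA values in inputs")
  L <- hyper$n_lags
  X <- lagged_design(S, L, trial_index, "backward")
  stx <- std_fit(X[train_frames, , drop = FALSE])
  Xtr <- std_apply(X[train_frames, , drop = FALSE], stx)
  Xval <- std_apply(X[val_frames, , drop = FALSE], stx)
  mu_y <- mean(resp_channel[train_frames])
  sd_y <- sd(resp_channel[train_frames]); if (sd_y < 1e-12) sd_y <- 1
  y <- (resp_channel[train_frames] - mu_y) / sd_y
  yv <- (resp_channel[val_frames] - mu_y) / sd_y
  w <- gradient_descent_channel(crossprod(Xtr), crossprod(Xtr, y), Xval, yv,
                                hyper$max_iter, hyper$patience)
  w_orig <- w * sd_y / stx$s
  intercept <- mu_y - sum(w_orig * stx$mu)
  weights <- matrix(w_orig, ncol(S), L, byrow = TRUE)  # [C x L]
  strf_model(weights, sm$space, sm$axis, intercept)
}

#' Cross-validated STRF with resampled statistics
#'
#' Monte Carlo cross-validation (20 resamples by default) of [fit_strf] for
#' one electrode: per-resample fits supply the weight SEs and t-ratios, and
#' the cross-validated forward prediction accuracy is the Fisher-averaged
#' test-set correlation.
#'
#' @param stim,resp_channel,hyper,trial_index,space,axis as in [fit_strf].
#' @param plan list: `n_resamples` (20), `fractions` (0.8, 0.1, 0.1), `seed`.
#' @param partitions optional partition list to reuse (identical partitions
#'   across STRF model types).
#' @return an [strf_model] with `prediction_r`, `resample_stats` and
#'   `resample_weights`; partitions attached as attribute.
#' @export
fit_strf_cv <- function(stim, resp_channel, plan = list(),
                        hyper = fit_config(), trial_index = NULL,
                        partitions = NULL, space = NULL, axis = NULL) {
  plan <- utils::modifyList(list(n_resamples = 20,
                                 fractions = c(0.8, 0.1, 0.1), seed = 1), plan)
  sm <- strf_stim_matrix(stim)
  S <- sm$S
  if (is.null(trial_index)) stop_invalid_input("trial_index required")
  trials <- unique(trial_index)
  n_tr <- length(trials)
  n_val <- max(1, round(plan$fractions[2] * n_tr))
  n_test <- max(1, round(plan$fractions[3] * n_tr))
  n_train <- n_tr - n_val - n_test
  if (n_train < 1) stop_invalid_config("too few trials for non-empty splits")
  if (is.null(partitions)) {
    partitions <- with_seed(derive_seed(plan$seed, "strf_partitions"), {
      lapply(seq_len(plan$n_resamples), function(i) {
        idx <- sample(trials)
        list(train = sort(idx[seq_len(n_train)]),
             val = sort(idx[n_train + seq_len(n_val)]),
             test = sort(idx[n_train + n_val + seq_len(n_test)]))
      })
    })
  }
  W_all <- NULL
  r_test <- numeric(length(partitions))
  for (i in seq_along(partitions)) {
    p <- partitions[[i]]
    tr_f <- which(trial_index %in% p$train)
    va_f <- which(trial_index %in% p$val)
    te_f <- which(trial_index %in% p$test)
    m <- fit_strf(S, resp_channel, tr_f, va_f, hyper, trial_index,
                  space = space, axis = axis)
    pred <- predict_response(m, S, trial_index = trial_index)
    r_test[i] <- safe_cor(pred$prediction[te_f], resp_channel[te_f])
    wv <- as.numeric(m$weights)
    if (is.null(W_all)) W_all <- matrix(NA_real_, length(partitions), length(wv))
    W_all[i, ] <- wv
    if (i == 1) first <- m
  }
  rs <- resample_stats(W_all)
  out <- strf_model(matrix(rs$mean, nrow(first$weights), ncol(first$weights)),
                    first$space, first$axis, first$intercept,
                    prediction_r = fisher_mean(r_test[!is.na(r_test)]),
                    resample_stats = list(
                      se = matrix(rs$se, nrow(first$weights), ncol(first$weights)),
                      t_ratio = matrix(rs$t_ratio, nrow(first$weights),
                                       ncol(first$weights)),
                      n_resamples = rs$n_resamples),
                    resample_weights = W_all)
  attr(out, "partitions") <- partitions
  out
}

#' Predict a neural response from an STRF
#'
#' Convolves the stimulus features with the filter over lags. When an
#' observed response is supplied, the held-out Pearson correlation is
#' returned alongside.
#'
#' @param m an [strf_model].
#' @param stim stimulus representation matching the model's space.
#' @param observed optional observed response for accuracy.
#' @param trial_index per-frame trial ids.
#' @return list: `prediction` (vector), `r` (or NA).
#' @export
predict_response <- function(m, stim, observed = NULL, trial_index = NULL) {
  sm <- strf_stim_matrix(stim, space = m$space)
  if (!identical(sm$space, m$space) && sm$space != "custom")
    stop_invalid_input("stimulus space ", sm$space,
                       " does not match model space ", m$space)
  if (ncol(sm$S) != nrow(m$weights))
    stop_invalid_input("feature count mismatch")
  L <- ncol(m$weights)
  X <- lagged_design(sm$S, L, trial_index, "backward")
  pred <- as.numeric(X %*% as.numeric(t(m$weights))) + m$intercept
  r <- if (!is.null(observed)) safe_cor(pred, observed) else NA_real_
  list(prediction = pred, r = r)
}

#' Tuning curve container
#'
#' @param axis axis values (frequency in Hz or rate in Hz).
#' @param values curve values (nonnegative after the excitatory transform).
#' @param se optional standard errors (SD across resampled estimates).
#' @param axis_type `"frequency"` or `"rate"`.
#' @param normalized whether values are max-normalized.
#' @return object of class `tuning_curve`.
#' @export
tuning_curve <- function(axis, values, se = NULL,
                         axis_type = c("frequency", "rate"),
                         normalized = FALSE) {
  axis_type <- match.arg(axis_type)
  structure(list(axis = axis, values = values, se = se,
                 axis_type = axis_type, normalized = normalized,
                 peaks = NULL),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat(sprintf("<tuning_curve> %s, %d points%s\n", x$axis_type,
              length(x$values),
              if (!is.null(x$peaks)) paste0(", peaks at ",
                paste(signif(x$peaks, 3), collapse = ", ")) else ""))
  invisible(x)
}

# Excitatory tuning transform: zero the inhibitory (negative) weights, then
# sum across the lag dimension.
excitatory_marginal <- function(W) {
  W <- pmax(W, 0)
  rowSums(W)
}

#' Frequency tuning curve from a linear STRF
#'
#' Inhibitory (negative) weights are set to zero and the remainder summed
#' across time lags, one value per frequency channel. SEs are propagated by
#' recomputing the transform on each resampled weight estimate and taking
#' the SD across resamples.
#'
#' @param m an [strf_model] in spectrogram space.
#' @return a [tuning_curve] over the model's frequency axis.
#' @export
frequency_tuning <- function(m) {
  if (!m$space %in% c("spectrogram32", "custom"))
    stop_invalid_input("frequency tuning requires a spectrogram-space STRF")
  vals <- excitatory_marginal(m$weights)
  se <- NULL
  if (!is.null(m$resample_weights)) {
    per <- apply(m$resample_weights, 1, function(wv)
      excitatory_marginal(matrix(wv, nrow(m$weights), ncol(m$weights))))
    se <- apply(per, 1, sd)
  }
  tuning_curve(m$axis, vals, se, "frequency")
}

#' Temporal modulation rate tuning from an STRF
#'
#' Three estimators: `"nonlinear"` applies the excitatory-marginal transform
#' to a rate-only (or full modulation) STRF; `"linear_filterbank"` filters a
#' spectrogram-space STRF with the modulation filterbank and averages the
#' magnitude over the irrelevant dimensions; `"linear_mtf"` takes the modulus
#' of the 2-D Fourier transform of the STRF (the modulation transfer
#' function) marginalized to temporal rate. The two linear estimators agree
#' closely on smooth STRFs.
#'
#' @param m an [strf_model].
#' @param method one of `"nonlinear"`, `"linear_filterbank"`, `"linear_mtf"`.
#' @param rates unsigned rates (Hz) at which the curve is evaluated.
#' @param scales scales for the filterbank method.
#' @param frame_rate_hz lag sampling rate (100).
#' @return a [tuning_curve] over unsigned rates.
#' @export
rate_tuning <- function(m, method = c("nonlinear", "linear_filterbank",
                                      "linear_mtf"),
                        rates = c(1, 2, 4, 8, 16, 32),
                        scales = c(0.5, 1, 2, 4, 8), frame_rate_hz = 100) {
  method <- match.arg(method)
  if (method == "nonlinear") {
    if (!m$space %in% c("rate_only", "modulation_full"))
      stop_invalid_input("nonlinear rate tuning needs a modulation-space STRF")
    if (m$space == "rate_only") {
      vals <- excitatory_marginal(m$weights)
      se <- NULL
      if (!is.null(m$resample_weights)) {
        per <- apply(m$resample_weights, 1, function(wv)
          excitatory_marginal(matrix(wv, nrow(m$weights), ncol(m$weights))))
        se <- apply(per, 1, sd)
      }
      return(tuning_curve(m$axis, vals, se, "rate"))
    }
    # full modulation space: marginalize the excitatory weights to rate,
    # averaging positive and negative sweep directions
    info <- m$axis
    ex <- rowSums(pmax(m$weights, 0))
    vals <- vapply(rates, function(r) mean(ex[abs(info$rate_hz) == r]),
                   numeric(1))
    return(tuning_curve(rates, vals, NULL, "rate"))
  }
  if (!m$space %in% c("spectrogram32", "custom"))
    stop_invalid_input("linear rate tuning requires a spectrogram-space STRF")
  one_curve <- function(W) {
    if (method == "linear_filterbank") {
      an <- mod_analyze(W, m$axis, frame_rate_hz, rates, scales,
                        return_transfer = TRUE)
      # total (Parseval) energy per channel: the causal low-rate filters ring
      # past the short STRF support, so energy is integrated in the Fourier
      # domain rather than over the support only
      Wp <- matrix(0, an$nf, an$nt)
      Wp[seq_len(nrow(W)), seq_len(ncol(W))] <- W - rowMeans(W)
      Z <- fft(Wp)
      prof <- matrix(0, length(scales), length(an$signed_rates))
      for (si in seq_along(scales)) for (ri in seq_along(an$signed_rates))
        prof[si, ri] <- sqrt(sum(Mod(an$transfer[[si, ri]] * Z)^2))
      vapply(rates, function(r) mean(prof[, abs(an$signed_rates) == r]),
             numeric(1))
    } else {
      nf2 <- 2 * nrow(W)
      nt2 <- max(256, stats::nextn(ncol(W), 2))
      Wp <- matrix(0, nf2, nt2)
      Wp[seq_len(nrow(W)), seq_len(ncol(W))] <- W - rowMeans(W)
      A2 <- Mod(fft(Wp))^2
      om <- (seq_len(nt2) - 1) / nt2 * frame_rate_hz
      om <- ifelse(om <= frame_rate_hz / 2, om, om - frame_rate_hz)
      en <- colSums(A2)                      # marginal over spectral axis
      # marginalize onto the log-spaced rate grid: each rate bin integrates
      # the modulus over its geometric neighborhood (half-octave each side)
      vapply(rates, function(r) {
        sqrt(sum(en[abs(om) >= r / sqrt(2) & abs(om) < r * sqrt(2)]))
      }, numeric(1))
    }
  }
  vals <- one_curve(m$weights)
  se <- NULL
  if (!is.null(m$resample_weights)) {
    per <- apply(m$resample_weights, 1, function(wv)
      one_curve(matrix(wv, nrow(m$weights), ncol(m$weights))))
    se <- apply(per, 1, sd)
  }
  tuning_curve(rates, vals, se, "rate")
}

#' Identify significant, separated peaks in a tuning curve
#'
#' Local maxima whose t statistic exceeds `t_threshold` (2.0); peaks closer
#' than `min_separation_oct` (0.5 octave, `log2` of the axis ratio) are
#' merged keeping the larger amplitude (exact ties keep the lower axis
#' position).
#'
#' @param curve a [tuning_curve].
#' @param t_stats per-point t statistics; defaults to `values / se` when the
#'   curve carries SEs.
#' @param t_threshold significance threshold.
#' @param min_separation_oct minimum peak separation in octaves.
#' @return the curve with `peaks` (axis positions) and `peak_idx` set.
#' @export
find_tuning_peaks <- function(curve, t_stats = NULL, t_threshold = 2.0,
                              min_separation_oct = 0.5) {
  v <- curve$values
  n <- length(v)
  if (is.null(t_stats)) {
    if (is.null(curve$se)) stop_invalid_input("no t statistics available")
    t_stats <- ifelse(curve$se > 0, v / curve$se, Inf)
  }
  is_max <- vapply(seq_len(n), function(i) {
    left <- if (i > 1) v[i] > v[i - 1] else v[i] > 0
    right <- if (i < n) v[i] >= v[i + 1] else v[i] > 0
    left && right
  }, logical(1))
  cand <- which(is_max & t_stats > t_threshold & v > 0)
  if (length(cand) > 1) {
    cand <- cand[order(-v[cand], curve$axis[cand])]
    kept <- integer(0)
    for (i in cand) {
      if (all(abs(log2(curve$axis[i] / curve$axis[kept])) >
              min_separation_oct) || length(kept) == 0)
        kept <- c(kept, i)
    }
    cand <- sort(kept)
  }
  curve$peak_idx <- cand
  curve$peaks <- curve$axis[cand]
  curve
}

#' Ensemble (population) tuning curve and peak histogram
#'
#' Sites with cross-validated forward prediction accuracy `r > min_r` are
#' analyzed: each site's curve is normalized by its maximum and averaged
#' across sites; the histogram of per-site peak locations is attached.
#'
#' @param models list of [strf_model]s.
#' @param tuning `"frequency"` or `"rate"`; curves are computed with
#'   [frequency_tuning] or [rate_tuning].
#' @param min_r inclusion threshold on `prediction_r` (0.1).
#' @param method passed to [rate_tuning] when `tuning = "rate"`.
#' @param ... further arguments to the tuning function.
#' @return list: `curve` (mean normalized [tuning_curve]), `peak_counts`
#'   (named vector over axis positions), `n_sites`.
#' @export
ensemble_tuning <- function(models, tuning = c("frequency", "rate"),
                            min_r = 0.1, method = "nonlinear", ...) {
  tuning <- match.arg(tuning)
  keep <- vapply(models, function(m) isTRUE(m$prediction_r > min_r),
                 logical(1))
  models <- models[keep]
  if (length(models) == 0)
    stop_invalid_input("no sites pass the prediction accuracy filter")
  curves <- lapply(models, function(m) {
    cu <- if (tuning == "frequency") frequency_tuning(m)
          else rate_tuning(m, method = method, ...)
    find_tuning_peaks(cu)
  })
  axis <- curves[[1]]$axis
  mat <- vapply(curves, function(cu) {
    mx <- max(cu$values)
    if (mx > 0) cu$values / mx else cu$values
  }, numeric(length(axis)))
  mean_curve <- tuning_curve(axis, rowMeans(mat),
                             se = apply(mat, 1, sd) / sqrt(ncol(mat)),
                             axis_type = curves[[1]]$axis_type,
                             normalized = TRUE)
  peak_counts <- table(factor(unlist(lapply(curves, function(cu)
    signif(cu$peaks, 6))), levels = signif(axis, 6)))
  list(curve = mean_curve,
       peak_counts = as.numeric(peak_counts) / max(1, length(curves)),
       n_sites = length(curves))
}

#' Tuning spread: fraction of frequency bins covered by peaks
#'
#' Pools the significant frequency-tuning peaks of all sites and reports the
#' fraction of bins on the log-frequency axis (180-7,000 Hz) containing at
#' least one peak: 0 means no peaks anywhere, 1 means every bin is covered.
#'
#' @param models list of spectrogram-space [strf_model]s.
#' @param n_bins number of bins over the frequency axis (32).
#' @param fmin,fmax axis range in Hz.
#' @return fraction in `[0, 1]`.
#' @export
tuning_spread <- function(models, n_bins = 32, fmin = 180, fmax = 7000) {
  peaks <- unlist(lapply(models, function(m) {
    cu <- find_tuning_peaks(frequency_tuning(m))
    cu$peaks
  }))
  if (length(peaks) == 0) return(0)
  edges <- exp(seq(log(fmin), log(fmax), length.out = n_bins + 1))
  edges[1] <- edges[1] * (1 - 1e-9); edges[n_bins + 1] <- edges[n_bins + 1] * (1 + 1e-9)
  covered <- unique(findInterval(peaks, edges, rightmost.closed = TRUE))
  covered <- covered[covered >= 1 & covered <= n_bins]
  length(covered) / n_bins
}
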