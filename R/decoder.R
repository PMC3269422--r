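# ---------------------------------------------------------------------------
# Lagged design matrices
# ---------------------------------------------------------------------------

# Build a lagged design matrix from a frames-by-channels matrix, respecting
# trial boundaries (lags never reach across trials; out-of-trial samples are
# zero, the mean in standardized units). direction = "forward": row t holds
# x[t .. t+L-1, ] (the decoder reads the response at and after the stimulus
# frame). direction = "backward": row t holds x[t .. t-L+1, ] (the encoder
# reads the stimulus at and before the response frame). Column order: channel
#-major, lag-minor: (ch1 lag0, ch1 lag1, ..., ch2 lag0, ...).
lagged_design <- function(x, n_lags, trial_index = NULL,
                          direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  x <- as.matrix(x)
  T_ <- nrow(x); n_ch <- ncol(x)
  if (T_ < n_lags) stop_invalid_input("fewer frames than lags")
  if (is.null(trial_index)) trial_index <- rep(1L, T_)
  X <- matrix(0, T_, n_ch * n_lags)
  for (tr in unique(trial_index)) {
    rows <- which(trial_index == tr)
    n <- length(rows)
    xt <- x[rows, , drop = FALSE]
    for (l in seq_len(n_lags) - 1L) {
      if (l >= n) break
      if (direction == "forward") {
        src <- (1L + l):n; dst <- 1L:(n - l)
      } else {
        src <- 1L:(n - l); dst <- (1L + l):n
      }
      cols <- (seq_len(n_ch) - 1L) * n_lags + l + 1L
      X[rows[dst], cols] <- xt[src, , drop = FALSE]
    }
  }
  X
}

#' Reconstruction (decoding) model container
#'
#' Per-stimulus-channel linear filters over response lags and electrodes.
#' `weights` has dimension `[n_stim_channels, n_lags, n_electrodes]`; each
#' stimulus channel's filter is estimated independently, and exact zeros are
#' expected (the fitting algorithm is sparse).
#'
#' @param weights weight array `[C x L x N]`.
#' @param intercept per-channel intercepts.
#' @param stim_space label of the reconstructed representation
#'   (`"spectrogram32"`, `"rate_scale60"`, `"modulation_full"`, ...).
#' @param lag_step_s lag discretization (0.01 s).
#' @param resample_stats optional per-weight statistics across resamples.
#' @return an object of class `reconstruction_model`.
#' @export
reconstruction_model <- function(weights, intercept, stim_space = "spectrogram32",
                                 lag_step_s = 0.01, resample_stats = NULL) {
  structure(list(weights = weights, intercept = intercept,
                 stim_space = stim_space, lag_step_s = lag_step_s,
                 resample_stats = resample_stats),
            class = "reconstruction_model")
}

#' @export
print.reconstruction_model <- function(x, ...) {
  d <- dim(x$weights)
  cat(sprintf("<reconstruction_model> %s: %d channels x %d lags x %d electrodes (%.1f%% nonzero)\n",
              x$stim_space, d[1], d[2], d[3],
              100 * mean(x$weights != 0)))
  invisible(x)
}

#' Fitting configuration for decoding / encoding models
#'
#' @param n_lags temporal lags at 10 ms steps (100 default, i.e. 1 s).
#' @param step coordinate-descent step size as a fraction of the SD ratio
#'   between target and predictor.
#' @param max_iter iteration cap.
#' @param patience stop after this many consecutive iterations without
#'   validation improvement (50); `Inf` disables early stopping so the fit
#'   runs to `max_iter` (used for oracle comparisons).
#' @return a list of class `fit_config`.
#' @export
fit_config <- function(n_lags = 100, step = 1e-3, max_iter = 1e5,
                       patience = 50) {
  structure(list(n_lags = n_lags, step = step, max_iter = max_iter,
                 patience = patience), class = "fit_config")
}

# Greedy coordinate descent with early stopping for one target channel.
# Works on a precomputed Gram matrix (XtX) and gradient seed (Xty), with
# validation MSE monitored on (Xval, yval). All inputs are centered/scaled by
# the caller. Returns the weight vector achieving the best validation MSE.
coord_descent_channel <- function(XtX, Xty, Xval, yval, step, max_iter,
                                  patience) {
  P <- length(Xty)
  w <- numeric(P)
  g <- Xty
  val_pred <- numeric(length(yval))
  best_val <- mean(yval^2)
  best_w <- w
  stall <- 0L
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    j <- which.max(abs(g))
    if (abs(g[j]) < 1e-12) break
    delta <- step * sign(g[j])
    w[j] <- w[j] + delta
    g <- g - delta * XtX[, j]
    n_iter <- it
    if (is.finite(patience)) {
      val_pred <- val_pred + delta * Xval[, j]
      val_mse <- mean((yval - val_pred)^2)
      if (val_mse < best_val - 1e-12) {
        best_val <- val_mse
        best_w <- w
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= patience) break
      }
    }
  }
  if (!is.finite(patience)) best_w <- w
  list(w = best_w, n_iter = n_iter)
}

# Standardize columns with given (or computed) centers/scales; zero-variance
# columns are centered but left unscaled.
std_fit <- function(x) {
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s < 1e-12] <- 1
  list(mu = mu, s = s)
}
std_apply <- function(x, st) sweep(sweep(x, 2, st$mu), 2, st$s, "/")

#' Fit a stimulus reconstruction model
#'
#' For each stimulus channel independently, greedy coordinate descent
#' minimizes training MSE over the `N electrodes x n_lags` filter, with early
#' stopping on a validation set: fitting stops after `patience` consecutive
#' iterations without validation improvement, and the iterate with the best
#' validation MSE is returned. The algorithm yields sparse filters (most
#' weights exactly zero for short fits), performing variable selection
#' implicitly, so all electrodes can be included.
#'
#' @param stim stimulus representation: matrix `[T x C]`, or an
#'   [auditory_spectrogram] / [modulation_representation].
#' @param resp a [neural_response] or matrix `[T x N]`, frame-aligned with
#'   `stim`.
#' @param train_frames,val_frames row indices of training and validation
#'   frames (typically whole trials).
#' @param hyper a [fit_config].
#' @param trial_index per-frame trial ids (taken from `resp` if absent).
#' @param stim_space label stored on the model.
#' @return a [reconstruction_model].
#' @export
fit_reconstruction <- function(stim, resp, train_frames, val_frames,
                               hyper = fit_config(), trial_index = NULL,
                               stim_space = NULL) {
  S <- if (is.matrix(stim)) stim else flatten_channels(stim)
  if (is.null(stim_space))
    stim_space <- if (is.matrix(stim)) "custom" else class(stim)[1]
  R <- if (inherits(resp, "neural_response")) resp$values else as.matrix(resp)
  if (is.null(trial_index) && inherits(resp, "neural_response"))
    trial_index <- resp$trial_index
  if (nrow(S) != nrow(R)) stop_invalid_input("stim/resp frame mismatch")
  if (anyNA(S) || anyNA(R)) stop_invalid_input("NA values in inputs")
  L <- hyper$n_lags
  if (nrow(R) < L) stop_invalid_input("fewer frames than lags")
  X <- lagged_design(R, L, trial_index, "forward")
  N <- ncol(R); C <- ncol(S); P <- N * L
  stx <- std_fit(X[train_frames, , drop = FALSE])
  Xtr <- std_apply(X[train_frames, , drop = FALSE], stx)
  Xval <- std_apply(X[val_frames, , drop = FALSE], stx)
  XtX <- crossprod(Xtr)
  sty <- std_fit(S[train_frames, , drop = FALSE])
  W <- matrix(0, P, C)
  for (ch in seq_len(C)) {
    y <- (S[train_frames, ch] - sty$mu[ch]) / sty$s[ch]
    yv <- (S[val_frames, ch] - sty$mu[ch]) / sty$s[ch]
    fit <- coord_descent_channel(XtX, crossprod(Xtr, y), Xval, yv,
                                 hyper$step, hyper$max_iter, hyper$patience)
    W[, ch] <- fit$w
  }
  # back-transform to original units: w_orig = w_std * sd_y / sd_x
  W_orig <- W * (1 / stx$s) %o% sty$s
  intercept <- sty$mu - as.numeric(crossprod(W_orig, stx$mu))
  weights <- array(t(W_orig), dim = c(C, L, N))
  reconstruction_model(weights, intercept, stim_space,
                       lag_step_s = 1 / 100)
}

#' Predict a stimulus representation from neural responses
#'
#' Applies the reconstruction filters: the estimate of stimulus channel `f`
#' at frame `t` sums `g(tau, f, n) R(t + tau, n)` over electrodes and lags
#' (the decoder reads the response at and after the stimulus frame). Frames
#' whose lag window extends past a trial end use zero (mean) padding and are
#' flagged in the `edge_frames` attribute.
#'
#' @param model a [reconstruction_model].
#' @param resp a [neural_response] or matrix, electrodes matching the model.
#' @param trial_index per-frame trial ids.
#' @return matrix `[T x C]` of reconstructed channels.
#' @export
predict_stimulus <- function(model, resp, trial_index = NULL) {
  R <- if (inherits(resp, "neural_response")) resp$values else as.matrix(resp)
  if (is.null(trial_index) && inherits(resp, "neural_response"))
    trial_index <- resp$trial_index
  d <- dim(model$weights)
  if (ncol(R) != d[3])
    stop_invalid_input("electrode count mismatch: model has ", d[3],
                       ", response has ", ncol(R))
  L <- d[2]
  X <- lagged_design(R, L, trial_index, "forward")
  W <- t(matrix(model$weights, d[1], L * d[3]))   # [P x C]
  out <- X %*% W
  out <- sweep(out, 2, model$intercept, "+")
  if (is.null(trial_index)) trial_index <- rep(1L, nrow(R))
  edge <- unlist(lapply(split(seq_len(nrow(R)), trial_index), function(rows) {
    utils::tail(rows, L - 1)
  }))
  attr(out, "edge_frames") <- sort(unname(edge))
  out
}

#' Evaluate reconstruction accuracy
#'
#' One Pearson correlation per stimulus channel between reconstruction and
#' original; the overall mean is computed through Fisher's z-transform and
#' back. Channels with zero variance in either input have undefined r and are
#' excluded from the mean (their count is reported).
#'
#' @param recon,orig matrices `[T x C]` (or objects flattening to them) with
#'   identical shape and channel order.
#' @return list of class `accuracy_report`: `per_channel_r`, `mean_r`,
#'   `n_test_frames`, `n_dropped_channels`.
#' @export
evaluate_accuracy <- function(recon, orig) {
  A <- if (is.matrix(recon)) recon else flatten_channels(recon)
  B <- if (is.matrix(orig)) orig else flatten_channels(orig)
  if (!all(dim(A) == dim(B))) stop_invalid_input("shape mismatch")
  rs <- vapply(seq_len(ncol(A)), function(ch) safe_cor(A[, ch], B[, ch]),
               numeric(1))
  structure(list(per_channel_r = rs,
                 mean_r = fisher_mean(rs),
                 n_test_frames = nrow(A),
                 n_dropped_channels = sum(is.na(rs))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("<accuracy_report> mean r = %.3f over %d channels (%d frames)\n",
              x$mean_r, length(x$per_channel_r), x$n_test_frames))
  invisible(x)
}

#' Monte Carlo (repeated random subsampling) cross-validation
#'
#' For each resample, trials are randomly partitioned into training,
#' validation and test sets (80/10/10 by default), the model is fit on
#' train/validation, and accuracy is evaluated on the held-out test trials.
#' Weights and accuracies are averaged over resamples; per-weight standard
#' errors are the SD of the resampled estimates and feed the t-ratio
#' statistics. Pass `partitions` from a previous run to reuse identical data
#' partitions when comparing two stimulus spaces.
#'
#' @param stim stimulus matrix `[T x C]` or representation object.
#' @param resp a [neural_response] with `trial_index`, or matrix plus
#'   `trial_index`.
#' @param plan list: `n_resamples`, `fractions` (train, val, test), `seed`.
#' @param hyper a [fit_config].
#' @param trial_index per-frame trial ids.
#' @param partitions optional partition list from a previous run (paired
#'   comparison contract).
#' @param stim_space label stored on the model.
#' @return list: `model` (mean weights with `resample_stats`), `report`
#'   (pooled [accuracy_report] plus per-resample accuracies), `partitions`.
#' @export
run_monte_carlo_cv <- function(stim, resp, plan = list(), hyper = fit_config(),
                               trial_index = NULL, partitions = NULL,
                               stim_space = NULL) {
  plan <- utils::modifyList(list(n_resamples = 10,
                                 fractions = c(0.8, 0.1, 0.1), seed = 1), plan)
  S <- if (is.matrix(stim)) stim else flatten_channels(stim)
  R <- if (inherits(resp, "neural_response")) resp$values else as.matrix(resp)
  if (is.null(trial_index) && inherits(resp, "neural_response"))
    trial_index <- resp$trial_index
  if (is.null(trial_index)) stop_invalid_input("trial_index required")
  trials <- unique(trial_index)
  n_tr <- length(trials)
  fr <- plan$fractions
  if (abs(sum(fr) - 1) > 1e-9) stop_invalid_config("fractions must sum to 1")
  n_val <- max(1, round(fr[2] * n_tr))
  n_test <- max(1, round(fr[3] * n_tr))
  n_train <- n_tr - n_val - n_test
  if (n_train < 1)
    stop_invalid_config("too few trials (", n_tr, ") for non-empty splits")
  if (is.null(partitions)) {
    partitions <- with_seed(derive_seed(plan$seed, "partitions"), {
      lapply(seq_len(plan$n_resamples), function(i) {
        idx <- sample(trials)
        list(train = sort(idx[seq_len(n_train)]),
             val = sort(idx[n_train + seq_len(n_val)]),
             test = sort(idx[n_train + n_val + seq_len(n_test)]))
      })
    })
  }
  C <- ncol(S)
  W_all <- NULL
  per_res_r <- matrix(NA_real_, length(partitions), C)
  mean_r_res <- numeric(length(partitions))
  for (i in seq_along(partitions)) {
    p <- partitions[[i]]
    tr_f <- which(trial_index %in% p$train)
    va_f <- which(trial_index %in% p$val)
    te_f <- which(trial_index %in% p$test)
    m <- fit_reconstruction(S, R, tr_f, va_f, hyper, trial_index, stim_space)
    pred <- predict_stimulus(m, R, trial_index)
    rep_i <- evaluate_accuracy(pred[te_f, , drop = FALSE],
                               S[te_f, , drop = FALSE])
    per_res_r[i, ] <- rep_i$per_channel_r
    mean_r_res[i] <- rep_i$mean_r
    wv <- as.numeric(m$weights)
    if (is.null(W_all)) W_all <- matrix(NA_real_, length(partitions), length(wv))
    W_all[i, ] <- wv
    if (i == 1) first_model <- m
  }
  rs <- resample_stats(W_all)
  d <- dim(first_model$weights)
  mean_w <- array(rs$mean, dim = d)
  model <- reconstruction_model(mean_w, first_model$intercept,
                                first_model$stim_space,
                                resample_stats = list(
                                  se = array(rs$se, dim = d),
                                  t_ratio = array(rs$t_ratio, dim = d),
                                  n_resamples = rs$n_resamples))
  per_channel_r <- apply(per_res_r, 2, function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) NA_real_ else fisher_mean(v)
  })
  report <- structure(list(per_channel_r = per_channel_r,
                           mean_r = fisher_mean(mean_r_res),
                           per_resample_r = mean_r_res,
                           resample_se = sd(atanh(pmin(pmax(mean_r_res, -1 + 1e-12),
                                                       1 - 1e-12))),
                           n_test_frames = length(which(trial_index %in%
                                                          partitions[[1]]$test)),
                           n_dropped_channels = sum(is.na(per_channel_r))),
                      class = "accuracy_report")
  list(model = model, report = report, partitions = partitions)
}

#' Reconstruction accuracy resolved by temporal modulation rate
#'
#' Projects spectrogram-space reconstructions through the modulation
#' filterbank into the reduced rate-scale space and correlates each of the 60
#' rate-scale components with those of the original stimulus; correlations
#' are then Fisher-averaged over the scale dimension and over positive and
#' negative rates, giving one accuracy per unsigned rate. A reconstruction
#' already in rate-scale space is compared directly.
#'
#' @param recon reconstruction: [auditory_spectrogram], rate-scale
#'   [modulation_representation], or list of per-trial objects.
#' @param orig original stimulus in the same form (spectrogram accepted for
#'   either).
#' @param rates,scales filterbank configuration; must match between the two
#'   paths.
#' @return named vector of accuracies, one per unsigned rate.
#' @export
rate_resolved_accuracy <- function(recon, orig, rates = c(1, 2, 4, 8, 16, 32),
                                   scales = c(0.5, 1, 2, 4, 8)) {
  to_rs <- function(x) {
    if (inherits(x, "modulation_representation")) {
      if (x$reduced_form != "rate_scale")
        stop_invalid_config("modulation input must be rate_scale form")
      if (!identical(sort(unique(abs(x$rates_hz))), sort(rates)))
        stop_invalid_config("mismatched filterbank configuration")
      return(flatten_channels(x))
    }
    if (inherits(x, "auditory_spectrogram"))
      return(flatten_channels(compute_modulation_representation(
        x, rates, scales, "rate_scale")))
    stop_invalid_input("unsupported input of class ", class(x)[1])
  }
  cat_rs <- function(x) {
    if (is.list(x) && !inherits(x, c("auditory_spectrogram",
                                     "modulation_representation")))
      do.call(rbind, lapply(x, to_rs))
    else to_rs(x)
  }
  A <- cat_rs(recon); B <- cat_rs(orig)
  if (!all(dim(A) == dim(B))) stop_invalid_input("shape mismatch")
  signed_rates <- c(-rev(rates), rates)
  grid <- expand.grid(scale = scales, rate_hz = signed_rates)
  rs <- vapply(seq_len(ncol(A)), function(ch) safe_cor(A[, ch], B[, ch]),
               numeric(1))
  vapply(sort(rates), function(r) {
    fisher_mean(rs[abs(grid$rate_hz) == r & !is.na(rs)])
  }, numeric(1)) -> out
  names(out) <- sort(rates)
  out
}

#' Select informative electrodes from resampled model statistics
#'
#' Screens per-weight t-ratios (resampled mean / SE): an electrode is flagged
#' informative when at least one of its weights exceeds `|t| > t_threshold`
#' and survives Benjamini-Hochberg FDR correction at `alpha` (two-sided p
#' from a t distribution with `n_resamples - 1` df). Per-electrode weight
#' magnitudes (mean |w| over channels and lags) are reported alongside.
#'
#' @param model a [reconstruction_model] carrying `resample_stats`.
#' @param alpha FDR level (0.05).
#' @param t_threshold minimum |t| (2.5).
#' @return list: `electrodes` (integer indices), `weight_magnitude`
#'   (per-electrode), `max_t` (per-electrode), `selected` (per-weight logical
#'   array).
#' @export
informative_electrodes <- function(model, alpha = 0.05, t_threshold = 2.5) {
  rs <- model$resample_stats
  if (is.null(rs)) stop_invalid_input("model has no resample_stats")
  if (rs$n_resamples < 3)
    stop_invalid_input("need >= 3 resamples for reliable SE")
  tv <- rs$t_ratio
  p <- 2 * pt(abs(tv), df = rs$n_resamples - 1, lower.tail = FALSE)
  sel_flat <- fdr_select(as.numeric(p), alpha)
  sel <- array(sel_flat & !is.na(as.numeric(tv)) &
                 abs(as.numeric(tv)) > t_threshold, dim = dim(tv))
  d <- dim(model$weights)
  per_el_sel <- apply(sel, 3, any)
  list(electrodes = which(per_el_sel),
       weight_magnitude = apply(abs(model$weights), 3, mean),
       max_t = apply(abs(tv), 3, max, na.rm = TRUE),
       selected = sel)
}

#' Reconstruction accuracy as a function of electrode count
#'
#' For each subset size, draws random electrode subsets, runs Monte Carlo
#' cross-validation on each subset, and averages accuracy over draws. On
#' populations with informative electrodes the curve is expected to be
#' non-decreasing in subset size.
#'
#' @param stim,resp,plan,hyper,trial_index as in [run_monte_carlo_cv].
#' @param subset_sizes electrode counts to evaluate.
#' @param n_draws random subsets per size.
#' @param seed integer seed for subset draws.
#' @return data frame: `n_electrodes`, `mean_r`, `se_r`.
#' @export
electrode_count_curve <- function(stim, resp, plan = list(),
                                  subset_sizes, n_draws = 3, seed = 1,
                                  hyper = fit_config(), trial_index = NULL) {
  R <- if (inherits(resp, "neural_response")) resp$values else as.matrix(resp)
  if (is.null(trial_index) && inherits(resp, "neural_response"))
    trial_index <- resp$trial_index
  N <- ncol(R)
  if (any(subset_sizes > N))
    stop_invalid_config("subset size exceeds electrode count")
  res <- lapply(subset_sizes, function(sz) {
    rs <- with_seed(derive_seed(seed, paste0("subset", sz)), {
      vapply(seq_len(if (sz == N) 1 else n_draws), function(d) {
        keep <- sort(sample.int(N, sz))
        cv <- run_monte_carlo_cv(stim, R[, keep, drop = FALSE], plan, hyper,
                                 trial_index)
        cv$report$mean_r
      }, numeric(1))
    })
    c(mean_r = fisher_mean(rs), se_r = if (length(rs) > 1) sd(rs) else NA_real_)
  })
  data.frame(n_electrodes = subset_sizes, do.call(rbind, res))
}
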