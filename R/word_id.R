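#' Word set container
#'
#' A labeled candidate set of word spectrograms sharing one frequency axis.
#'
#' @param labels unique character labels.
#' @param spectrograms list of [auditory_spectrogram]s.
#' @return object of class `word_set`.
#' @export
word_set <- function(labels, spectrograms) {
  if (length(labels) != length(spectrograms))
    stop_invalid_input("labels/spectrograms length mismatch")
  if (anyDuplicated(labels)) stop_invalid_input("labels must be unique")
  f0 <- spectrograms[[1]]$freq_hz
  ok <- vapply(spectrograms, function(s)
    isTRUE(all.equal(s$freq_hz, f0)), logical(1))
  if (!all(ok)) stop_invalid_input("all spectrograms must share a frequency axis")
  structure(list(labels = as.character(labels), spectrograms = spectrograms,
                 n = length(labels)),
            class = "word_set")
}

#' @export
print.word_set <- function(x, ...) {
  cat(sprintf("<word_set> %d words, %d frequency channels\n", x$n,
              length(x$spectrograms[[1]]$freq_hz)))
  invisible(x)
}

#' Smooth a spectrogram with a 2-D box filter
#'
#' Moving average over a window of `t_window` seconds by `f_window_oct`
#' octaves, with edge truncation (the window shrinks at the borders); the
#' shape is preserved. Identification performance is typically best after
#' smoothing with the default (500 ms, 2 octave) window.
#'
#' @param s an [auditory_spectrogram].
#' @param t_window temporal window in seconds (full width, 0.5).
#' @param f_window_oct spectral window in octaves (full width, 2).
#' @return smoothed [auditory_spectrogram].
#' @export
smooth_spectrogram <- function(s, t_window = 0.5, f_window_oct = 2) {
  if (t_window <= 0 || f_window_oct <= 0)
    stop_invalid_config("windows must be positive")
  v <- s$values
  ht <- floor(t_window * s$frame_rate_hz / 2)
  dx <- if (nrow(v) > 1) mean(diff(log2(s$freq_hz))) else 1
  hf <- floor(f_window_oct / dx / 2)
  if (2 * ht + 1 > 3 * ncol(v) && 2 * hf + 1 > 3 * nrow(v))
    stop_invalid_config("window far exceeds the spectrogram in both dimensions")
  n <- nrow(v); m <- ncol(v)
  # integral-image moving average with border truncation
  Iimg <- matrix(0, n + 1, m + 1)
  Iimg[-1, -1] <- if (n == 1) matrix(cumsum(v), 1)
                  else t(apply(apply(v, 2, cumsum), 1, cumsum))
  out <- matrix(0, n, m)
  for (i in seq_len(n)) {
    i0 <- max(1, i - hf); i1 <- min(n, i + hf)
    for (j in seq_len(m)) {
      j0 <- max(1, j - ht); j1 <- min(m, j + ht)
      tot <- Iimg[i1 + 1, j1 + 1] - Iimg[i0, j1 + 1] -
             Iimg[i1 + 1, j0] + Iimg[i0, j0]
      out[i, j] <- tot / ((i1 - i0 + 1) * (j1 - j0 + 1))
    }
  }
  auditory_spectrogram(pmax(out, 0), s$freq_hz, s$frame_rate_hz, s$compression)
}

# Local cost matrix for DTW: 1 - Pearson correlation between frequency
# columns; zero-variance frames get correlation 0 (cost 1).
dtw_cost_matrix <- function(A, B) {
  F_ <- nrow(A)
  za <- scale(A); zb <- scale(B)
  za[, attr(za, "scaled:scale") == 0] <- 0
  zb[, attr(zb, "scaled:scale") == 0] <- 0
  1 - crossprod(za, zb) / (F_ - 1)
}

#' Dynamic-time-warping similarity between two spectrograms
#'
#' Aligns the two frame sequences by DTW (local cost `1 - r` between
#' frequency columns; symmetric steps, no band constraint) and returns the
#' Pearson correlation between the aligned, vectorized spectrograms. The
#' score is symmetric up to tie-breaking in the alignment.
#'
#' @param a,b [auditory_spectrogram]s on the same frequency axis.
#' @return scalar similarity with attribute `path`.
#' @export
dtw_similarity <- function(a, b) {
  A <- a$values; B <- b$values
  if (ncol(A) == 0 || ncol(B) == 0) stop_invalid_input("empty spectrogram")
  if (nrow(A) != nrow(B)) stop_invalid_input("frequency axes differ")
  cost <- dtw_cost_matrix(A, B)
  al <- dtw_core(cost)
  sim <- safe_cor(A[, al$index1], B[, al$index2])
  if (is.na(sim)) sim <- 0
  attr(sim, "path") <- cbind(al$index1, al$index2)
  attr(sim, "distance") <- al$distance
  sim
}

#' Identification rank of a reconstruction within a candidate set
#'
#' Similarity of the reconstruction to every candidate is computed; the rank
#' is the proportion of incorrect candidates scoring strictly below the
#' correct word (ties count one half). 1 means the reconstruction matched the
#' correct word best of all candidates; 0 means the correct word scored
#' lowest; chance mean is 0.5.
#'
#' @param target_recon reconstructed [auditory_spectrogram].
#' @param truth_label correct label, present in `candidates`.
#' @param candidates a [word_set].
#' @param scores optional precomputed similarity scores to each candidate.
#' @return rank in `[0, 1]` with attribute `scores`.
#' @export
identification_rank <- function(target_recon, truth_label, candidates,
                                scores = NULL) {
  k <- match(truth_label, candidates$labels)
  if (is.na(k)) stop_invalid_input("label not in candidate set: ", truth_label)
  if (is.null(scores)) {
    scores <- vapply(candidates$spectrograms, function(w)
      as.numeric(dtw_similarity(target_recon, w)), numeric(1))
  }
  others <- scores[-k]
  rank <- (sum(others < scores[k]) + 0.5 * sum(others == scores[k])) /
    (candidates$n - 1)
  attr(rank, "scores") <- scores
  rank
}

#' Word identification analysis of a set of reconstructions
#'
#' Computes the identification rank of every reconstruction against the
#' candidate set (after 2-D box smoothing), the median rank, a randomization
#' p value (null distribution of the median from shuffling the
#' reconstruction-word pairing `n_shuffles` times; the p value is the
#' proportion of null medians at or above the true median), an ROC curve
#' over rank thresholds, and pairwise similarity matrices (actual-vs-actual
#' and reconstructed-vs-actual) computed prior to smoothing, with their
#' correlation over distinct word pairs.
#'
#' @param recons list of reconstructed [auditory_spectrogram]s, one per word.
#' @param truth_labels correct label for each reconstruction.
#' @param candidates a [word_set].
#' @param n_shuffles shuffles for the null (10,000).
#' @param seed integer seed for the shuffles.
#' @param smooth apply [smooth_spectrogram] before scoring (default TRUE).
#' @param t_window,f_window_oct smoothing window.
#' @param similarity_matrices also compute the pre-smoothing pairwise
#'   similarity matrices (TRUE).
#' @return list of class `identification_result`.
#' @export
identification_suite <- function(recons, truth_labels, candidates,
                                 n_shuffles = 10000, seed = 1, smooth = TRUE,
                                 t_window = 0.5, f_window_oct = 2,
                                 similarity_matrices = TRUE) {
  n <- length(recons)
  if (length(truth_labels) != n)
    stop_invalid_input("one label per reconstruction required")
  sm_rec <- if (smooth) lapply(recons, smooth_spectrogram, t_window,
                               f_window_oct) else recons
  sm_cand <- if (smooth) lapply(candidates$spectrograms, smooth_spectrogram,
                                t_window, f_window_oct)
             else candidates$spectrograms
  sim <- matrix(NA_real_, n, candidates$n,
                dimnames = list(truth_labels, candidates$labels))
  for (i in seq_len(n)) for (j in seq_len(candidates$n))
    sim[i, j] <- as.numeric(dtw_similarity(sm_rec[[i]], sm_cand[[j]]))
  rank_of <- function(i, k) {
    others <- sim[i, -k]
    (sum(others < sim[i, k]) + 0.5 * sum(others == sim[i, k])) /
      (candidates$n - 1)
  }
  truth_idx <- match(truth_labels, candidates$labels)
  if (anyNA(truth_idx)) stop_invalid_input("labels missing from candidate set")
  ranks <- vapply(seq_len(n), function(i) rank_of(i, truth_idx[i]), numeric(1))
  med <- median(ranks)
  null_medians <- with_seed(derive_seed(seed, "wordid_null"), {
    vapply(seq_len(n_shuffles), function(s) {
      perm <- sample.int(candidates$n)[seq_len(n)]
      median(vapply(seq_len(n), function(i) rank_of(i, perm[i]), numeric(1)))
    }, numeric(1))
  })
  p <- mean(null_medians >= med)
  th <- seq(0, 1, by = 0.02)
  roc <- data.frame(fpr = 1 - th,
                    tpr = vapply(th, function(x) mean(ranks >= x), numeric(1)))
  sim_actual <- sim_recon <- NULL
  sim_cor <- NA_real_
  if (similarity_matrices) {
    sim_actual <- matrix(NA_real_, candidates$n, candidates$n,
                         dimnames = list(candidates$labels, candidates$labels))
    for (i in seq_len(candidates$n)) for (j in i:candidates$n) {
      v <- as.numeric(dtw_similarity(candidates$spectrograms[[i]],
                                     candidates$spectrograms[[j]]))
      sim_actual[i, j] <- v; sim_actual[j, i] <- v
    }
    sim_recon <- matrix(NA_real_, n, candidates$n,
                        dimnames = list(truth_labels, candidates$labels))
    for (i in seq_len(n)) for (j in seq_len(candidates$n))
      sim_recon[i, j] <- as.numeric(dtw_similarity(recons[[i]],
                                                   candidates$spectrograms[[j]]))
    # distinct word pairs: reconstruction of word i vs actual word j, i != j
    mask <- outer(truth_idx, seq_len(candidates$n), `!=`)
    sim_cor <- safe_cor(sim_actual[truth_idx, ][mask], sim_recon[mask])
  }
  structure(list(ranks = ranks, median_rank = med, p_value = p,
                 null_medians = null_medians, roc = roc,
                 similarity_actual = sim_actual, similarity_recon = sim_recon,
                 similarity_correlation = sim_cor, scores = sim),
            class = "identification_result")
}

#' @export
print.identification_result <- function(x, ...) {
  cat(sprintf("<identification_result> median rank %.3f (p = %.4g, %d words)\n",
              x$median_rank, x$p_value, length(x$ranks)))
  invisible(x)
}
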