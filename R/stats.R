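#' Fisher z-averaged mean of correlation coefficients
#'
#' Correlations are averaged on the Fisher z scale (`atanh`) and transformed
#' back, which approximates additivity and a normal sampling distribution.
#' Values of exactly +/-1 are clipped just inside the open interval with a
#' warning; missing values are dropped.
#'
#' @param rs vector of correlation coefficients in `[-1, 1]`.
#' @return a scalar in `(-1, 1)`.
#' @export
fisher_mean <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) == 0) stop_invalid_input("no correlations to average")
  if (any(abs(rs) >= 1)) {
    warning("correlations of +/-1 clipped before Fisher transform")
    rs <- pmin(1 - 1e-12, pmax(-1 + 1e-12, rs))
  }
  tanh(mean(atanh(rs)))
}

#' Randomization test for reconstruction accuracy
#'
#' Builds a null distribution by shuffling the pairing between reconstructed
#' and original trials `n_shuffles` times and recomputing the statistic for
#' each shuffle. The p value is the proportion of null values greater than or
#' equal to the observed statistic (plug-in rule); the conservative
#' `(k+1)/(n+1)` variant is attached as an attribute.
#'
#' @param observed observed statistic (e.g. mean correlation with true
#'   pairing).
#' @param reconstructions,originals lists of equal length; element `i` of each
#'   is one trial's representation (numeric vector/matrix).
#' @param statistic function of (recon, orig) pairs returning the pooled
#'   scalar statistic; default mean Pearson correlation over trials (Fisher
#'   averaged).
#' @param n_shuffles number of shuffles (1,000 default).
#' @param seed integer seed.
#' @return p value with attributes `p_conservative` and `null` (the null
#'   distribution).
#' @export
randomization_test <- function(observed, reconstructions, originals,
                               statistic = NULL, n_shuffles = 1000, seed = 1) {
  n <- length(reconstructions)
  if (n < 2 || length(originals) != n)
    stop_invalid_input("need >= 2 paired trials")
  if (n_shuffles < 100)
    warning("fewer than 100 shuffles limits p-value resolution")
  if (is.null(statistic)) {
    statistic <- function(recons, origs) {
      fisher_mean(mapply(function(a, b) safe_cor(a, b), recons, origs))
    }
  }
  null <- with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      statistic(reconstructions[sample.int(n)], originals)
    }, numeric(1))
  })
  p <- mean(null >= observed)
  attr(p, "p_conservative") <- (sum(null >= observed) + 1) / (n_shuffles + 1)
  attr(p, "null") <- null
  p
}

#' Benjamini-Hochberg FDR selection
#'
#' Step-up selection controlling the false discovery rate at `alpha`.
#'
#' @param p_values vector of p values in `[0, 1]`.
#' @param alpha FDR level (0.05).
#' @return logical vector: TRUE where selected.
#' @export
fdr_select <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_invalid_input("p values must lie in [0, 1]")
  out <- p.adjust(p_values, method = "BH") <= alpha
  out[is.na(out)] <- FALSE
  out
}

#' Resampled parameter statistics
#'
#' The standard error of each parameter is the standard deviation (n-1
#' denominator) of its estimates across resamples, and significance is
#' screened by the t-ratio (mean / SE). Parameters with zero SE get an
#' undefined (NA) t-ratio.
#'
#' @param estimates matrix `[n_resamples x n_params]`.
#' @return list with vectors `mean`, `se`, `t_ratio` and scalar
#'   `n_resamples`.
#' @export
resample_stats <- function(estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) < 2)
    stop_invalid_input("need >= 2 resamples for resampled SE")
  m <- colMeans(estimates)
  se <- apply(estimates, 2, sd)
  t_ratio <- ifelse(se > 0, m / se, NA_real_)
  list(mean = m, se = se, t_ratio = t_ratio, n_resamples = nrow(estimates))
}

#' Bonferroni-adjusted significance threshold
#'
#' Simple `alpha / m` division for a family of `m` tests.
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return per-test threshold.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m) alpha / m

#' One-sample t test against zero on Fisher-z transformed correlations
#'
#' Thin wrapper used for group summaries of per-unit accuracies.
#'
#' @param rs correlations.
#' @return `htest` object from [stats::t.test] on `atanh(rs)`.
#' @export
fisher_t_test <- function(rs) stats::t.test(atanh(rs), mu = 0)
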