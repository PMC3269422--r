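#' @useDynLib speechdecode, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx cor fft median pt p.adjust quantile rnorm runif sd var
#' @importFrom utils head read.csv write.csv
NULL

stop_invalid_input <- function(...) {
  stop(structure(class = c("invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_invalid_config <- function(...) {
  stop(structure(class = c("invalid_config", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' Derive a child seed from a master seed and a tag
#'
#' All stochastic steps draw their seeds from a single master seed so a whole
#' analysis is reproducible from one integer. Derived seeds stay below 2^31.
#'
#' @param seed master seed (integer).
#' @param tag character tag naming the consumer.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 1103) %% (2^31 - 1))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals do not disturb the
#' caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Analytic signal via frequency-domain construction (positive frequencies
# doubled, negative zeroed). x may be a vector or a matrix (columns = signals).
analytic_signal <- function(x) {
  if (is.matrix(x)) return(apply(x, 2, analytic_signal))
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  fft(X * h, inverse = TRUE) / n
}

# Average x (vector or column-per-channel matrix at sample rate sr) into
# non-overlapping frames at frame_rate; returns matrix [n_frames x n_channels].
frame_average <- function(x, sr, frame_rate = 100) {
  if (!is.matrix(x)) x <- matrix(x, ncol = 1)
  hop <- sr / frame_rate
  n_frames <- floor(nrow(x) / hop)
  if (n_frames < 1) stop_invalid_input("signal shorter than one frame")
  idx <- floor((seq_len(nrow(x)) - 1) / hop) + 1
  keep <- idx <= n_frames
  unname(rowsum(x[keep, , drop = FALSE], idx[keep]) /
           as.vector(table(idx[keep])))
}

# Pearson correlation that tolerates zero-variance inputs (returns NA).
safe_cor <- function(a, b) {
  a <- as.vector(a); b <- as.vector(b)
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# z-score columns of a matrix; constant columns become all zeros.
zscore_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  s <- apply(x, 2, sd)
  s[s == 0] <- 1
  sweep(sweep(x, 2, mu), 2, s, "/")
}
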