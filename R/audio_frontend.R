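#' Waveform container
#'
#' A mono audio waveform with its sample rate. All frontend analyses start
#' from this object.
#'
#' @param samples numeric vector of finite samples.
#' @param sample_rate_hz sampling rate in Hz (16,000 typical for speech).
#' @return an object of class `waveform`.
#' @export
waveform <- function(samples, sample_rate_hz) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop_invalid_input("empty waveform")
  if (!all(is.finite(samples))) stop_invalid_input("waveform contains non-finite samples")
  structure(list(samples = samples, sample_rate_hz = sample_rate_hz),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %g Hz (%.3f s)\n",
              length(x$samples), x$sample_rate_hz,
              length(x$samples) / x$sample_rate_hz))
  invisible(x)
}

#' Read a mono PCM WAV file
#'
#' Minimal reader for 16-bit (and 32-bit float) PCM WAV. Stereo files are
#' averaged to mono; files not at `target_rate` are linearly resampled with a
#' warning.
#'
#' @param path file path.
#' @param target_rate resample target in Hz (default 16,000).
#' @return a [waveform].
#' @export
read_wav <- function(path, target_rate = 16000) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop_invalid_input("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1, 4)                    # chunk size
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop_invalid_input("not a WAVE file: ", path)
  fmt <- NULL; dat <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4)
    if (id == "fmt ") {
      fmt <- list(
        audio_format = readBin(con, "integer", 1, 2, signed = FALSE),
        n_channels   = readBin(con, "integer", 1, 2, signed = FALSE),
        sample_rate  = readBin(con, "integer", 1, 4),
        byte_rate    = readBin(con, "integer", 1, 4),
        block_align  = readBin(con, "integer", 1, 2, signed = FALSE),
        bits         = readBin(con, "integer", 1, 2, signed = FALSE))
      extra <- sz - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (id == "data") {
      dat <- readBin(con, "raw", sz)
      if (sz %% 2 == 1) readBin(con, "raw", 1)
    } else {
      readBin(con, "raw", sz + sz %% 2)
    }
    if (!is.null(fmt) && !is.null(dat)) break
  }
  if (is.null(fmt) || is.null(dat)) stop_invalid_input("malformed WAV: ", path)
  if (fmt$audio_format == 1 && fmt$bits == 16) {
    x <- readBin(dat, "integer", length(dat) / 2, 2, signed = TRUE) / 32768
  } else if (fmt$audio_format == 3 && fmt$bits == 32) {
    x <- readBin(dat, "double", length(dat) / 4, 4)
  } else {
    stop_invalid_input("unsupported WAV encoding (format ", fmt$audio_format,
                       ", ", fmt$bits, " bit)")
  }
  if (fmt$n_channels > 1)
    x <- rowMeans(matrix(x, ncol = fmt$n_channels, byrow = TRUE))
  if (fmt$sample_rate != target_rate) {
    warning(sprintf("resampling %g Hz -> %g Hz", fmt$sample_rate, target_rate))
    n_out <- round(length(x) * target_rate / fmt$sample_rate)
    x <- approx(seq_along(x), x, xout = seq(1, length(x), length.out = n_out))$y
  }
  waveform(x, target_rate)
}

#' Write a waveform to 16-bit PCM WAV
#'
#' @param w a [waveform]; samples are clipped to `[-1, 1]`.
#' @param path output path.
#' @export
write_wav <- function(w, path) {
  x <- pmin(1, pmax(-1, w$samples))
  pcm <- as.integer(round(x * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  n_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + n_bytes), con, 4)
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4)
  writeBin(as.integer(c(1, 1)), con, 2)            # PCM, mono
  writeBin(as.integer(w$sample_rate_hz), con, 4)
  writeBin(as.integer(w$sample_rate_hz * 2), con, 4)
  writeBin(as.integer(c(2, 16)), con, 2)
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(n_bytes), con, 4)
  writeBin(pcm, con, 2)
  invisible(path)
}

#' Auditory spectrogram container
#'
#' Log-frequency, envelope-compressed time-frequency representation with
#' frames at `frame_rate_hz`. Values are nonnegative with floor 0 (no dB
#' conversion in the analysis path).
#'
#' @param values nonnegative matrix `[n_freq x n_frames]`.
#' @param freq_hz ascending log-spaced channel center frequencies (Hz).
#' @param frame_rate_hz frame rate (100 after alignment).
#' @param compression compression applied to the envelope (`"cuberoot"` or
#'   `"none"`); recorded so inversions can undo it.
#' @return an object of class `auditory_spectrogram`.
#' @export
auditory_spectrogram <- function(values, freq_hz, frame_rate_hz,
                                 compression = "cuberoot") {
  values <- as.matrix(values)
  if (nrow(values) != length(freq_hz))
    stop_invalid_input("values/freq_hz dimension mismatch")
  if (any(values < 0)) stop_invalid_input("spectrogram values must be >= 0")
  if (length(freq_hz) > 1) {
    if (any(diff(freq_hz) <= 0))
      stop_invalid_input("freq_hz must be strictly increasing")
    lr <- diff(log(freq_hz))
    if (max(abs(lr - mean(lr))) > 1e-6 * mean(lr))
      stop_invalid_input("freq_hz must be log-spaced")
  }
  structure(list(values = values, freq_hz = as.numeric(freq_hz),
                 frame_rate_hz = frame_rate_hz, compression = compression),
            class = "auditory_spectrogram")
}

#' @export
print.auditory_spectrogram <- function(x, ...) {
  cat(sprintf("<auditory_spectrogram> %d freq x %d frames @ %g Hz, %g-%g Hz\n",
              nrow(x$values), ncol(x$values), x$frame_rate_hz,
              min(x$freq_hz), max(x$freq_hz)))
  invisible(x)
}

# One-sided (analytic) constant-Q transfer functions for the cochlear
# filterbank, evaluated on the n FFT bins of a signal at rate sr.
# Returns matrix [n x n_channels]; Gaussian on the log2-frequency axis with
# FWHM = bandwidth_oct octaves.
cochlear_transfer <- function(n, sr, freq_hz, bandwidth_oct = 1 / 12) {
  f <- (seq_len(n) - 1) * sr / n
  pos <- f > 0 & f <= sr / 2
  sigma <- bandwidth_oct / (2 * sqrt(2 * log(2)))
  H <- matrix(0, n, length(freq_hz))
  lf <- log2(f[pos])
  for (k in seq_along(freq_hz)) {
    H[pos, k] <- 2 * exp(-0.5 * ((lf - log2(freq_hz[k])) / sigma)^2)
  }
  H
}

#' Compute the auditory spectrogram of a waveform
#'
#' A bank of constant-Q bandpass filters (Gaussian on the log-frequency axis,
#' ~1/12 octave bandwidth) with log-spaced center frequencies models the
#' frequency analysis of the auditory periphery. The per-channel Hilbert
#' envelope is amplitude-compressed (cube root by default) and averaged into
#' frames at `frame_rate`.
#'
#' @param w a [waveform].
#' @param n_channels number of filterbank channels (128 native).
#' @param fmin,fmax frequency range in Hz (180-7,000).
#' @param frame_rate output frame rate in Hz (100).
#' @param bandwidth_oct filter FWHM in octaves.
#' @param compression `"cuberoot"` (default) or `"none"`.
#' @return an [auditory_spectrogram] `[n_channels x n_frames]`.
#' @export
compute_auditory_spectrogram <- function(w, n_channels = 128, fmin = 180,
                                         fmax = 7000, frame_rate = 100,
                                         bandwidth_oct = 1 / 12,
                                         compression = c("cuberoot", "none")) {
  compression <- match.arg(compression)
  if (!inherits(w, "waveform")) stop_invalid_input("w must be a waveform")
  if (fmax >= w$sample_rate_hz / 2)
    stop_invalid_config("fmax must be below the Nyquist frequency")
  x <- w$samples
  n <- length(x)
  freq_hz <- exp(seq(log(fmin), log(fmax), length.out = n_channels))
  H <- cochlear_transfer(n, w$sample_rate_hz, freq_hz, bandwidth_oct)
  X <- fft(x)
  env <- matrix(0, n, n_channels)
  for (k in seq_len(n_channels)) {
    env[, k] <- Mod(fft(X * H[, k], inverse = TRUE) / n)
  }
  if (compression == "cuberoot") env <- env^(1 / 3)
  vals <- t(frame_average(env, w$sample_rate_hz, frame_rate))
  auditory_spectrogram(vals, freq_hz, frame_rate, compression)
}

#' Downsample a spectrogram by averaging adjacent frequency channels
#'
#' Non-overlapping groups of `n_freq / n_out` adjacent channels are replaced
#' by their arithmetic mean; group center frequencies are geometric means, so
#' the log spacing and frequency range are preserved.
#'
#' @param s an [auditory_spectrogram].
#' @param n_out output channel count; must divide `n_freq`.
#' @return an [auditory_spectrogram] with `n_out` channels.
#' @export
downsample_spectrogram <- function(s, n_out = 32) {
  n_freq <- nrow(s$values)
  if (n_freq %% n_out != 0)
    stop_invalid_config("n_freq (", n_freq, ") not divisible by n_out (", n_out, ")")
  g <- n_freq / n_out
  grp <- rep(seq_len(n_out), each = g)
  vals <- unname(rowsum(s$values, grp)) / g
  freq <- exp(as.vector(rowsum(log(s$freq_hz), grp)) / g)
  auditory_spectrogram(vals, freq, s$frame_rate_hz, s$compression)
}

# ---------------------------------------------------------------------------
# Modulation filterbank
# ---------------------------------------------------------------------------

# Analytic transfer function of a causal temporal modulation filter at `rate`
# Hz, on `nt` FFT bins at `frame_rate`. The kernel is a gamma-windowed complex
# sinusoid, h(t) = (r t)^2 exp(-3.5 r t) exp(i 2 pi r t), peak gain 1.
mod_temporal_transfer <- function(nt, frame_rate, rate) {
  t <- (seq_len(nt) - 1) / frame_rate
  h <- (rate * t)^2 * exp(-3.5 * rate * t) * exp(2i * pi * rate * t)
  H <- fft(h)
  H[1] <- 0                       # exactly zero DC gain: a static spectrogram
  H / max(Mod(H))                 # carries no temporal modulation energy
}

# Spectral (scale) transfer function at `scale` cyc/oct on `nf` FFT bins of a
# log-frequency axis with channel spacing dx octaves. Gaussian-derivative
# magnitude profile (omega/s)^2 exp(1 - (omega/s)^2), one-sided: sign = +1
# keeps positive spectral frequencies, -1 the mirrored negative ones.
mod_spectral_transfer <- function(nf, dx, scale, sign = 1) {
  j <- seq_len(nf) - 1
  omega <- ifelse(j <= nf / 2, j, j - nf) / (nf * dx)   # cyc/oct per bin
  H <- numeric(nf)
  side <- if (sign > 0) omega > 0 else omega < 0
  a <- abs(omega[side]) / scale
  H[side] <- a^2 * exp(1 - a^2)
  H
}

# Complex modulation filterbank outputs of a spectrogram value matrix
# [n_freq x n_frames]. Returns list of complex [n_freq x n_frames] matrices
# indexed by (scale, signed rate), plus the padded transfer functions
# (needed for inversion).
mod_analyze <- function(vals, freq_hz, frame_rate, rates, scales,
                        return_transfer = FALSE) {
  F_ <- nrow(vals); T_ <- ncol(vals)
  dx <- mean(diff(log2(freq_hz)))
  nf <- 2 * F_
  nt <- stats::nextn(T_ + 2 * frame_rate, 2)
  S <- matrix(0, nf, nt)
  # modulation filters are zero-DC bandpass: analyze envelope fluctuations
  # around each channel's mean, so the static level cannot leak through the
  # filters' low-frequency skirts
  S[1:F_, 1:T_] <- vals - rowMeans(vals)
  Z <- fft(S)
  signed_rates <- c(-rev(rates), rates)
  Hr <- lapply(rates, function(r) mod_temporal_transfer(nt, frame_rate, r))
  Hs_pos <- lapply(scales, function(s) mod_spectral_transfer(nf, dx, s, +1))
  Hs_neg <- lapply(scales, function(s) mod_spectral_transfer(nf, dx, s, -1))
  out <- vector("list", length(scales) * length(signed_rates))
  dim(out) <- c(length(scales), length(signed_rates))
  transfer <- if (return_transfer) out else NULL
  for (si in seq_along(scales)) {
    for (ri in seq_along(signed_rates)) {
      r <- signed_rates[ri]
      hr <- Hr[[match(abs(r), rates)]]
      # positive (downward-sweep) rates pair positive temporal frequency with
      # positive spectral frequency; negative (upward) with negative.
      hs <- if (r > 0) Hs_pos[[si]] else Hs_neg[[si]]
      filt <- outer(hs, hr)
      y <- fft(Z * filt, inverse = TRUE) / (nf * nt)
      out[[si, ri]] <- y[1:F_, 1:T_, drop = FALSE]
      if (return_transfer) transfer[[si, ri]] <- filt
    }
  }
  list(out = out, transfer = transfer, signed_rates = signed_rates,
       nf = nf, nt = nt, dx = dx)
}

#' Modulation representation container
#'
#' Nonnegative modulation energy of a spectrogram: the magnitude of a bank of
#' causal 2-D spectro-temporal filters spanning spectral scales (cyc/oct) and
#' signed temporal rates (Hz). Negative rates denote upward frequency sweeps,
#' positive rates downward sweeps.
#'
#' @param values nonnegative array; `[n_scale, n_rate, n_freq, n_frames]` for
#'   the full form, `[n_scale, n_rate, n_frames]` for `rate_scale`,
#'   `[n_rate, n_frames]` for `rate_only`.
#' @param scales_cyc_per_oct spectral scales.
#' @param rates_hz signed rates (full / rate_scale) or unsigned (rate_only).
#' @param freq_hz channel center frequencies (full form only).
#' @param frame_rate_hz frame rate.
#' @param reduced_form one of `"full"`, `"rate_scale"`, `"rate_only"`.
#' @return an object of class `modulation_representation`.
#' @export
modulation_representation <- function(values, scales_cyc_per_oct, rates_hz,
                                      freq_hz = NULL, frame_rate_hz = 100,
                                      reduced_form = "full") {
  if (any(values < -1e-12)) stop_invalid_input("modulation energy must be >= 0")
  structure(list(values = values, scales_cyc_per_oct = scales_cyc_per_oct,
                 rates_hz = rates_hz, freq_hz = freq_hz,
                 frame_rate_hz = frame_rate_hz, reduced_form = reduced_form),
            class = "modulation_representation")
}

#' @export
print.modulation_representation <- function(x, ...) {
  cat(sprintf("<modulation_representation> form=%s, %s channels x %d frames\n",
              x$reduced_form,
              paste(head(dim(x$values), -1), collapse = "x"),
              tail(dim(x$values), 1)))
  invisible(x)
}

#' Compute the modulation-energy representation of a spectrogram
#'
#' The spectrogram is analyzed by a bank of causal modulation-selective
#' filters (quadrature spectro-temporal kernels implemented in the 2-D Fourier
#' domain); the magnitude of the complex output is the modulation energy.
#' Reduced forms lower dimensionality: `rate_scale` averages the complex
#' output over frequency before the magnitude operation (60 channels at
#' defaults); `rate_only` filters the frequency-averaged envelope with pure
#' temporal filters, which are not directional, so rates are unsigned (6
#' channels).
#'
#' @param s an [auditory_spectrogram] (32 channels for pipeline use).
#' @param rates unsigned temporal rates in Hz; realized as +/- pairs except in
#'   `rate_only`.
#' @param scales spectral scales in cyc/oct.
#' @param reduced_form `"full"`, `"rate_scale"` or `"rate_only"`.
#' @return a [modulation_representation].
#' @export
compute_modulation_representation <- function(s, rates = c(1, 2, 4, 8, 16, 32),
                                              scales = c(0.5, 1, 2, 4, 8),
                                              reduced_form = c("full", "rate_scale", "rate_only")) {
  reduced_form <- tryCatch(match.arg(reduced_form),
                           error = function(e) stop_invalid_config(
                             "unknown reduced_form: ", reduced_form[1]))
  vals <- s$values
  if (reduced_form == "rate_only") {
    a <- colMeans(vals)
    a <- a - mean(a)
    nt <- stats::nextn(length(a) + 2 * s$frame_rate_hz, 2)
    A <- fft(c(a, numeric(nt - length(a))))
    out <- matrix(0, length(rates), length(a))
    for (ri in seq_along(rates)) {
      Hr <- mod_temporal_transfer(nt, s$frame_rate_hz, rates[ri])
      y <- fft(A * Hr, inverse = TRUE) / nt
      out[ri, ] <- Mod(y[seq_along(a)])
    }
    return(modulation_representation(out, scales, rates, NULL,
                                     s$frame_rate_hz, "rate_only"))
  }
  if (nrow(vals) < 2)
    stop_invalid_input("full/rate_scale forms need >= 2 frequency channels")
  an <- mod_analyze(vals, s$freq_hz, s$frame_rate_hz, rates, scales)
  ns <- length(scales); nr <- length(an$signed_rates)
  if (reduced_form == "rate_scale") {
    out <- array(0, c(ns, nr, ncol(vals)))
    for (si in seq_len(ns)) for (ri in seq_len(nr))
      out[si, ri, ] <- Mod(colMeans(an$out[[si, ri]]))
    return(modulation_representation(out, scales, an$signed_rates, NULL,
                                     s$frame_rate_hz, "rate_scale"))
  }
  out <- array(0, c(ns, nr, nrow(vals), ncol(vals)))
  for (si in seq_len(ns)) for (ri in seq_len(nr))
    out[si, ri, , ] <- Mod(an$out[[si, ri]])
  modulation_representation(out, scales, an$signed_rates, s$freq_hz,
                            s$frame_rate_hz, "full")
}

#' Flatten a representation to a frames-by-channels matrix
#'
#' Decoding targets are matrices with one column per stimulus channel. The
#' full modulation form flattens to `n_freq * n_rate * n_scale` columns (1,920
#' at pipeline defaults), `rate_scale` to 60, `rate_only` to 6; a spectrogram
#' flattens to its frequency channels.
#'
#' @param x an [auditory_spectrogram] or [modulation_representation].
#' @return numeric matrix `[n_frames x n_channels]` with a
#'   `channel_info` attribute describing each column.
#' @export
flatten_channels <- function(x) {
  if (inherits(x, "auditory_spectrogram")) {
    m <- t(x$values)
    attr(m, "channel_info") <- data.frame(freq_hz = x$freq_hz)
    return(m)
  }
  if (!inherits(x, "modulation_representation"))
    stop_invalid_input("cannot flatten object of class ", class(x)[1])
  v <- x$values
  d <- dim(v)
  nfr <- d[length(d)]
  m <- t(matrix(v, ncol = nfr))
  info <- switch(x$reduced_form,
    full = expand.grid(scale = x$scales_cyc_per_oct, rate_hz = x$rates_hz,
                       freq_hz = x$freq_hz),
    rate_scale = expand.grid(scale = x$scales_cyc_per_oct, rate_hz = x$rates_hz),
    rate_only = data.frame(rate_hz = x$rates_hz))
  attr(m, "channel_info") <- info
  m
}

#' Invert a magnitude-only modulation representation to a spectrogram
#'
#' Iterative projection (Griffin-Lim style) in the modulation domain: starting
#' from random phases, alternate between substituting the known channel
#' magnitudes and resynthesizing a nonnegative spectrogram through the
#' (overcomplete) filterbank inverse. The returned spectrogram is the mean of
#' the converged estimates over `n_init` random initializations. Magnitude-only
#' recovery is approximate even for the representation of the original
#' stimulus.
#'
#' @param m a full-form [modulation_representation].
#' @param n_init number of random initializations (100 default).
#' @param seed integer seed; output is deterministic given the seed.
#' @param max_iter iteration cap per initialization.
#' @param tol stop when the successive-iterate correlation changes by less
#'   than this.
#' @return an [auditory_spectrogram].
#' @export
invert_modulation_to_spectrogram <- function(m, n_init = 100, seed = 1,
                                             max_iter = 200, tol = 1e-4) {
  if (!inherits(m, "modulation_representation") || m$reduced_form != "full")
    stop_invalid_input("m must be a full-form modulation representation")
  ns <- dim(m$values)[1]; nr <- dim(m$values)[2]
  F_ <- dim(m$values)[3]; T_ <- dim(m$values)[4]
  rates <- sort(unique(abs(m$rates_hz)))
  an <- mod_analyze(matrix(0, F_, T_), m$freq_hz, m$frame_rate_hz,
                    rates, m$scales_cyc_per_oct, return_transfer = TRUE)
  stopifnot(identical(an$signed_rates, m$rates_hz))
  nf <- an$nf; nt <- an$nt
  K <- ns * nr
  transfer <- an$transfer
  # least-squares synthesis for a real image from one-sided (analytic)
  # channels needs the Hermitian-symmetrized coverage in the denominator
  D <- matrix(0, nf, nt)
  for (k in seq_len(K)) D <- D + Mod(transfer[[k]])^2
  Dsym <- D + D[c(1, nf:2), c(1, nt:2)]
  Dsym <- Dsym + 1e-4 * max(Dsym)
  mag <- vector("list", K)
  for (k in seq_len(K)) mag[[k]] <- matrix(m$values[((k - 1) %% ns) + 1,
                                                    ((k - 1) %/% ns) + 1, , ],
                                           F_, T_)
  if (max(m$values) == 0) {
    return(auditory_spectrogram(matrix(0, F_, T_), m$freq_hz,
                                m$frame_rate_hz, "cuberoot"))
  }
  sd0 <- sd(Reduce(`+`, mag))
  synth <- function(chan) {
    acc <- matrix(0 + 0i, nf, nt)
    for (k in seq_len(K)) acc <- acc + Conj(transfer[[k]]) * fft(chan[[k]])
    (2 * Re(fft(acc / Dsym, inverse = TRUE) / (nf * nt)))[1:F_, 1:T_]
  }
  result <- with_seed(seed, {
    total <- matrix(0, F_, T_)
    ref <- NULL
    for (init in seq_len(n_init)) {
      # iterate on the mean-centered image; channel magnitudes are blind to
      # per-channel means (the filters are zero-DC), so means are restored
      # only at the end, from the envelope floor
      Sc <- matrix(rnorm(F_ * T_), F_, T_) * sd0
      prev_cor <- -Inf
      converged <- FALSE
      for (it in seq_len(max_iter)) {
        full <- matrix(0, nf, nt)
        full[1:F_, 1:T_] <- Sc
        Z <- fft(full)
        chan <- vector("list", K)
        for (k in seq_len(K)) {
          y <- fft(Z * transfer[[k]], inverse = TRUE) / (nf * nt)
          ys <- y[1:F_, 1:T_]
          a <- Mod(ys)
          ph <- ifelse(a > 1e-12, ys / a, 1 + 0i)
          # substitute magnitudes on the signal support only; the padding
          # region keeps the causal filter tails and stays unconstrained
          y[1:F_, 1:T_] <- mag[[k]] * ph
          chan[[k]] <- y
        }
        S_new <- synth(chan)
        cc <- safe_cor(S_new, Sc)
        Sc <- S_new
        if (!is.na(cc) && is.finite(prev_cor) && abs(cc - prev_cor) < tol) {
          converged <- TRUE
          break
        }
        prev_cor <- cc
      }
      if (!converged)
        warning("iterative projection did not converge; returning best iterate")
      # magnitudes cannot distinguish Sc from -Sc; envelope fluctuations are
      # positively skewed (bursts above a floor), which resolves each
      # initialization's sign before averaging
      if (mean((Sc - mean(Sc))^3) < 0) Sc <- -Sc
      total <- total + Sc
    }
    total <- total / n_init
    total <- total - apply(total, 1, min)    # restore per-channel floor at 0
    total
  })
  auditory_spectrogram(result, m$freq_hz, m$frame_rate_hz, "cuberoot")
}

#' Invert a spectrogram to a waveform by iterative phase estimation
#'
#' The spectrogram is magnitude-only, so the waveform phase is estimated by
#' iterative projection (Griffin-Lim): alternate between imposing the target
#' per-channel envelopes on the analytic subband signals of the current
#' estimate and resynthesizing through the filterbank inverse.
#'
#' @param s an [auditory_spectrogram].
#' @param n_iter number of projection iterations.
#' @param seed integer seed for the random initial waveform.
#' @param sample_rate_hz output sample rate (Hz).
#' @param bandwidth_oct filterbank bandwidth, matching the analysis.
#' @return a [waveform]; re-analysis of it approximates `s`.
#' @export
invert_spectrogram_to_waveform <- function(s, n_iter = 30, seed = 1,
                                           sample_rate_hz = 16000,
                                           bandwidth_oct = 1 / 12) {
  E_fr <- s$values
  if (identical(s$compression, "cuberoot")) E_fr <- E_fr^3
  F_ <- nrow(E_fr); T_ <- ncol(E_fr)
  n <- round(T_ * sample_rate_hz / s$frame_rate_hz)
  ft <- ((seq_len(T_) - 0.5) / s$frame_rate_hz)        # frame midpoints (s)
  tt <- (seq_len(n) - 0.5) / sample_rate_hz
  E <- matrix(0, n, F_)
  for (k in seq_len(F_))
    E[, k] <- approx(ft, E_fr[k, ], xout = tt, rule = 2)$y
  H <- cochlear_transfer(n, sample_rate_hz, s$freq_hz, bandwidth_oct)
  D <- rowSums(Mod(H)^2)
  D <- D + 1e-3 * max(D)
  with_seed(seed, {
    x <- rnorm(n, sd = max(E) + 1e-12)
    for (it in seq_len(n_iter)) {
      X <- fft(x)
      acc <- complex(length.out = n)
      for (k in seq_len(F_)) {
        z <- fft(X * H[, k], inverse = TRUE) / n
        a <- Mod(z)
        ph <- ifelse(a > 1e-12, z / a, 1 + 0i)
        acc <- acc + Conj(H[, k]) * fft(E[, k] * ph)
      }
      x <- Re(fft(acc / D, inverse = TRUE) / n)
    }
    w <- waveform(x, sample_rate_hz)
    w
  })
}
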