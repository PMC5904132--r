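# Internal helpers: seeded RNG scopes, zero-phase filters, FFT band power.

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a base seed and a stream index, staying in 32-bit
# integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103L + 7919L * as.numeric(k)) %% 2147483629)
}

# Evaluate a digital filter's frequency response at radian frequencies w.
freqResponseAt <- function(flt, w) {
  num <- exp(-1i * outer(w, seq_along(flt$b) - 1)) %*% flt$b
  den <- exp(-1i * outer(w, seq_along(flt$a) - 1)) %*% flt$a
  as.vector(num / den)
}

# Zero-phase Butterworth gain at the DFT bin frequencies of an n-sample
# signal: the squared magnitude response of the design (the gain a
# forward-backward pass realizes), as a length-n vector symmetric in the
# folded frequency so spectral application keeps real signals real.
# `low` (2nd order high-pass) and/or `high` (4th order low-pass) may be NA;
# `band` gives a 4th-order band-pass instead.
butterZeroPhaseGain <- function(n, sfreq, low = NA, high = NA, band = NULL,
                                order = 4L) {
  nyq <- sfreq / 2
  freqs <- (seq_len(n) - 1) * sfreq / n
  fold <- pmin(freqs, sfreq - freqs)
  w <- 2 * pi * fold / sfreq
  g <- rep(1, n)
  if (!is.null(band)) {
    flt <- signal::butter(order, band / nyq, type = "pass")
    return(Mod(freqResponseAt(flt, w))^2)
  }
  if (!is.na(low)) {
    flt <- signal::butter(2L, low / nyq, type = "high")
    g <- g * Mod(freqResponseAt(flt, w))^2
  }
  if (!is.na(high)) {
    stopifnot(high < nyq)
    flt <- signal::butter(order, high / nyq, type = "low")
    g <- g * Mod(freqResponseAt(flt, w))^2
  }
  g
}

# Apply a per-bin spectral gain to every trial/channel of a trials x
# channels x samples array (zero-phase by construction).
applySpectralGain <- function(a, gain) {
  d <- dim(a)
  out <- a
  for (tr in seq_len(d[1L])) {
    X <- t(a[tr, , , drop = TRUE])
    if (d[2L] == 1L) X <- matrix(a[tr, 1L, ], ncol = 1L)
    F <- stats::mvfft(X) * gain
    out[tr, , ] <- t(Re(stats::mvfft(F, inverse = TRUE)) / d[3L])
  }
  out
}

# Power (sum of squared DFT-bin amplitudes, Parseval-scaled to time-domain
# sum of squares) of `x` inside [low, high) Hz. Half-open bins make adjacent
# bands partition the spectrum exactly.
fftBandPower <- function(x, sfreq, low, high, rightClosed = FALSE) {
  n <- length(x)
  sp <- abs(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * sfreq / n
  # fold to one-sided frequencies
  fold <- pmin(freqs, sfreq - freqs)
  inBand <- if (rightClosed) fold >= low & fold <= high
            else fold >= low & fold < high
  sum(sp[inBand])
}

# Gaussian white noise restricted to [low, high) Hz by an ideal (brick-wall)
# zero-phase spectral mask; real-valued because the mask is symmetric in the
# folded frequency.
bandLimitedNoise <- function(nSamples, sfreq, low, high) {
  z <- stats::fft(stats::rnorm(nSamples))
  freqs <- (seq_len(nSamples) - 1) * sfreq / nSamples
  fold <- pmin(freqs, sfreq - freqs)
  z[!(fold >= low & fold < high)] <- 0
  Re(stats::fft(z, inverse = TRUE)) / nSamples
}

# Canonical EEG rhythm bands used throughout the package (Hz).
rhythmBands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30))
}

#' Construct an EpochSet
#'
#' @param data trials x channels x samples numeric array (microvolts).
#' @param sfreq sampling rate in Hz.
#' @param labels per-trial class labels, coerced to a factor with levels
#'   \code{error}, \code{correct}.
#' @param rt per-trial reaction times in ms (defaults to NA).
#' @param channelNames optional channel names.
#' @param window epoch window (start, end) in seconds.
#' @return An [EpochSet-class].
#' @export
epochSet <- function(data, sfreq, labels, rt = rep(NA_real_, dim(data)[1L]),
                     channelNames = NULL, window = c(0, dim(data)[3L] / sfreq)) {
  if (is.null(channelNames))
    channelNames <- sprintf("ch%02d", seq_len(dim(data)[2L]))
  labels <- factor(as.character(labels), levels = c("error", "correct"))
  new("EpochSet", data = data, sfreq = sfreq, labels = labels,
      rt = as.numeric(rt), channelNames = channelNames, window = window)
}

# Rebuild an EpochSet keeping a subset of trials (order preserved).
subsetTrials <- function(epochs, keep) {
  new("EpochSet",
      data = epochs@data[keep, , , drop = FALSE],
      sfreq = epochs@sfreq,
      labels = droplevels0(epochs@labels[keep]),
      rt = epochs@rt[keep],
      channelNames = epochs@channelNames,
      window = epochs@window)
}

# Keep the error/correct levels even if one class vanishes.
droplevels0 <- function(f) factor(as.character(f), levels = c("error", "correct"))
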