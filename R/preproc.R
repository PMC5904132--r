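#' Epoch a continuous multichannel recording
#'
#' Cuts fixed-length windows around event samples from a continuous
#' channels x samples recording (e.g. 200 ms pre- to 4500 ms post-stimulus,
#' or the 0-700 ms post-offset analysis window).
#'
#' @param recording channels x samples numeric matrix (microvolts).
#' @param sfreq sampling rate, Hz.
#' @param events integer sample indices of the alignment events.
#' @param tmin,tmax window edges in seconds relative to each event
#'   (\code{tmin} may be negative for a pre-event segment).
#' @param labels,rt optional per-event metadata.
#' @return An [EpochSet-class]; events whose window falls outside the
#'   recording are dropped with a warning.
#' @export
epochContinuous <- function(recording, sfreq, events, tmin = 0, tmax = 0.7,
                            labels = rep("error", length(events)),
                            rt = rep(NA_real_, length(events))) {
  recording <- as.matrix(recording)
  stopifnot(tmax > tmin, length(labels) == length(events))
  i0 <- round(events + tmin * sfreq)
  i1 <- round(events + tmax * sfreq) - 1L
  ok <- i0 >= 1L & i1 <= ncol(recording)
  if (!all(ok)) {
    warning(sprintf("epochContinuous: dropped %d event(s) outside the recording",
                    sum(!ok)))
    events <- events[ok]; labels <- labels[ok]; rt <- rt[ok]
    i0 <- i0[ok]; i1 <- i1[ok]
  }
  if (!length(events)) stop("epochContinuous: no events inside the recording")
  nS <- i1[1L] - i0[1L] + 1L
  a <- array(0, c(length(events), nrow(recording), nS))
  for (k in seq_along(events))
    a[k, , ] <- recording[, i0[k]:(i0[k] + nS - 1L)]
  epochSet(a, sfreq, labels, rt = rt, window = c(tmin, tmax))
}

#' Reject trials exceeding an amplitude criterion
#'
#' Removes every trial whose absolute amplitude exceeds \code{threshold}
#' microvolts on any channel at any sample (the +/-75 uV transient-artifact
#' criterion by default). Surviving trials keep their original order and
#' their labels / reaction times.
#'
#' @param epochs an [EpochSet-class].
#' @param threshold rejection threshold in microvolts (> 0; \code{Inf} keeps
#'   everything).
#' @return The cleaned [EpochSet-class]; the integer indices of rejected
#'   trials are attached as attribute \code{"rejected"}.
#' @export
rejectArtifactTrials <- function(epochs, threshold = 75) {
  stopifnot(is(epochs, "EpochSet"), threshold >= 0)
  peak <- apply(abs(epochs@data), 1L, max)
  keep <- which(peak <= threshold)
  if (!length(keep))
    stop("rejectArtifactTrials: all trials exceed the amplitude criterion")
  out <- subsetTrials(epochs, keep)
  attr(out, "rejected") <- setdiff(seq_len(nTrials(epochs)), keep)
  out
}

#' Band-pass filter epochs
#'
#' Zero-phase Butterworth filtering of every channel of every trial,
#' 0.1-30 Hz by default. The squared magnitude response of the design (a
#' 2nd-order high-pass at the low edge cascaded with a 4th-order low-pass at
#' the high edge -- the gain a forward-backward pass realizes) is applied
#' spectrally, which is exactly zero-phase and free of edge transients.
#'
#' @param epochs an [EpochSet-class].
#' @param low,high band edges in Hz, \code{0 < low < high < sfreq/2}.
#' @return Filtered [EpochSet-class].
#' @export
bandpassEpochs <- function(epochs, low = 0.1, high = 30) {
  stopifnot(is(epochs, "EpochSet"))
  if (!(low > 0 && low < high)) stop("bandpassEpochs: need 0 < low < high")
  if (high >= epochs@sfreq / 2)
    stop("bandpassEpochs: high edge must be below Nyquist")
  out <- epochs
  g <- butterZeroPhaseGain(dim(epochs@data)[3L], epochs@sfreq,
                           low = low, high = high)
  out@data <- applySpectralGain(epochs@data, g)
  out
}

#' Re-reference epochs
#'
#' \code{method = "average"}: subtracts the instantaneous channel mean
#' (per-sample column means become 0; idempotent).
#' \code{method = "rest"}: reference electrode standardization technique --
#' the data are first average-referenced, sources are estimated through the
#' Moore-Penrose pseudoinverse of the average-referenced leadfield, and the
#' scalp potentials are rebuilt against the original (infinity-referenced)
#' leadfield, approximating a reference at infinity.
#'
#' @param epochs an [EpochSet-class].
#' @param method \code{"average"} or \code{"rest"}.
#' @param leadfield a [Leadfield-class]; required for \code{"rest"} and
#'   assumed to be computed against a reference at infinity.
#' @return Re-referenced [EpochSet-class].
#' @export
rereference <- function(epochs, method = c("average", "rest"), leadfield = NULL) {
  stopifnot(is(epochs, "EpochSet"))
  method <- match.arg(method)
  out <- epochs
  nT <- nTrials(epochs)
  if (method == "average") {
    for (tr in seq_len(nT)) {
      x <- epochs@data[tr, , ]
      out@data[tr, , ] <- sweep(x, 2L, colMeans(x), "-")
    }
    return(out)
  }
  if (is.null(leadfield))
    stop("rereference: method = 'rest' requires a leadfield")
  A <- leadfield@gain
  if (nrow(A) != nChannels(epochs))
    stop("rereference: leadfield channel count does not match the epochs")
  n <- nrow(A)
  H <- diag(n) - matrix(1 / n, n, n)      # average-reference operator
  Tmat <- A %*% MASS::ginv(H %*% A)       # REST transform: avg-ref -> infinity
  for (tr in seq_len(nT))
    out@data[tr, , ] <- Tmat %*% (H %*% epochs@data[tr, , ])
  out
}

#' Decompose epochs into theta / alpha / beta bands
#'
#' Produces three band-limited copies of the input (theta 4-8, alpha 8-13,
#' beta 13-30 Hz) using zero-phase 4th-order Butterworth band-pass filters
#' (squared magnitude response applied spectrally).
#'
#' @param epochs an [EpochSet-class] with sampling rate >= 64 Hz.
#' @return Named list of three [EpochSet-class] objects
#'   (\code{theta}, \code{alpha}, \code{beta}).
#' @export
extractBands <- function(epochs) {
  stopifnot(is(epochs, "EpochSet"))
  if (epochs@sfreq < 64)
    stop("extractBands: sampling rate must be at least 64 Hz")
  bands <- rhythmBands()
  nS <- dim(epochs@data)[3L]
  out <- lapply(names(bands), function(nm) {
    e <- epochs
    g <- butterZeroPhaseGain(nS, epochs@sfreq, band = bands[[nm]])
    e@data <- applySpectralGain(epochs@data, g)
    e
  })
  names(out) <- names(bands)
  out
}
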