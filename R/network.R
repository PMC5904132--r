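#' Region-averaged node time series
#'
#' Builds network node series by averaging the dipole waveforms of each
#' region of a (typically trial-averaged) source matrix.
#'
#' @param sources dipoles x samples matrix of cortical activity, or a
#'   single-trial [SourceSet-class].
#' @param regions named list of non-empty, disjoint dipole index vectors.
#' @return nodes x samples matrix with one row per region.
#' @export
regionTimeSeries <- function(sources, regions) {
  if (is(sources, "SourceSet")) {
    stopifnot(nTrials(sources) == 1L)
    sources <- sources@data[1L, , ]
  }
  sources <- as.matrix(sources)
  if (!length(regions) || any(!vapply(regions, length, integer(1L))))
    stop("regionTimeSeries: regions must be non-empty")
  if (anyDuplicated(unlist(regions)))
    stop("regionTimeSeries: regions must be disjoint")
  out <- t(vapply(regions, function(idx)
    colMeans(sources[idx, , drop = FALSE]), numeric(ncol(sources))))
  rownames(out) <- if (is.null(names(regions)))
    sprintf("node%d", seq_along(regions)) else names(regions)
  out
}

#' Kalman-filter fit of a time-varying VAR (MVAAR)
#'
#' Tracks the coefficients of \code{X(t) = sum_k w(k, t) X(t-k) + eps(t)}
#' with a Kalman filter whose adaptation speed is set by the update
#' coefficient \code{uc}. On a time-invariant stable VAR the time-averaged
#' coefficients after burn-in approach the generating values.
#'
#' @param X nodes x time numeric matrix.
#' @param p model order (>= 1); series length must be at least
#'   \code{10 * p * nodes}.
#' @param uc Kalman update coefficient in (0, 1); default \code{1e-3}.
#' @param sfreq sampling rate of the series (Hz); default 250.
#' @return An [MVAARFit-class]; \code{coefArray(fit)[i, j, k, t]} is the
#'   influence of node j at lag k on node i at time t.
#' @export
fitMvaarKalman <- function(X, p, uc = 1e-3, sfreq = 250) {
  X <- as.matrix(X)
  if (any(!is.finite(X))) stop("fitMvaarKalman: input must be finite")
  n <- nrow(X); T <- ncol(X)
  stopifnot(p >= 1L, uc > 0, uc < 1)
  if (T < 10 * p * n)
    stop("fitMvaarKalman: series too short (need >= 10 * p * nodes samples)")
  fit <- cpp_kalman_mvaar(X, as.integer(p), uc)
  co <- array(fit$coeffs, c(n, n * p, T))
  coeffs <- array(0, c(n, n, p, T))
  for (k in seq_len(p))
    coeffs[, , k, ] <- co[, (k - 1L) * n + seq_len(n), , drop = FALSE]
  nodeNames <- rownames(X)
  if (is.null(nodeNames)) nodeNames <- sprintf("node%d", seq_len(n))
  new("MVAARFit", coeffs = coeffs, order = as.integer(p), uc = uc,
      residuals = fit$residuals, nodeNames = nodeNames, sfreq = sfreq)
}

#' VAR model-order selection by the Schwarz Bayesian criterion
#'
#' Fits stationary VAR models of order 1..pMax by least squares on a common
#' sample and returns the order minimizing
#' \code{log det(Sigma_hat) + log(N) * p * n^2 / N}.
#'
#' @param X nodes x time matrix.
#' @param pMax largest candidate order.
#' @return Integer order in \code{[1, pMax]}.
#' @export
selectOrderSbc <- function(X, pMax) {
  X <- as.matrix(X)
  n <- nrow(X); T <- ncol(X)
  stopifnot(pMax >= 1L)
  N <- T - pMax
  if (N <= n * pMax + 1L)
    stop("selectOrderSbc: series too short for pMax")
  Y <- t(X[, (pMax + 1L):T, drop = FALSE])          # N x n responses
  sbc <- vapply(seq_len(pMax), function(p) {
    Z <- do.call(cbind, lapply(seq_len(p), function(k)
      t(X[, (pMax + 1L - k):(T - k), drop = FALSE])))
    B <- qr.solve(Z, Y)
    E <- Y - Z %*% B
    Sigma <- crossprod(E) / N
    determinant(Sigma, logarithm = TRUE)$modulus + log(N) * p * n^2 / N
  }, numeric(1L))
  which.min(sbc)
}

#' Time-varying spectral transfer function
#'
#' Computes \code{H(f, t) = A(f, t)^-1} with
#' \code{A(f, t) = I - sum_k w_k(t) exp(-i 2 pi f k / sfreq)} (the identity
#' lag-0 convention, so zero coupling gives \code{H = I}).
#'
#' @param fit an [MVAARFit-class].
#' @param freqs frequency grid in Hz; default 1 Hz spacing from 1 to Nyquist.
#' @return Complex array nodes x nodes x frequencies x time, with the grid
#'   attached as attribute \code{"freqs"}.
#' @export
transferFunction <- function(fit, freqs = NULL) {
  stopifnot(is(fit, "MVAARFit"))
  if (is.null(freqs)) freqs <- seq(1, floor(fit@sfreq / 2))
  d <- dim(fit@coeffs)
  co <- array(fit@coeffs, c(d[1L], d[2L] * d[3L], d[4L]))
  H <- cpp_transfer_function(co, fit@order, freqs, fit@sfreq)
  dim(H) <- c(d[1L], d[1L], length(freqs), d[4L])
  attr(H, "freqs") <- freqs
  H
}

#' Normalized ADTF
#'
#' \code{iota2[i, j, f, t] = |H_ij|^2 / sum_k |H_ik|^2}: for each receiving
#' node i, frequency and time, the values over senders j sum to 1.
#'
#' @param H complex transfer-function array (nodes x nodes x freqs x time),
#'   e.g. from [transferFunction()].
#' @return Numeric array of the same shape with values in \[0, 1\].
#' @export
adtfNormalize <- function(H) {
  H2 <- Mod(H)^2
  d <- dim(H2)
  denom <- apply(H2, c(1L, 3L, 4L), sum)
  if (any(denom <= 0))
    stop("adtfNormalize: zero denominator row in the transfer function")
  out <- H2
  for (j in seq_len(d[2L]))
    out[, j, , ] <- H2[, j, , , drop = FALSE] / array(denom, c(d[1L], 1L, d[3L], d[4L]))
  fr <- attr(H, "freqs")
  if (!is.null(fr)) attr(out, "freqs") <- fr
  out
}

#' Band-integrated ADTF
#'
#' Per edge and time point, the mean of the normalized ADTF over the
#' frequency bins inside \code{[f1, f2]} (4-30 Hz by default, the union of
#' the theta, alpha and beta bands).
#'
#' @param iota2 normalized ADTF array (nodes x nodes x freqs x time).
#' @param freqs frequency grid matching dim 3 (taken from the
#'   \code{"freqs"} attribute when missing).
#' @param f1,f2 integration band edges in Hz.
#' @return Numeric array nodes x nodes x time with values in \[0, 1\].
#' @export
integrateAdtf <- function(iota2, freqs = attr(iota2, "freqs"), f1 = 4, f2 = 30) {
  if (is.null(freqs)) stop("integrateAdtf: frequency grid required")
  sel <- which(freqs >= f1 & freqs <= f2)
  if (!length(sel)) stop("integrateAdtf: no frequency bins inside the band")
  apply(iota2[, , sel, , drop = FALSE], c(1L, 2L, 4L), mean)
}

# Fused coefficient -> band-integrated ADTF path (identical to
# transferFunction |> adtfNormalize |> integrateAdtf, computed in C++).
integratedAdtfFromFit <- function(fit, freqs = NULL, band = c(4, 30)) {
  if (is.null(freqs)) freqs <- seq(1, floor(fit@sfreq / 2))
  inBand <- freqs[freqs >= band[1L] & freqs <= band[2L]]
  if (!length(inBand)) stop("no frequency bins inside the band")
  d <- dim(fit@coeffs)
  co <- array(fit@coeffs, c(d[1L], d[2L] * d[3L], d[4L]))
  cpp_adtf_integrated(co, fit@order, inBand, fit@sfreq)
}

#' Phase-randomized surrogate of node time series
#'
#' Independently per node, randomizes the phases of the Fourier coefficients
#' under Hermitian symmetry (real output), exactly preserving each node's
#' amplitude spectrum while destroying cross-node phase relations.
#'
#' @param X nodes x time matrix.
#' @param seed RNG seed.
#' @return Surrogate matrix of the same shape.
#' @export
phaseRandomize <- function(X, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); T <- ncol(X)
  withSeed(seed, {
    out <- X
    half <- floor((T - 1) / 2)
    for (i in seq_len(n)) {
      Xf <- stats::fft(X[i, ])
      if (half >= 1L) {
        ph <- stats::runif(half, 0, 2 * pi)
        idx <- 2L:(half + 1L)
        Xf[idx] <- Mod(Xf[idx]) * exp(1i * ph)
        Xf[T + 2L - idx] <- Conj(Xf[idx])
      }
      out[i, ] <- Re(stats::fft(Xf, inverse = TRUE)) / T
    }
    out
  })
}

#' Surrogate null distribution for the integrated ADTF
#'
#' Runs the full connectivity pipeline (Kalman MVAAR fit, transfer function,
#' normalized ADTF, band integration) on \code{nSurrogates} phase-randomized
#' copies of the node series and pools the surrogate values per directed edge
#' across retained (post burn-in) time points into an empirical null, with
#' per-edge 95th-percentile thresholds.
#'
#' @param X nodes x time matrix.
#' @param p VAR order.
#' @param nSurrogates number of phase-randomized shuffles (default 200).
#' @param seed RNG seed.
#' @param uc Kalman update coefficient.
#' @param sfreq sampling rate (Hz).
#' @param band integration band (Hz).
#' @param burnIn time points excluded from the null
#'   (default \code{max(50, 5 * p)}).
#' @param prob threshold percentile (default 0.95).
#' @param perTimePoint if TRUE, thresholds are computed per (edge, time)
#'   across surrogates instead of pooled over time.
#' @return List with \code{thresholds} (nodes x nodes, NA diagonal; a
#'   nodes x nodes x time array in per-time-point mode), \code{null}
#'   (matrix of pooled null draws, one column per directed edge j->i,
#'   NULL in per-time-point mode) and the parameters used.
#' @export
surrogateNull <- function(X, p, nSurrogates = 200L, seed = 1L, uc = 1e-3,
                          sfreq = 250, band = c(4, 30),
                          burnIn = max(50L, 5L * p), prob = 0.95,
                          perTimePoint = FALSE) {
  X <- as.matrix(X)
  stopifnot(nSurrogates >= 1L)
  n <- nrow(X); T <- ncol(X)
  if (T <= burnIn + 10L) stop("surrogateNull: series too short for burn-in")
  keep <- (burnIn + 1L):T
  nK <- length(keep)
  vals <- array(NA_real_, c(n, n, nK, nSurrogates))
  for (s in seq_len(nSurrogates)) {
    Xs <- phaseRandomize(X, seed = childSeed(seed, s))
    fitS <- fitMvaarKalman(Xs, p = p, uc = uc, sfreq = sfreq)
    vals[, , , s] <- integratedAdtfFromFit(fitS, band = band)[, , keep]
  }
  if (perTimePoint) {
    thresholds <- apply(vals, c(1L, 2L, 3L), stats::quantile, probs = prob)
    for (i in seq_len(n)) thresholds[i, i, ] <- NA_real_
    return(list(thresholds = thresholds, null = NULL, prob = prob,
                burnIn = burnIn, perTimePoint = TRUE))
  }
  thresholds <- matrix(NA_real_, n, n)
  nullMat <- matrix(NA_real_, nK * nSurrogates, n * n)
  edgeNames <- character(n * n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    col <- (j - 1L) * n + i
    edgeNames[col] <- sprintf("%d->%d", j, i)
    if (i == j) next
    draws <- as.vector(vals[i, j, , ])
    nullMat[, col] <- draws
    thresholds[i, j] <- stats::quantile(draws, probs = prob, names = FALSE)
  }
  colnames(nullMat) <- edgeNames
  list(thresholds = thresholds, null = nullMat, prob = prob,
       burnIn = burnIn, perTimePoint = FALSE)
}

#' Time-varying directed network from node time series
#'
#' End-to-end connectivity analysis: VAR order selection (SBC) unless an
#' order is given, Kalman MVAAR fit, band-integrated normalized ADTF, and
#' optional phase-randomization surrogate significance testing.
#'
#' @param X nodes x time matrix of node series.
#' @param sfreq sampling rate (Hz).
#' @param p VAR order; selected by [selectOrderSbc()] (pMax = 5) when NULL.
#' @param uc Kalman update coefficient (default 1e-3).
#' @param band integration band in Hz (default c(4, 30)).
#' @param nSurrogates phase-randomized surrogates for significance; 0 skips
#'   surrogate testing.
#' @param seed RNG seed for the surrogates.
#' @param burnIn Kalman burn-in excluded from significance summaries.
#' @return A [TVNetwork-class].
#' @export
computeTvNetwork <- function(X, sfreq = 250, p = NULL, uc = 1e-3,
                             band = c(4, 30), nSurrogates = 0L, seed = 1L,
                             burnIn = NULL) {
  X <- as.matrix(X)
  if (is.null(p)) p <- selectOrderSbc(X, pMax = 5L)
  if (is.null(burnIn)) burnIn <- max(50L, 5L * p)
  fit <- fitMvaarKalman(X, p = p, uc = uc, sfreq = sfreq)
  freqs <- seq(1, floor(sfreq / 2))
  integ <- integratedAdtfFromFit(fit, freqs = freqs, band = band)
  n <- nrow(X); T <- ncol(X)
  thresholds <- matrix(numeric(0), 0L, 0L)
  signif <- array(logical(0), c(0L, 0L, 0L))
  if (nSurrogates > 0L) {
    nullRes <- surrogateNull(X, p = p, nSurrogates = nSurrogates, seed = seed,
                             uc = uc, sfreq = sfreq, band = band,
                             burnIn = burnIn)
    thresholds <- nullRes$thresholds
    signif <- array(FALSE, dim(integ))
    keep <- (burnIn + 1L):T
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i == j) next
      signif[i, j, keep] <- integ[i, j, keep] > thresholds[i, j]
    }
  }
  nodeNames <- rownames(X)
  if (is.null(nodeNames)) nodeNames <- sprintf("node%d", seq_len(n))
  new("TVNetwork", integrated = integ, band = band, freqs = freqs,
      nodeNames = nodeNames, sfreq = sfreq, burnIn = as.integer(burnIn),
      nullThresholds = thresholds, significant = signif)
}

#' Net (pure) information flow between two directions
#'
#' Difference of the two directed integrated-ADTF values; the sign gives the
#' dominant direction: \code{netFlow(x, y) = x - y} is positive when the
#' first direction carries more flow. Antisymmetric by construction.
#'
#' @param forward,backward integrated ADTF values (scalars or aligned
#'   vectors) for the two directions of an edge.
#' @return Signed difference.
#' @export
netFlow <- function(forward, backward) forward - backward
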