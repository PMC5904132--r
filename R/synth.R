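#' Synthetic EEG generator with known ground truth
#'
#' The generator emulates the statistical structure the downstream pipeline is
#' designed to detect: two trial classes (error / correct) whose active
#' cortical dipoles differ in their theta/alpha/beta band-power proportions
#' (hence in rhythm entropy), volume conduction through a known linear
#' leadfield, additive white sensor noise at a configured SNR, and per-class
#' reaction times with the error mean above the correct mean.
#'
#' @param nChannels,nDipoles geometry (dipoles >= channels).
#' @param sfreq sampling rate, Hz.
#' @param epochLen epoch length in seconds (default 0.7, the post-offset
#'   analysis window).
#' @param nTrialsPerClass trials per class (default 20, the minimum error-trial
#'   count the pipeline assumes for training).
#' @param activeDipoles indices of dipoles carrying the class contrast.
#' @param bandPropsError,bandPropsCorrect theta/alpha/beta power proportions
#'   per class; each must be nonnegative and sum to 1.
#' @param sensorSnr scalp signal power divided by sensor noise power.
#' @param backgroundLevel inactive-dipole broadband amplitude relative to the
#'   active-dipole amplitude (default 0.1).
#' @param rtModel list with elements \code{error} and \code{correct}, each
#'   \code{c(mean, sd)} in ms; reaction times are drawn truncated at 100 ms.
#' @param seed integer RNG seed; identical configs give bit-identical datasets.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nChannels = 48L, nDipoles = 64L, sfreq = 250,
                      epochLen = 0.7, nTrialsPerClass = 20L,
                      activeDipoles = c(10L, 32L, 54L),
                      bandPropsError = c(0.8, 0.1, 0.1),
                      bandPropsCorrect = c(1, 1, 1) / 3,
                      sensorSnr = 10, backgroundLevel = 0.1,
                      rtModel = list(error = c(650, 120), correct = c(500, 100)),
                      seed = 1L) {
  new("SimConfig",
      nChannels = as.integer(nChannels), nDipoles = as.integer(nDipoles),
      sfreq = sfreq, epochLen = epochLen,
      nTrialsPerClass = as.integer(nTrialsPerClass),
      activeDipoles = as.integer(activeDipoles),
      bandPropsError = bandPropsError, bandPropsCorrect = bandPropsCorrect,
      sensorSnr = sensorSnr, backgroundLevel = backgroundLevel,
      rtModel = rtModel, seed = as.integer(seed))
}

#' Generate a synthetic leadfield
#'
#' Draws a random mixing matrix with spatially correlated rows (nearby
#' channels see similar mixtures, as volume conduction implies) and
#' independent unit-norm columns, so that distinct dipoles have distinct gain
#' patterns and the inverse problem is well posed. The matrix is guaranteed
#' full row rank; a rank-deficient draw is regenerated (up to 10 retries).
#'
#' @param nChannels number of channels (>= 2).
#' @param nDipoles number of dipoles (>= nChannels).
#' @param seed RNG seed; fixed seed gives a bit-identical matrix.
#' @param smoothness channel-axis correlation length as a fraction of the
#'   channel array extent (default 0.1).
#' @return A [Leadfield-class] with unit-norm columns.
#' @export
makeLeadfield <- function(nChannels, nDipoles, seed = 1L, smoothness = 0.1) {
  stopifnot(nChannels >= 2L, nDipoles >= nChannels)
  withSeed(seed, {
    for (try in seq_len(10L)) {
      pos <- seq(0, 1, length.out = nChannels)
      # smooth (channel-correlated) component plus an equal-weight independent
      # component: rows are spatially correlated while the matrix stays well
      # conditioned and columns remain distinct
      K <- exp(-outer(pos, pos, "-")^2 / (2 * smoothness^2)) + diag(nChannels)
      G <- K %*% matrix(stats::rnorm(nChannels * nDipoles), nChannels, nDipoles)
      G <- sweep(G, 2L, sqrt(colSums(G^2)), "/")
      if (qr(G)$rank == nChannels) {
        return(new("Leadfield", gain = G,
                   channelNames = sprintf("ch%02d", seq_len(nChannels)),
                   dipoleNames = sprintf("dip%03d", seq_len(nDipoles))))
      }
    }
    stop("makeLeadfield: could not draw a full-row-rank gain matrix in 10 tries")
  })
}

#' Simulate a band-structured source signal
#'
#' Produces a single source time course as the sum of three band-limited
#' noise components (theta 4-8, alpha 8-13, beta 13-30 Hz), each obtained by
#' zero-phase band-limiting of white noise (ideal spectral mask) and
#' rescaling so its sum of squares equals \code{props[i] * totalPower}; the
#' empirical band powers therefore match the requested proportions exactly
#' up to floating point.
#'
#' @param props theta/alpha/beta power proportions (nonnegative, sum 1).
#' @param totalPower target sum of squared amplitudes over the segment.
#' @param nSamples number of samples (at least two theta cycles, sfreq / 2).
#' @param sfreq sampling rate, Hz.
#' @param seed RNG seed.
#' @return Numeric vector of length \code{nSamples}.
#' @export
simulateBandSource <- function(props, totalPower, nSamples, sfreq, seed = 1L) {
  if (any(props < 0)) stop("simulateBandSource: props must be nonnegative")
  if (abs(sum(props) - 1) > 1e-12) stop("simulateBandSource: props must sum to 1")
  if (nSamples < sfreq / 2)
    stop("simulateBandSource: need at least two theta cycles (sfreq/2 samples)")
  bands <- rhythmBands()
  withSeed(seed, {
    x <- numeric(nSamples)
    for (i in seq_along(bands)) {
      if (props[i] <= 0) next
      comp <- bandLimitedNoise(nSamples, sfreq, bands[[i]][1L], bands[[i]][2L])
      pw <- sum(comp^2)
      if (pw <= 0) stop("simulateBandSource: degenerate filtered component")
      x <- x + comp * sqrt(props[i] * totalPower / pw)
    }
    x
  })
}

#' Simulate coupled node time series from a stable VAR
#'
#' Uses the multivariate autoregressive model generatively with time-constant
#' coefficients; the ground-truth directed edges are the nonzero off-diagonal
#' coefficient entries.
#'
#' @param coeffs nodes x nodes x order array; \code{coeffs[i, j, k]} is the
#'   influence of node j at lag k on node i.
#' @param nSamples number of retained samples.
#' @param noiseSd innovation standard deviation (default 1).
#' @param seed RNG seed.
#' @param burnIn discarded initial samples (default 200).
#' @return List with \code{series} (nodes x nSamples matrix) and
#'   \code{edges} (directed adjacency matrix, \code{edges[i, j] = 1} for a
#'   true influence j -> i).
#' @export
simulateMvarNodes <- function(coeffs, nSamples, noiseSd = 1, seed = 1L,
                              burnIn = 200L) {
  d <- dim(coeffs)
  if (length(d) == 2L) { coeffs <- array(coeffs, c(d, 1L)); d <- dim(coeffs) }
  stopifnot(length(d) == 3L, d[1L] == d[2L])
  n <- d[1L]; p <- d[3L]
  rho <- varSpectralRadius(coeffs)
  if (rho >= 1)
    stop(sprintf("simulateMvarNodes: unstable VAR (spectral radius %.4f >= 1)", rho))
  edges <- matrix(0, n, n)
  for (k in seq_len(p)) edges <- edges + (coeffs[, , k] != 0)
  edges <- (edges > 0) * 1; diag(edges) <- 0
  withSeed(seed, {
    total <- nSamples + burnIn
    X <- matrix(0, n, total)
    eps <- matrix(stats::rnorm(n * total, sd = noiseSd), n, total)
    for (t in seq_len(total)) {
      acc <- eps[, t]
      for (k in seq_len(min(p, t - 1L)))
        acc <- acc + coeffs[, , k] %*% X[, t - k]
      X[, t] <- acc
    }
    list(series = X[, burnIn + seq_len(nSamples), drop = FALSE], edges = edges)
  })
}

# Spectral radius of the VAR companion matrix.
varSpectralRadius <- function(coeffs) {
  n <- dim(coeffs)[1L]; p <- dim(coeffs)[3L]
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[seq_len(n), (k - 1L) * n + seq_len(n)] <- coeffs[, , k]
  if (p > 1L)
    comp[n + seq_len(n * (p - 1L)), seq_len(n * (p - 1L))] <-
      diag(n * (p - 1L))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Simulate a full synthetic dataset
#'
#' For each trial, active dipoles carry band-structured signals with the
#' class's configured theta/alpha/beta proportions; inactive dipoles carry
#' low-amplitude broadband (4-30 Hz) background. Scalp data are
#' \code{leadfield x sources} plus white sensor noise scaled so that the
#' dataset-wide scalp signal power over noise power equals \code{sensorSnr}.
#' Reaction times are drawn from the per-class truncated-normal model
#' (floor 100 ms).
#'
#' @param config a [SimConfig-class].
#' @param leadfield optional [Leadfield-class]; generated from the config seed
#'   when missing.
#' @return List with \code{epochs} ([EpochSet-class]), \code{truth}
#'   ([GroundTruth-class]) and \code{leadfield}.
#' @export
simulateDataset <- function(config, leadfield = NULL) {
  validObject(config)
  nSamples <- round(config@epochLen * config@sfreq)
  if (nSamples < config@sfreq / 2)
    stop("simulateDataset: epoch too short for the theta band (need >= 2 cycles)")
  if (is.null(leadfield))
    leadfield <- makeLeadfield(config@nChannels, config@nDipoles,
                               seed = childSeed(config@seed, 1L))
  A <- leadfield@gain
  nPerClass <- config@nTrialsPerClass
  nT <- 2L * nPerClass
  labels <- factor(rep(c("error", "correct"), each = nPerClass),
                   levels = c("error", "correct"))
  propsByClass <- list(error = config@bandPropsError,
                       correct = config@bandPropsCorrect)
  totalPower <- nSamples            # unit mean-square active sources
  bgPower <- config@backgroundLevel^2 * nSamples
  active <- config@activeDipoles
  inactive <- setdiff(seq_len(config@nDipoles), active)

  S <- array(0, c(nT, config@nDipoles, nSamples))
  scalp <- array(0, c(nT, config@nChannels, nSamples))
  for (tr in seq_len(nT)) {
    props <- propsByClass[[as.character(labels[tr])]]
    for (j in seq_along(active))
      S[tr, active[j], ] <- simulateBandSource(
        props, totalPower, nSamples, config@sfreq,
        seed = childSeed(config@seed, 100L + tr * 61L + j))
    if (length(inactive)) {
      bg <- withSeed(childSeed(config@seed, 5000L + tr), {
        t(vapply(seq_along(inactive), function(i)
          bandLimitedNoise(nSamples, config@sfreq, 4, 30),
          numeric(nSamples)))
      })
      bg <- bg * sqrt(bgPower / pmax(rowSums(bg^2), .Machine$double.eps))
      S[tr, inactive, ] <- bg
    }
    scalp[tr, , ] <- A %*% S[tr, , ]
  }
  sigPower <- mean(scalp^2)
  noiseSd <- sqrt(sigPower / config@sensorSnr)
  noise <- withSeed(childSeed(config@seed, 2L),
                    array(stats::rnorm(length(scalp), sd = noiseSd), dim(scalp)))
  scalp <- scalp + noise

  rt <- withSeed(childSeed(config@seed, 3L), {
    vapply(seq_len(nT), function(tr) {
      m <- config@rtModel[[as.character(labels[tr])]]
      max(100, stats::rnorm(1L, m[1L], m[2L]))
    }, numeric(1L))
  })

  epochs <- epochSet(scalp, config@sfreq, labels, rt = rt,
                     channelNames = leadfield@channelNames,
                     window = c(0, config@epochLen))
  truth <- new("GroundTruth",
               activeDipoles = active,
               classEntropy = c(error = rhythmEntropy(config@bandPropsError),
                                correct = rhythmEntropy(config@bandPropsCorrect)),
               couplingGraph = matrix(numeric(0), 0L, 0L),
               rt = rt)
  list(epochs = epochs, truth = truth, leadfield = leadfield)
}
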