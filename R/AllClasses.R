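#' @import methods
NULL

#' EpochSet: epoched multichannel scalp EEG
#'
#' Container for epoched EEG: a trials x channels x samples array in microvolts
#' together with the sampling rate, per-trial class labels (\code{"error"} /
#' \code{"correct"}), per-trial reaction times in milliseconds, channel names
#' and the epoch window relative to the alignment event.
#'
#' @slot data numeric array, trials x channels x samples (microvolts).
#' @slot sfreq sampling rate in Hz.
#' @slot labels factor of length trials with levels \code{error}, \code{correct}.
#' @slot rt numeric vector of per-trial reaction times (ms).
#' @slot channelNames character vector, one per channel.
#' @slot window numeric length-2, epoch start/end in seconds.
#'
#' @seealso [epochSet()] for the user-facing constructor.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(
    data = "array",
    sfreq = "numeric",
    labels = "factor",
    rt = "numeric",
    channelNames = "character",
    window = "numeric"
  )
)

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x channels x samples array")
  else {
    if (length(object@labels) != d[1L])
      msg <- c(msg, "labels length must equal the number of trials")
    if (length(object@rt) != d[1L])
      msg <- c(msg, "rt length must equal the number of trials")
    if (length(object@channelNames) != d[2L])
      msg <- c(msg, "channelNames length must equal the number of channels")
  }
  if (length(object@sfreq) != 1L || object@sfreq <= 60)
    msg <- c(msg, "sfreq must be a single value > 60 Hz (2 x 30 Hz band edge)")
  if (length(object@window) != 2L)
    msg <- c(msg, "window must have length 2")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "data must be finite (no NaN/Inf)")
  if (length(msg)) msg else TRUE
})

#' Leadfield: channels x dipoles forward gain matrix
#'
#' Linear forward operator mapping dipole amplitudes to scalp potentials.
#' Columns (dipole gain patterns) are unit-norm by construction in
#' [makeLeadfield()].
#'
#' @slot gain numeric matrix, channels x dipoles.
#' @slot channelNames,dipoleNames character vectors naming rows/columns.
#' @exportClass Leadfield
setClass("Leadfield",
  representation(
    gain = "matrix",
    channelNames = "character",
    dipoleNames = "character"
  )
)

setValidity("Leadfield", function(object) {
  msg <- character()
  if (!is.numeric(object@gain)) msg <- c(msg, "gain must be numeric")
  if (nrow(object@gain) < 2L) msg <- c(msg, "need at least 2 channels")
  if (ncol(object@gain) < nrow(object@gain))
    msg <- c(msg, "need at least as many dipoles as channels")
  if (length(object@channelNames) != nrow(object@gain))
    msg <- c(msg, "channelNames length must equal nrow(gain)")
  if (length(object@dipoleNames) != ncol(object@gain))
    msg <- c(msg, "dipoleNames length must equal ncol(gain)")
  if (length(msg)) msg else TRUE
})

#' InverseModel: weighted minimum-norm inverse operator
#'
#' Holds the gain matrix A, source covariance R, noise covariance C, the
#' assumed SNR, the regularization scalar lambda2 and the resulting linear
#' inverse operator W = R A' (A R A' + lambda2 C)^-1.
#'
#' @slot A channels x dipoles gain matrix.
#' @slot R dipoles x dipoles source covariance.
#' @slot C channels x channels noise covariance.
#' @slot snr assumed amplitude signal-to-noise ratio (dimensionless).
#' @slot lambda2 regularization scalar.
#' @slot W dipoles x channels inverse operator.
#' @exportClass InverseModel
setClass("InverseModel",
  representation(
    A = "matrix",
    R = "matrix",
    C = "matrix",
    snr = "numeric",
    lambda2 = "numeric",
    W = "matrix"
  )
)

setValidity("InverseModel", function(object) {
  msg <- character()
  if (!all(dim(object@W) == rev(dim(object@A))))
    msg <- c(msg, "W must have the transposed shape of A")
  if (!isTRUE(all.equal(object@R, t(object@R), tolerance = 1e-8)))
    msg <- c(msg, "R must be symmetric")
  if (!isTRUE(all.equal(object@C, t(object@C), tolerance = 1e-8)))
    msg <- c(msg, "C must be symmetric")
  if (object@lambda2 < 0) msg <- c(msg, "lambda2 must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SourceSet: estimated cortical activity per trial
#'
#' Trials x dipoles x samples array of source amplitudes for one frequency
#' band (or broadband), with the trial metadata carried along from the
#' originating [EpochSet-class].
#'
#' @slot data numeric array, trials x dipoles x samples.
#' @slot band one of \code{"theta"}, \code{"alpha"}, \code{"beta"},
#'   \code{"broadband"}.
#' @slot sfreq sampling rate (Hz).
#' @slot labels,rt per-trial metadata.
#' @exportClass SourceSet
setClass("SourceSet",
  representation(
    data = "array",
    band = "character",
    sfreq = "numeric",
    labels = "factor",
    rt = "numeric"
  )
)

setValidity("SourceSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L)
    msg <- c(msg, "data must be a trials x dipoles x samples array")
  else if (length(object@labels) != d[1L])
    msg <- c(msg, "labels length must equal the number of trials")
  if (!object@band %in% c("theta", "alpha", "beta", "broadband"))
    msg <- c(msg, "band must be theta, alpha, beta or broadband")
  if (length(msg)) msg else TRUE
})

#' FeatureTable: rhythm entropy per trial and dipole
#'
#' @slot values trials x dipoles matrix of rhythm entropies (bits).
#' @slot labels per-trial class factor.
#' @slot rt per-trial reaction times (ms).
#' @slot bandPowers trials x dipoles x 3 array of theta/alpha/beta powers
#'   (sum of squared amplitudes over the window).
#' @slot excluded integer indices (in the input trial order) of trials
#'   dropped as degenerate (all-zero band power at some dipole).
#' @exportClass FeatureTable
setClass("FeatureTable",
  representation(
    values = "matrix",
    labels = "factor",
    rt = "numeric",
    bandPowers = "array",
    excluded = "integer"
  )
)

setValidity("FeatureTable", function(object) {
  msg <- character()
  if (length(object@labels) != nrow(object@values))
    msg <- c(msg, "labels length must equal nrow(values)")
  if (length(object@rt) != nrow(object@values))
    msg <- c(msg, "rt length must equal nrow(values)")
  rng <- range(object@values)
  if (rng[1L] < -1e-9 || rng[2L] > log2(3) + 1e-9)
    msg <- c(msg, "entropy values must lie in [0, log2 3]")
  if (any(object@bandPowers < 0))
    msg <- c(msg, "band powers must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' R2Map: per-dipole discriminability and selection
#'
#' @slot r2 numeric vector of per-dipole R-squared discriminability values.
#' @slot thresholdFrac fraction of the maximum R-squared used as cut.
#' @slot selected integer indices of selected dipoles.
#' @slot projected full-dipole-space back-projected map (R-squared at
#'   selected dipoles, zero elsewhere).
#' @exportClass R2Map
setClass("R2Map",
  representation(
    r2 = "numeric",
    thresholdFrac = "numeric",
    selected = "integer",
    projected = "numeric"
  )
)

setValidity("R2Map", function(object) {
  msg <- character()
  if (any(object@r2 < 0)) msg <- c(msg, "r2 values must be nonnegative")
  if (length(object@projected) != length(object@r2))
    msg <- c(msg, "projected must have one value per dipole")
  if (length(object@selected) &&
      (min(object@selected) < 1L || max(object@selected) > length(object@r2)))
    msg <- c(msg, "selected indices out of range")
  if (length(msg)) msg else TRUE
})

#' EvalResult: LOOCV classification performance
#'
#' @slot ca,se,sp,auc accuracy, sensitivity, specificity, area under the ROC
#'   curve, all in \[0, 1\].
#' @slot confusion named integer vector (TP, TN, FP, FN).
#' @slot predictions data.frame with one row per held-out trial: truth,
#'   predicted label, decision score, penalty C chosen for that fold.
#' @slot seed integer seed used for fold-internal randomness.
#' @exportClass EvalResult
setClass("EvalResult",
  representation(
    ca = "numeric",
    se = "numeric",
    sp = "numeric",
    auc = "numeric",
    confusion = "integer",
    predictions = "data.frame",
    seed = "integer"
  )
)

setValidity("EvalResult", function(object) {
  msg <- character()
  cf <- object@confusion
  if (!all(c("TP", "TN", "FP", "FN") %in% names(cf)))
    msg <- c(msg, "confusion must have TP, TN, FP, FN")
  else {
    n <- sum(cf)
    if (n > 0 && abs(object@ca - (cf["TP"] + cf["TN"]) / n) > 1e-12)
      msg <- c(msg, "ca inconsistent with confusion counts")
    if (nrow(object@predictions) && n != nrow(object@predictions))
      msg <- c(msg, "confusion counts must sum to the number of predictions")
  }
  if (length(msg)) msg else TRUE
})

#' MVAARFit: Kalman-fitted time-varying VAR coefficients
#'
#' @slot coeffs array nodes x nodes x order x time; \code{coeffs[i, j, k, t]}
#'   is the influence of node j at lag k on node i at time t.
#' @slot order model order p.
#' @slot uc Kalman update coefficient.
#' @slot residuals nodes x time one-step prediction errors.
#' @slot nodeNames character vector.
#' @slot sfreq sampling rate of the node series (Hz).
#' @exportClass MVAARFit
setClass("MVAARFit",
  representation(
    coeffs = "array",
    order = "integer",
    uc = "numeric",
    residuals = "matrix",
    nodeNames = "character",
    sfreq = "numeric"
  )
)

setValidity("MVAARFit", function(object) {
  msg <- character()
  d <- dim(object@coeffs)
  if (length(d) != 4L || d[1L] != d[2L])
    msg <- c(msg, "coeffs must be nodes x nodes x order x time")
  else if (d[3L] != object@order)
    msg <- c(msg, "third dimension of coeffs must equal order")
  if (object@order < 1L) msg <- c(msg, "order must be >= 1")
  if (object@uc <= 0 || object@uc >= 1)
    msg <- c(msg, "uc must lie in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' TVNetwork: time-varying directed network (integrated ADTF)
#'
#' @slot integrated nodes x nodes x time array of band-integrated normalized
#'   ADTF values; entry \[i, j, t\] is the directed influence j -> i.
#' @slot band numeric length-2 integration band in Hz (default 4-30).
#' @slot freqs frequency grid used (Hz).
#' @slot nodeNames character vector.
#' @slot sfreq sampling rate (Hz).
#' @slot burnIn number of initial Kalman time points excluded from summaries.
#' @slot nullThresholds nodes x nodes matrix of per-edge surrogate 95th
#'   percentiles (NA diagonal), or a 0 x 0 matrix when no surrogates were run.
#' @slot significant logical array like \code{integrated}; TRUE where the
#'   observed value exceeds the edge's surrogate threshold.
#' @exportClass TVNetwork
setClass("TVNetwork",
  representation(
    integrated = "array",
    band = "numeric",
    freqs = "numeric",
    nodeNames = "character",
    sfreq = "numeric",
    burnIn = "integer",
    nullThresholds = "matrix",
    significant = "array"
  )
)

setValidity("TVNetwork", function(object) {
  msg <- character()
  d <- dim(object@integrated)
  if (length(d) != 3L || d[1L] != d[2L])
    msg <- c(msg, "integrated must be nodes x nodes x time")
  v <- object@integrated
  if (any(v < -1e-10 | v > 1 + 1e-10))
    msg <- c(msg, "integrated ADTF values must lie in [0, 1]")
  if (length(object@band) != 2L || object@band[1L] >= object@band[2L])
    msg <- c(msg, "band must be (f1, f2) with f1 < f2")
  if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic dataset configuration
#'
#' Describes the simulated study conditions: geometry (channels/dipoles),
#' timing (sampling rate, epoch length), design (trials per class, active
#' dipoles), the per-class theta/alpha/beta band-power proportions, the
#' sensor-level SNR, and the per-class reaction-time model.
#'
#' @slot nChannels,nDipoles geometry counts.
#' @slot sfreq sampling rate (Hz).
#' @slot epochLen epoch length (seconds).
#' @slot nTrialsPerClass trials per class.
#' @slot activeDipoles integer indices of dipoles carrying class structure.
#' @slot bandPropsError,bandPropsCorrect 3-vectors of theta/alpha/beta power
#'   proportions (each sums to 1).
#' @slot sensorSnr scalp signal power / sensor noise power.
#' @slot backgroundLevel amplitude of inactive-dipole broadband background,
#'   relative to active-dipole amplitude.
#' @slot rtModel named list with \code{error} and \code{correct}, each
#'   \code{c(mean, sd)} in ms.
#' @slot seed integer RNG seed.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nChannels = "integer",
    nDipoles = "integer",
    sfreq = "numeric",
    epochLen = "numeric",
    nTrialsPerClass = "integer",
    activeDipoles = "integer",
    bandPropsError = "numeric",
    bandPropsCorrect = "numeric",
    sensorSnr = "numeric",
    backgroundLevel = "numeric",
    rtModel = "list",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  for (nm in c("bandPropsError", "bandPropsCorrect")) {
    p <- slot(object, nm)
    if (length(p) != 3L || any(p < 0) || abs(sum(p) - 1) > 1e-12)
      msg <- c(msg, sprintf("%s must be a nonnegative 3-vector summing to 1", nm))
  }
  if (object@nTrialsPerClass < 1L)
    msg <- c(msg, "nTrialsPerClass must be >= 1")
  if (object@sfreq <= 60)
    msg <- c(msg, "sfreq must exceed 60 Hz so the 30 Hz beta edge is below Nyquist")
  if (length(object@activeDipoles) &&
      (min(object@activeDipoles) < 1L || max(object@activeDipoles) > object@nDipoles))
    msg <- c(msg, "activeDipoles out of range")
  if (object@nDipoles < object@nChannels)
    msg <- c(msg, "nDipoles must be >= nChannels")
  if (object@sensorSnr <= 0) msg <- c(msg, "sensorSnr must be > 0")
  if (!all(c("error", "correct") %in% names(object@rtModel)))
    msg <- c(msg, "rtModel must have error and correct entries")
  if (length(msg)) msg else TRUE
})

#' GroundTruth: what the generator planted
#'
#' @slot activeDipoles integer indices of truly active dipoles.
#' @slot classEntropy named numeric (error, correct): analytic rhythm entropy
#'   -sum p log2 p of the configured proportions, in bits.
#' @slot couplingGraph directed adjacency matrix over simulated nodes
#'   (0 x 0 when the dataset has no coupled-node component).
#' @slot rt per-trial reaction times (ms), aligned with the EpochSet.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    activeDipoles = "integer",
    classEntropy = "numeric",
    couplingGraph = "matrix",
    rt = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  msg <- character()
  ce <- object@classEntropy
  if (any(ce < -1e-12 | ce > log2(3) + 1e-12))
    msg <- c(msg, "classEntropy must lie in [0, log2 3]")
  g <- object@couplingGraph
  if (length(g) && any(diag(g) != 0))
    msg <- c(msg, "couplingGraph must have a zero diagonal (no self-loops)")
  if (length(msg)) msg else TRUE
})

#' AssociationResult: correlation / paired-contrast summary
#'
#' @slot r Pearson coefficient (NA for paired tests).
#' @slot p two-sided p-value.
#' @slot n sample size.
#' @slot t t statistic (NA for plain correlations reported without one).
#' @slot d Cohen's d for a paired contrast (NA otherwise).
#' @slot method short description of the computed statistic.
#' @exportClass AssociationResult
setClass("AssociationResult",
  representation(
    r = "numeric",
    p = "numeric",
    n = "integer",
    t = "numeric",
    d = "numeric",
    method = "character"
  )
)

setValidity("AssociationResult", function(object) {
  msg <- character()
  if (!is.na(object@r) && abs(object@r) > 1 + 1e-12)
    msg <- c(msg, "r must lie in [-1, 1]")
  if (!is.na(object@p) && (object@p <= 0 || object@p > 1))
    msg <- c(msg, "p must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})
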