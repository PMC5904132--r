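#' Regularization scalar for the weighted minimum-norm operator
#'
#' Computes \code{lambda2 = trace(A R A') / (trace(C) * snr^2)}, the
#' regularization used in the weighted minimum-norm inverse at an assumed
#' amplitude SNR (default 5, the conventional value for evoked responses).
#'
#' @param A channels x dipoles gain matrix.
#' @param R dipoles x dipoles source covariance (default identity).
#' @param C channels x channels noise covariance (default identity).
#' @param snr assumed signal-to-noise ratio (> 0).
#' @return The scalar lambda2.
#' @export
computeLambda2 <- function(A, R = diag(ncol(A)), C = diag(nrow(A)), snr = 5) {
  stopifnot(snr > 0)
  trC <- sum(diag(C))
  if (trC <= 0) stop("computeLambda2: trace(C) must be positive")
  sum(diag(A %*% R %*% t(A))) / (trC * snr^2)
}

#' Weighted minimum-norm inverse operator
#'
#' Builds \code{W = R A' (A R A' + lambda2 C)^-1} via a symmetric solve (no
#' explicit matrix inverse). \code{R} defaults to the identity with optional
#' depth weighting (inverse squared leadfield column norms); \code{C}
#' defaults to the identity.
#'
#' @inheritParams computeLambda2
#' @param lambda2 optional explicit regularization scalar; computed from
#'   \code{snr} when \code{NULL}.
#' @param depthWeight if TRUE, \code{R} is set to
#'   \code{diag(1 / colNorms(A)^2)} (ignored when \code{R} is supplied).
#' @return An [InverseModel-class].
#' @export
computeInverseOperator <- function(A, R = NULL, C = NULL, snr = 5,
                                   lambda2 = NULL, depthWeight = FALSE) {
  if (is(A, "Leadfield")) A <- A@gain
  if (is.null(R))
    R <- if (depthWeight) diag(1 / colSums(A^2)) else diag(ncol(A))
  if (is.null(C)) C <- diag(nrow(A))
  if (is.null(lambda2)) lambda2 <- computeLambda2(A, R, C, snr)
  M <- A %*% R %*% t(A) + lambda2 * C
  rc <- rcond(M)
  if (rc < .Machine$double.eps * 100)
    stop(sprintf("computeInverseOperator: system is singular (rcond = %.3g)", rc))
  # W = R A' M^-1; with M symmetric this is t(solve(M, A R))
  W <- t(solve(M, A %*% R))
  # built by slot assignment: an argument named `C` in new() would partially
  # match its `Class` formal
  obj <- new("InverseModel")
  obj@A <- A; obj@R <- R; obj@C <- C
  obj@snr <- snr; obj@lambda2 <- lambda2; obj@W <- W
  validObject(obj)
  obj
}

#' Apply an inverse operator to epochs
#'
#' Computes \code{S(t) = W x(t)} for every trial: a linear map from scalp
#' potentials to dipole amplitudes.
#'
#' @param model an [InverseModel-class].
#' @param epochs an [EpochSet-class] whose channel count matches the model.
#' @param band band tag carried into the output (default \code{"broadband"}).
#' @return A [SourceSet-class] (trials x dipoles x samples).
#' @export
applyInverse <- function(model, epochs, band = "broadband") {
  stopifnot(is(model, "InverseModel"), is(epochs, "EpochSet"))
  if (nChannels(epochs) != ncol(model@W))
    stop("applyInverse: epoch channel count does not match the inverse operator")
  d <- dim(epochs@data)
  S <- array(0, c(d[1L], nrow(model@W), d[3L]))
  for (tr in seq_len(d[1L]))
    S[tr, , ] <- model@W %*% epochs@data[tr, , ]
  new("SourceSet", data = S, band = band, sfreq = epochs@sfreq,
      labels = epochs@labels, rt = epochs@rt)
}
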