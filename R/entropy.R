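#' Band power of a source segment
#'
#' Sum of squared amplitudes over the segment, \code{sum(S(t)^2)}.
#'
#' @param segment numeric vector of source samples.
#' @return Nonnegative scalar.
#' @export
bandPower <- function(segment) {
  if (!length(segment)) stop("bandPower: empty segment")
  sum(segment^2)
}

#' Normalize three band powers to proportions
#'
#' @param pTheta,pAlpha,pBeta nonnegative band powers; at least one must be
#'   positive.
#' @return 3-vector \code{P} with \code{P_i = Power_i / sum(Power)} summing
#'   to 1.
#' @export
normalizePowers <- function(pTheta, pAlpha, pBeta) {
  p <- c(pTheta, pAlpha, pBeta)
  if (any(p < 0)) stop("normalizePowers: powers must be nonnegative")
  s <- sum(p)
  if (s <= 0) stop("normalizePowers: all band powers are zero (degenerate trial)")
  p / s
}

#' Rhythm entropy of band-power proportions
#'
#' Shannon entropy in bits of the theta/alpha/beta power proportions,
#' \code{-sum(P_i * log2(P_i))} with the continuity convention
#' \code{0 * log2(0) = 0}. Ranges from 0 (all power in one band) to
#' \code{log2(3)} (uniform).
#'
#' @param P probability 3-vector (nonnegative, sums to 1).
#' @return Entropy in bits.
#' @export
rhythmEntropy <- function(P) {
  if (any(P < 0)) stop("rhythmEntropy: proportions must be nonnegative")
  if (abs(sum(P) - 1) > 1e-9) stop("rhythmEntropy: proportions must sum to 1")
  nz <- P > 0
  -sum(P[nz] * log2(P[nz]))
}

#' Rhythm-entropy features for a dataset
#'
#' Computes one rhythm-entropy value per (trial, dipole) from the three
#' band-specific source sets: per band the power is summed over the trial
#' window, the three powers are normalized, and their Shannon entropy (bits)
#' is taken. Trials with all-zero band power at any dipole are flagged as
#' degenerate, excluded and recorded.
#'
#' @param sources named list with elements \code{theta}, \code{alpha},
#'   \code{beta}, each a [SourceSet-class] with matching trials and dipoles.
#' @return A [FeatureTable-class].
#' @export
rhythmEntropyFeatures <- function(sources) {
  need <- c("theta", "alpha", "beta")
  if (!all(need %in% names(sources)))
    stop("rhythmEntropyFeatures: need theta, alpha and beta source sets")
  dims <- lapply(sources[need], function(s) dim(s@data))
  if (!all(vapply(dims, function(d) all(d == dims[[1L]]), logical(1L))))
    stop("rhythmEntropyFeatures: source sets must have matching dimensions")
  nT <- dims[[1L]][1L]; nD <- dims[[1L]][2L]
  pw <- array(0, c(nT, nD, 3L),
              dimnames = list(NULL, NULL, need))
  for (b in seq_along(need)) {
    s <- sources[[need[b]]]@data
    pw[, , b] <- apply(s^2, c(1L, 2L), sum)
  }
  tot <- matrix(pw[, , 1L] + pw[, , 2L] + pw[, , 3L], nT, nD)
  degenerate <- which(apply(tot <= 0, 1L, any))
  keep <- setdiff(seq_len(nT), degenerate)
  if (!length(keep)) stop("rhythmEntropyFeatures: all trials degenerate")
  if (length(degenerate))
    warning(sprintf("rhythmEntropyFeatures: excluded %d degenerate trial(s)",
                    length(degenerate)))
  vals <- matrix(0, length(keep), nD)
  for (ii in seq_along(keep)) {
    tr <- keep[ii]
    for (j in seq_len(nD))
      vals[ii, j] <- rhythmEntropy(pw[tr, j, ] / tot[tr, j])
  }
  new("FeatureTable",
      values = vals,
      labels = droplevels0(sources$theta@labels[keep]),
      rt = sources$theta@rt[keep],
      bandPowers = pw[keep, , , drop = FALSE],
      excluded = as.integer(degenerate))
}
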