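#' R-squared class discriminability of a feature
#'
#' Squared standardized class-mean difference,
#' \code{(mean(xPos) - mean(xNeg))^2 / (4 * sigma^2)}, where \code{sigma} is
#' the population standard deviation of the pooled (both-class) sample. With
#' the factor 4 and equal class sizes this equals the squared point-biserial
#' correlation between the feature and the class tag. A constant feature
#' (zero pooled variance) gives 0 with a warning.
#'
#' @param xPos,xNeg feature values of the positive (error) and negative
#'   (correct) class; each needs at least 2 samples.
#' @return Nonnegative scalar.
#' @export
rSquare <- function(xPos, xNeg) {
  if (length(xPos) < 2L || length(xNeg) < 2L)
    stop("rSquare: each class needs at least 2 samples")
  pooled <- c(xPos, xNeg)
  sigma2 <- mean((pooled - mean(pooled))^2)
  if (sigma2 == 0) {
    warning("rSquare: constant feature (zero pooled variance); returning 0")
    return(0)
  }
  (mean(xPos) - mean(xNeg))^2 / (4 * sigma2)
}

# Per-column R-squared of a feature matrix against two-level labels.
r2PerColumn <- function(X, y, positive = "error") {
  y <- as.character(y)
  pos <- y == positive
  apply(X, 2L, function(col) suppressWarnings(rSquare(col[pos], col[!pos])))
}

#' Threshold selection of discriminative dipoles
#'
#' Selects the dipoles whose R-squared value reaches
#' \code{thresholdFrac * max(r2)}. The argmax always qualifies, so the
#' selection is never empty; \code{thresholdFrac = 0} keeps every dipole and
#' \code{1} keeps the maximum (and exact ties).
#'
#' @param r2 numeric vector of per-dipole R-squared values.
#' @param thresholdFrac fraction of the maximum (default 0.6).
#' @return Integer indices of selected dipoles.
#' @export
selectDipoles <- function(r2, thresholdFrac = 0.6) {
  stopifnot(thresholdFrac >= 0, thresholdFrac <= 1)
  which(r2 >= thresholdFrac * max(r2))
}

#' Back-project selected-space values to the full dipole space
#'
#' Places each selected dipole's value at its original index and zeros
#' elsewhere (identity mapping U, so selected values pass through unchanged).
#'
#' @param r2Selected values in the reduced (selected) space.
#' @param indices dipole indices of the selected values.
#' @param nDipoles size of the full dipole space.
#' @return Numeric vector of length \code{nDipoles}.
#' @export
backProject <- function(r2Selected, indices, nDipoles) {
  stopifnot(length(r2Selected) == length(indices))
  if (length(indices) && (min(indices) < 1L || max(indices) > nDipoles))
    stop("backProject: dipole index out of range")
  D <- numeric(nDipoles)
  D[indices] <- r2Selected
  D
}

#' Compute the discriminability map of a feature table
#'
#' Per-dipole R-squared between the two classes' rhythm entropies, the
#' threshold selection at \code{thresholdFrac} of the maximum, and the
#' back-projected full-space map.
#'
#' @param features a [FeatureTable-class] (or a trials x dipoles matrix with
#'   \code{labels} supplied).
#' @param thresholdFrac fraction of the maximum R-squared (default 0.6).
#' @param labels class labels when \code{features} is a plain matrix.
#' @return An [R2Map-class].
#' @export
computeR2Map <- function(features, thresholdFrac = 0.6, labels = NULL) {
  if (is(features, "FeatureTable")) {
    X <- features@values; y <- features@labels
  } else {
    X <- as.matrix(features); y <- labels
  }
  r2 <- r2PerColumn(X, y)
  sel <- selectDipoles(r2, thresholdFrac)
  new("R2Map", r2 = r2, thresholdFrac = thresholdFrac,
      selected = as.integer(sel),
      projected = backProject(r2[sel], sel, length(r2)))
}

#' Sweep the selection threshold against LOOCV accuracy
#'
#' For each threshold fraction, dipoles are selected inside every LOOCV
#' training fold (R-squared recomputed on the fold, avoiding selection
#' leakage) and the leave-one-out accuracy of the RBF-SVM is recorded. Ties
#' in accuracy resolve to the smallest fraction.
#'
#' @param features a balanced [FeatureTable-class].
#' @param fracs threshold fractions (default 0.1, 0.2, ..., 1.0).
#' @param seed RNG seed for fold-internal randomness.
#' @param nested nested inner grid search (see [loocvRbfSvm()]).
#' @param perFoldSelection recompute selection inside each training fold
#'   (default) or once on all data.
#' @return List with \code{table} (data.frame: frac, ca, nSelected) and
#'   \code{best} (the selected fraction).
#' @export
thresholdSweep <- function(features, fracs = seq(0.1, 1, by = 0.1), seed = 1L,
                           nested = TRUE, perFoldSelection = TRUE) {
  stopifnot(is(features, "FeatureTable"))
  counts <- table(features@labels)
  if (length(unique(counts)) != 1L)
    stop("thresholdSweep: labels must be balanced (see balanceClasses)")
  X <- features@values; y <- features@labels
  rows <- lapply(seq_along(fracs), function(k) {
    frac <- fracs[k]
    if (perFoldSelection) {
      sel <- function(Xtr, ytr) selectDipoles(r2PerColumn(Xtr, ytr), frac)
      res <- loocvRbfSvm(X, y, selector = sel, nested = nested,
                         seed = childSeed(seed, k))
      nSel <- length(selectDipoles(r2PerColumn(X, y), frac))
    } else {
      cols <- selectDipoles(r2PerColumn(X, y), frac)
      res <- loocvRbfSvm(X[, cols, drop = FALSE], y, nested = nested,
                         seed = childSeed(seed, k))
      nSel <- length(cols)
    }
    data.frame(frac = frac, ca = res@ca, nSelected = nSel)
  })
  tab <- do.call(rbind, rows)
  best <- tab$frac[which.max(tab$ca)]   # which.max takes the first (smallest frac)
  list(table = tab, best = best)
}
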