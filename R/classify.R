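#' Penalty grid for the RBF-SVM
#'
#' The grid-search range for the SVM penalty C: \code{10^-8} to \code{10^8}
#' in multiplicative steps of \code{10^0.8} (21 values).
#'
#' @return Numeric vector of 21 penalty values.
#' @export
defaultCGrid <- function() 10^seq(-8, 8, by = 0.8)

#' Balance classes by subsampling the majority
#'
#' Randomly subsamples the majority class to the minority-class count,
#' leaving the minority class untouched and preserving trial order.
#' Deterministic for a fixed seed. A minority class below 20 trials triggers
#' a warning (small training sample), not an error.
#'
#' @param features a [FeatureTable-class].
#' @param seed RNG seed for the subsample.
#' @return A balanced [FeatureTable-class].
#' @export
balanceClasses <- function(features, seed = 1L) {
  stopifnot(is(features, "FeatureTable"))
  y <- features@labels
  counts <- table(y)
  if (any(counts == 0L))
    stop("balanceClasses: a class has zero trials")
  nMin <- min(counts)
  if (nMin < 20L)
    warning(sprintf("balanceClasses: minority class has only %d trials (< 20)", nMin))
  if (length(unique(counts)) == 1L) return(features)
  minority <- names(counts)[which.min(counts)]
  keep <- withSeed(seed, {
    idxMaj <- which(y != minority)
    sort(c(which(y == minority), sample(idxMaj, nMin)))
  })
  new("FeatureTable",
      values = features@values[keep, , drop = FALSE],
      labels = droplevels0(y[keep]),
      rt = features@rt[keep],
      bandPowers = features@bandPowers[keep, , , drop = FALSE],
      excluded = features@excluded)
}

#' Classification accuracy, sensitivity and specificity
#'
#' Exact evaluation of CA = (TP+TN)/(TP+TN+FP+FN), SE = TP/(TP+FN),
#' SP = TN/(TN+FP).
#'
#' @param TP,TN,FP,FN nonnegative integer counts, total > 0.
#' @return Named numeric vector \code{c(ca, se, sp)}.
#' @export
confusionMetrics <- function(TP, TN, FP, FN) {
  TP <- unname(TP); TN <- unname(TN); FP <- unname(FP); FN <- unname(FN)
  counts <- c(TP, TN, FP, FN)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  if (TP + FN == 0) stop("confusionMetrics: SE undefined (no positive samples)")
  if (TN + FP == 0) stop("confusionMetrics: SP undefined (no negative samples)")
  c(ca = (TP + TN) / sum(counts), se = TP / (TP + FN), sp = TN / (TN + FP))
}

#' Area under the ROC curve
#'
#' Tie-corrected Mann-Whitney statistic normalized by \code{n_pos * n_neg}:
#' the probability that a random positive-class score exceeds a random
#' negative-class score (ties counting one half).
#'
#' @param scores numeric decision scores (larger = more positive-class).
#' @param y two-level labels.
#' @param positive label value treated as the positive class (default
#'   \code{"error"}).
#' @return AUC in \[0, 1\].
#' @export
rocAuc <- function(scores, y, positive = "error") {
  y <- as.character(y)
  pos <- y == positive
  nPos <- sum(pos); nNeg <- sum(!pos)
  if (nPos == 0 || nNeg == 0)
    stop("rocAuc: both classes must be present")
  r <- rank(scores)                      # midranks handle ties
  (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

# Fit one RBF-SVM on standardized features with inverse-frequency class
# weights (counteracts the 1-trial imbalance LOOCV creates in each training
# fold of a balanced design).
fitRbfSvm <- function(X, y, C, gamma, classWeights = TRUE) {
  w <- NULL
  if (classWeights) {
    tab <- table(y)
    w <- as.numeric(length(y) / (length(tab) * tab))
    names(w) <- names(tab)
  }
  e1071::svm(x = X, y = y, type = "C-classification", kernel = "radial",
             cost = C, gamma = gamma, class.weights = w, scale = FALSE)
}

# Decision score oriented so that larger = more `positive` class.
svmScore <- function(fit, Xnew, positive) {
  pr <- stats::predict(fit, Xnew, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  s <- as.numeric(dv[, 1L])
  # colname "A/B" means positive decision values favour class A
  first <- strsplit(colnames(dv)[1L], "/", fixed = TRUE)[[1L]][1L]
  if (first != positive) s <- -s
  list(pred = as.character(pr), score = s)
}

# k-fold CV accuracy for each C on (X, y); ties break toward the C nearest
# to 1 in log10 distance (then the smaller C). Within each fold the grid is
# scanned in increasing C; the remaining (larger) C values reuse the current
# held-out predictions once either (a) the predictions have been identical
# for three consecutive values at C >= 100 (the decision rule has saturated
# in C), or (b) a fit at C >= 100 ran into the SMO iteration cap (> 1 s on
# these problem sizes) -- beyond that point libsvm returns iteration-capped
# approximations anyway while costing seconds per fit.
innerGridSearch <- function(X, y, Cgrid, gamma, k = 5L, seed = 1L,
                            classWeights = FALSE) {
  n <- length(y)
  ord <- order(Cgrid)
  folds <- withSeed(seed, {
    f <- integer(n)
    for (lv in unique(as.character(y))) {
      idx <- sample(which(as.character(y) == lv))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  hits <- numeric(length(Cgrid)); tot <- 0L
  for (fd in seq_len(k)) {
    tr <- folds != fd; te <- !tr
    if (!any(te) || length(unique(as.character(y[tr]))) < 2L) next
    tot <- tot + sum(te)
    yte <- as.character(y[te])
    prev <- NULL; sameRun <- 0L; lastDt <- 0
    for (j in seq_along(ord)) {
      ci <- ord[j]; C <- Cgrid[ci]
      if ((sameRun >= 3L || lastDt > 1) && C >= 100) {
        hits[ci] <- hits[ci] + sum(prev == yte)
        next
      }
      t0 <- proc.time()[[3L]]
      fit <- fitRbfSvm(X[tr, , drop = FALSE], y[tr], C, gamma, classWeights)
      lastDt <- proc.time()[[3L]] - t0
      pr <- as.character(stats::predict(fit, X[te, , drop = FALSE]))
      hits[ci] <- hits[ci] + sum(pr == yte)
      sameRun <- if (!is.null(prev) && identical(pr, prev)) sameRun + 1L else 0L
      prev <- pr
    }
  }
  if (tot == 0L) return(which.min(abs(log10(Cgrid))))
  acc <- hits / tot
  best <- which(acc == max(acc))
  best[order(abs(log10(Cgrid[best])), Cgrid[best])][1L]
}

#' Leave-one-out cross-validated RBF-SVM
#'
#' Each trial is held out once; the SVM is trained on the remaining trials
#' with the penalty C chosen by an inner stratified 5-fold grid search on the
#' training fold (nested, the default), or by a single grid search on all
#' data (\code{nested = FALSE}). Features are standardized with the training
#' fold's mean/SD. On a balanced design, leaving one trial out leaves the
#' training fold imbalanced by one trial, which biases plain LOOCV; with
#' \code{foldBalance = TRUE} (default) one seeded random trial of the
#' opposite class is dropped from each training fold so training stays
#' balanced. Pooled held-out predictions give the confusion matrix and
#' CA/SE/SP; pooled signed decision scores give the AUC.
#'
#' @param X trials x features numeric matrix.
#' @param y two-level labels (positive class \code{"error"}).
#' @param Cgrid penalty grid (default [defaultCGrid()]).
#' @param gamma RBF kernel width; default \code{1 / (n_features * mean
#'   feature variance)} computed on the training fold.
#' @param nested nested (per-fold) grid search, or one grid search on all
#'   data before LOOCV.
#' @param standardize standardize features with training-fold statistics.
#' @param foldBalance drop one seeded opposite-class trial per training fold
#'   to keep fold classes balanced (default TRUE).
#' @param classWeights use inverse-frequency class weights (off by default;
#'   redundant under \code{foldBalance}).
#' @param selector optional function \code{(Xtrain, ytrain) -> column
#'   indices} recomputed inside every training fold (e.g. R-squared dipole
#'   selection) to avoid selection leakage.
#' @param seed seed for fold assignment in the inner grid search.
#' @param positive positive-class label.
#' @return An [EvalResult-class].
#' @export
loocvRbfSvm <- function(X, y, Cgrid = defaultCGrid(), gamma = NULL,
                        nested = TRUE, standardize = TRUE, foldBalance = TRUE,
                        classWeights = FALSE,
                        selector = NULL, seed = 1L, positive = "error") {
  X <- as.matrix(X)
  y <- droplevels0(factor(as.character(y), levels = unique(c("error", "correct", as.character(y)))))
  n <- nrow(X)
  if (n < 6L) stop("loocvRbfSvm: need at least 6 trials")
  if (length(unique(as.character(y))) < 2L)
    stop("loocvRbfSvm: both classes must be present")
  prepFold <- function(idxTr) {
    Xtr <- X[idxTr, , drop = FALSE]; ytr <- y[idxTr]
    if (length(unique(as.character(ytr))) < 2L)
      stop("loocvRbfSvm: single-class training fold")
    cols <- if (is.null(selector)) seq_len(ncol(X)) else selector(Xtr, ytr)
    Xtr <- Xtr[, cols, drop = FALSE]
    mu <- colMeans(Xtr); sdv <- apply(Xtr, 2L, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    if (!standardize) { mu[] <- 0; sdv[] <- 1 }
    Xs <- sweep(sweep(Xtr, 2L, mu, "-"), 2L, sdv, "/")
    g <- gamma
    if (is.null(g)) {
      v <- mean(apply(Xs, 2L, stats::var))
      g <- 1 / (ncol(Xs) * max(v, .Machine$double.eps))
    }
    list(X = Xs, y = ytr, cols = cols, mu = mu, sd = sdv, gamma = g)
  }
  globalC <- NULL
  if (!nested) {
    fl <- prepFold(seq_len(n))
    globalC <- Cgrid[innerGridSearch(fl$X, fl$y, Cgrid, fl$gamma,
                                     seed = childSeed(seed, 0L),
                                     classWeights = classWeights)]
  }
  truth <- as.character(y)
  pred <- character(n); score <- numeric(n); usedC <- numeric(n)
  for (i in seq_len(n)) {
    idxTr <- setdiff(seq_len(n), i)
    if (foldBalance) {
      cnt <- table(as.character(y[idxTr]))
      if (length(cnt) == 2L && cnt[1L] != cnt[2L]) {
        big <- names(cnt)[which.max(cnt)]
        drop <- withSeed(childSeed(seed, 10000L + i),
                         sample(idxTr[as.character(y[idxTr]) == big], 1L))
        idxTr <- setdiff(idxTr, drop)
      }
    }
    fl <- prepFold(idxTr)
    Ci <- if (nested)
      Cgrid[innerGridSearch(fl$X, fl$y, Cgrid, fl$gamma,
                            seed = childSeed(seed, i),
                            classWeights = classWeights)]
    else globalC
    fit <- fitRbfSvm(fl$X, fl$y, Ci, fl$gamma, classWeights)
    xte <- (X[i, fl$cols, drop = FALSE] - fl$mu) / fl$sd
    out <- svmScore(fit, matrix(xte, nrow = 1L), positive)
    pred[i] <- out$pred; score[i] <- out$score; usedC[i] <- Ci
  }
  TP <- sum(truth == positive & pred == positive)
  TN <- sum(truth != positive & pred != positive)
  FP <- sum(truth != positive & pred == positive)
  FN <- sum(truth == positive & pred != positive)
  m <- confusionMetrics(TP, TN, FP, FN)
  new("EvalResult",
      ca = unname(m["ca"]), se = unname(m["se"]), sp = unname(m["sp"]),
      auc = rocAuc(score, truth, positive = positive),
      confusion = c(TP = TP, TN = TN, FP = FP, FN = FN),
      predictions = data.frame(truth = truth, predicted = pred,
                               score = score, C = usedC,
                               stringsAsFactors = FALSE),
      seed = as.integer(seed))
}
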