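#' Pearson correlation between reaction time and entropy
#'
#' Standard Pearson correlation with a two-sided p-value (per-subject means
#' are the intended unit of analysis at group level, per-trial values at
#' single-dataset level).
#'
#' @param rt numeric vector (ms).
#' @param en numeric vector (bits), same length, n >= 3.
#' @return An [AssociationResult-class] with r, t, p and n.
#' @export
pearsonRtEntropy <- function(rt, en) {
  stopifnot(length(rt) == length(en))
  n <- length(rt)
  if (n < 3L) stop("pearsonRtEntropy: need at least 3 pairs")
  if (stats::sd(rt) == 0 || stats::sd(en) == 0)
    stop("pearsonRtEntropy: zero variance in an input vector")
  ct <- stats::cor.test(rt, en, method = "pearson", alternative = "two.sided")
  new("AssociationResult",
      r = unname(ct$estimate), p = ct$p.value, n = as.integer(n),
      t = unname(ct$statistic), d = NA_real_,
      method = "Pearson correlation (RT vs entropy)")
}

#' Paired comparison of entropy between classes
#'
#' Paired t-test of error-class versus correct-class entropies (one pair per
#' subject), with Cohen's d for the paired contrast,
#' \code{mean(diff) / sd(diff)}.
#'
#' @param enError,enCorrect paired numeric vectors (bits), n >= 2.
#' @return An [AssociationResult-class] with t, p, d and n.
#' @export
pairedEntropyTest <- function(enError, enCorrect) {
  stopifnot(length(enError) == length(enCorrect))
  n <- length(enError)
  if (n < 2L) stop("pairedEntropyTest: need at least 2 pairs")
  diffs <- enError - enCorrect
  if (stats::sd(diffs) <= 1e-12 * max(1, abs(mean(diffs))))
    stop("pairedEntropyTest: zero-variance differences (degenerate contrast)")
  tt <- stats::t.test(enError, enCorrect, paired = TRUE)
  new("AssociationResult",
      r = NA_real_, p = tt$p.value, n = as.integer(n),
      t = unname(tt$statistic), d = mean(diffs) / stats::sd(diffs),
      method = "paired t-test (error vs correct entropy)")
}

#' Degree-adjusted edge value
#'
#' Divides a directed edge's integrated-ADTF value by the weighted degree of
#' a node at that time point: the sum of the node's incident edge values
#' (incoming plus outgoing by default, self-terms excluded). Scale-invariant
#' under a common rescaling of all edges.
#'
#' @param value the edge's integrated ADTF value at the time point.
#' @param network a [TVNetwork-class].
#' @param node node index whose degree normalizes the value.
#' @param time time index into the network trajectory.
#' @param mode \code{"total"} (in + out), \code{"in"} or \code{"out"}.
#' @return Nonnegative adjusted value.
#' @export
degreeAdjust <- function(value, network, node, time,
                         mode = c("total", "in", "out")) {
  stopifnot(is(network, "TVNetwork"))
  mode <- match.arg(mode)
  W <- network@integrated[, , time]
  n <- nrow(W)
  stopifnot(node >= 1L, node <= n)
  inDeg <- sum(W[node, -node])    # senders j -> node
  outDeg <- sum(W[-node, node])   # node -> receivers i
  deg <- switch(mode, total = inDeg + outDeg, "in" = inDeg, out = outDeg)
  if (deg <= 0) stop("degreeAdjust: zero weighted degree at this time point")
  value / deg
}
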