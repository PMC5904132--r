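#' Accessors for rhenet containers
#'
#' Small accessor methods returning slot contents of the package's S4
#' containers; use these rather than \code{@} access.
#'
#' @param x a rhenet container object.
#' @return The requested component (dimension count, metadata vector, matrix
#'   or array as documented per class).
#' @name accessors
NULL

#' @rdname accessors
setMethod("nTrials", "EpochSet", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nTrials", "SourceSet", function(x) dim(x@data)[1L])
#' @rdname accessors
setMethod("nTrials", "FeatureTable", function(x) nrow(x@values))

#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@data)[2L])
#' @rdname accessors
setMethod("nChannels", "Leadfield", function(x) nrow(x@gain))

#' @rdname accessors
setMethod("nDipoles", "Leadfield", function(x) ncol(x@gain))
#' @rdname accessors
setMethod("nDipoles", "SourceSet", function(x) dim(x@data)[2L])
#' @rdname accessors
setMethod("nDipoles", "FeatureTable", function(x) ncol(x@values))

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@sfreq)
#' @rdname accessors
setMethod("samplingRate", "SourceSet", function(x) x@sfreq)
#' @rdname accessors
setMethod("samplingRate", "MVAARFit", function(x) x@sfreq)

#' @rdname accessors
setMethod("trialLabels", "EpochSet", function(x) x@labels)
#' @rdname accessors
setMethod("trialLabels", "SourceSet", function(x) x@labels)
#' @rdname accessors
setMethod("trialLabels", "FeatureTable", function(x) x@labels)

#' @rdname accessors
setMethod("reactionTimes", "EpochSet", function(x) x@rt)
#' @rdname accessors
setMethod("reactionTimes", "SourceSet", function(x) x@rt)
#' @rdname accessors
setMethod("reactionTimes", "FeatureTable", function(x) x@rt)
#' @rdname accessors
setMethod("reactionTimes", "GroundTruth", function(x) x@rt)

#' @rdname accessors
setMethod("epochData", "EpochSet", function(x) x@data)
#' @rdname accessors
setMethod("sourceData", "SourceSet", function(x) x@data)
#' @rdname accessors
setMethod("gainMatrix", "Leadfield", function(x) x@gain)
#' @rdname accessors
setMethod("gainMatrix", "InverseModel", function(x) x@A)
#' @rdname accessors
setMethod("inverseOperator", "InverseModel", function(x) x@W)

#' @rdname accessors
setMethod("featureValues", "FeatureTable", function(x) x@values)
#' @rdname accessors
setMethod("bandPowers", "FeatureTable", function(x) x@bandPowers)

#' @rdname accessors
setMethod("r2Values", "R2Map", function(x) x@r2)
#' @rdname accessors
setMethod("selectedDipoles", "R2Map", function(x) x@selected)
#' @rdname accessors
setMethod("projectedMap", "R2Map", function(x) x@projected)
#' @rdname accessors
setMethod("selectedDipoles", "GroundTruth", function(x) x@activeDipoles)

#' @rdname accessors
setMethod("coefArray", "MVAARFit", function(x) x@coeffs)
#' @rdname accessors
setMethod("integratedAdtf", "TVNetwork", function(x) x@integrated)
#' @rdname accessors
setMethod("nullThresholds", "TVNetwork", function(x) x@nullThresholds)
#' @rdname accessors
setMethod("significantEdges", "TVNetwork", function(x) x@significant)

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("EpochSet: %d trials x %d channels x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], object@sfreq))
  cat(sprintf("  labels: %s\n",
              paste(sprintf("%s=%d", levels(object@labels),
                            tabulate(object@labels, nbins = nlevels(object@labels))),
                    collapse = ", ")))
  cat(sprintf("  window: [%g, %g] s\n", object@window[1L], object@window[2L]))
})

setMethod("show", "Leadfield", function(object) {
  cat(sprintf("Leadfield: %d channels x %d dipoles (unit-norm columns)\n",
              nrow(object@gain), ncol(object@gain)))
})

setMethod("show", "InverseModel", function(object) {
  cat(sprintf("InverseModel (WMNE): %d dipoles x %d channels, snr = %g, lambda2 = %.6g\n",
              nrow(object@W), ncol(object@W), object@snr, object@lambda2))
})

setMethod("show", "SourceSet", function(object) {
  d <- dim(object@data)
  cat(sprintf("SourceSet [%s]: %d trials x %d dipoles x %d samples @ %g Hz\n",
              object@band, d[1L], d[2L], d[3L], object@sfreq))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d trials x %d dipoles rhythm entropy (bits)\n",
              nrow(object@values), ncol(object@values)))
  if (length(object@excluded))
    cat(sprintf("  %d degenerate trial(s) excluded\n", length(object@excluded)))
})

setMethod("show", "R2Map", function(object) {
  cat(sprintf("R2Map: %d dipoles, max R2 = %.4f, threshold frac = %g, %d selected\n",
              length(object@r2), max(object@r2), object@thresholdFrac,
              length(object@selected)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf("EvalResult (LOOCV RBF-SVM): CA = %.3f, SE = %.3f, SP = %.3f, AUC = %.3f\n",
              object@ca, object@se, object@sp, object@auc))
  cat(sprintf("  confusion: TP=%d TN=%d FP=%d FN=%d\n",
              object@confusion["TP"], object@confusion["TN"],
              object@confusion["FP"], object@confusion["FN"]))
})

setMethod("show", "MVAARFit", function(object) {
  d <- dim(object@coeffs)
  cat(sprintf("MVAARFit: %d nodes, order %d, uc = %g, %d time points\n",
              d[1L], object@order, object@uc, d[4L]))
})

setMethod("show", "TVNetwork", function(object) {
  d <- dim(object@integrated)
  cat(sprintf("TVNetwork: %d nodes x %d time points, band %g-%g Hz\n",
              d[1L], d[3L], object@band[1L], object@band[2L]))
  if (length(object@nullThresholds))
    cat(sprintf("  surrogate thresholds present (95th percentile)\n"))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d ch x %d dipoles, %g Hz, %g s epochs, %d trials/class, seed %d\n",
              object@nChannels, object@nDipoles, object@sfreq, object@epochLen,
              object@nTrialsPerClass, object@seed))
  cat(sprintf("  active dipoles: %s\n", paste(object@activeDipoles, collapse = ", ")))
  cat(sprintf("  props error: (%s); correct: (%s); sensor SNR %g\n",
              paste(signif(object@bandPropsError, 3), collapse = ", "),
              paste(signif(object@bandPropsCorrect, 3), collapse = ", "),
              object@sensorSnr))
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf("GroundTruth: active dipoles {%s}; class entropy error = %.3f, correct = %.3f bits\n",
              paste(object@activeDipoles, collapse = ", "),
              object@classEntropy["error"], object@classEntropy["correct"]))
})

setMethod("show", "AssociationResult", function(object) {
  cat(sprintf("AssociationResult [%s]: ", object@method))
  if (!is.na(object@r)) cat(sprintf("r = %.3f, ", object@r))
  if (!is.na(object@t)) cat(sprintf("t = %.3f, ", object@t))
  if (!is.na(object@d)) cat(sprintf("d = %.3f, ", object@d))
  cat(sprintf("p = %.4g, n = %d\n", object@p, object@n))
})
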