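# Accessor generics shared across the container classes.

#' @rdname accessors
#' @export
setGeneric("nTrials", function(x) standardGeneric("nTrials"))

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname accessors
#' @export
setGeneric("nDipoles", function(x) standardGeneric("nDipoles"))

#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname accessors
#' @export
setGeneric("trialLabels", function(x) standardGeneric("trialLabels"))

#' @rdname accessors
#' @export
setGeneric("reactionTimes", function(x) standardGeneric("reactionTimes"))

#' @rdname accessors
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname accessors
#' @export
setGeneric("sourceData", function(x) standardGeneric("sourceData"))

#' @rdname accessors
#' @export
setGeneric("gainMatrix", function(x) standardGeneric("gainMatrix"))

#' @rdname accessors
#' @export
setGeneric("inverseOperator", function(x) standardGeneric("inverseOperator"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("bandPowers", function(x) standardGeneric("bandPowers"))

#' @rdname accessors
#' @export
setGeneric("r2Values", function(x) standardGeneric("r2Values"))

#' @rdname accessors
#' @export
setGeneric("selectedDipoles", function(x) standardGeneric("selectedDipoles"))

#' @rdname accessors
#' @export
setGeneric("projectedMap", function(x) standardGeneric("projectedMap"))

#' @rdname accessors
#' @export
setGeneric("coefArray", function(x) standardGeneric("coefArray"))

#' @rdname accessors
#' @export
setGeneric("integratedAdtf", function(x) standardGeneric("integratedAdtf"))

#' @rdname accessors
#' @export
setGeneric("nullThresholds", function(x) standardGeneric("nullThresholds"))

#' @rdname accessors
#' @export
setGeneric("significantEdges", function(x) standardGeneric("significantEdges"))
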