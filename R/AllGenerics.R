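#' @include AllClasses.R
NULL

#' Accessors for cbctalert objects
#'
#' `voxelData()` returns the raw array of a volume or mask, `voxelSpacing()`
#' and `voxelOrigin()` its geometry in mm, `planId()` the plan identifier,
#' `failedValues()` the failed-voxel gamma multiset, `nEvaluated()` the
#' evaluated-voxel count(s), `gammaRef()` the reference-match percentile
#' gamma, `mqpEntries()` the MQP table, `triggerFraction()` the alert's
#' fraction, and `confusionCounts()` the TP/TN/FP/FN counts.
#'
#' @param x an object from this package.
#' @return the accessed component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelOrigin", function(x) standardGeneric("voxelOrigin"))
#' @rdname accessors
#' @export
setGeneric("planId", function(x) standardGeneric("planId"))
#' @rdname accessors
#' @export
setGeneric("failedValues", function(x) standardGeneric("failedValues"))
#' @rdname accessors
#' @export
setGeneric("nEvaluated", function(x) standardGeneric("nEvaluated"))
#' @rdname accessors
#' @export
setGeneric("gammaRef", function(x) standardGeneric("gammaRef"))
#' @rdname accessors
#' @export
setGeneric("mqpEntries", function(x) standardGeneric("mqpEntries"))
#' @rdname accessors
#' @export
setGeneric("triggerFraction", function(x) standardGeneric("triggerFraction"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' @rdname failedPercentile
#' @export
setGeneric("failedPercentile", function(x, percentile = 80)
  standardGeneric("failedPercentile"))

#' @rdname detectAlert
#' @export
setGeneric("detectAlert", function(series, config = alertConfig())
  standardGeneric("detectAlert"))

#' @rdname alertEvents
#' @export
setGeneric("alertEvents", function(series, config = alertConfig())
  standardGeneric("alertEvents"))
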