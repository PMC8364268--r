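#' @include AllGenerics.R
NULL

# ---- accessors --------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("voxelData", "VolumeGrid", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "MaskVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("voxelData", "GammaResult", function(x) x@gamma)

#' @rdname accessors
#' @export
setMethod("voxelSpacing", "VolumeGrid", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("voxelSpacing", "MaskVolume", function(x) x@spacing)

#' @rdname accessors
#' @export
setMethod("voxelOrigin", "VolumeGrid", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("voxelOrigin", "MaskVolume", function(x) x@origin)

#' @rdname accessors
#' @export
setMethod("planId", "CourseComparison", function(x) x@plan_id)
#' @rdname accessors
#' @export
setMethod("planId", "MqpSeries", function(x) x@plan_id)
#' @rdname accessors
#' @export
setMethod("planId", "AlertEvent", function(x) x@plan_id)

#' @rdname accessors
#' @export
setMethod("failedValues", "GammaResult", function(x) x@failed_values)
#' @rdname accessors
#' @export
setMethod("failedValues", "CourseComparison", function(x) x@failed_values)

#' @rdname accessors
#' @export
setMethod("nEvaluated", "GammaResult", function(x) x@n_evaluated)
#' @rdname accessors
#' @export
setMethod("nEvaluated", "CourseComparison", function(x) x@n_evaluated)

#' @rdname accessors
#' @export
setMethod("gammaRef", "MqpSeries", function(x) x@gamma_ref)

#' @rdname accessors
#' @export
setMethod("mqpEntries", "MqpSeries", function(x) x@entries)

#' @rdname accessors
#' @export
setMethod("triggerFraction", "AlertEvent", function(x) x@trigger_fraction)

#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionSummary", function(x)
  c(tp = x@tp, tn = x@tn, fp = x@fp, fn = x@fn))

#' Sensitivity and false positive rate of a ConfusionSummary
#'
#' @param x a [ConfusionSummary-class].
#' @return a numeric scalar (full precision; `NA` when undefined).
#' @export
sensitivity <- function(x) {
  stopifnot(is(x, "ConfusionSummary"))
  x@sensitivity
}

#' @rdname sensitivity
#' @export
falsePositiveRate <- function(x) {
  stopifnot(is(x, "ConfusionSummary"))
  x@false_positive_rate
}

# ---- show methods -----------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  d <- dim(object@data)
  cat(sprintf("VolumeGrid %dx%dx%d (slice,row,col), spacing %s mm, origin %s mm\n",
              d[1], d[2], d[3],
              paste(format(object@spacing), collapse = "x"),
              paste(format(object@origin), collapse = ", ")))
  cat(sprintf("  HU range [%.1f, %.1f]\n",
              min(object@data), max(object@data)))
})

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("MaskVolume %dx%dx%d, %d voxels true (%s)\n",
              d[1], d[2], d[3], sum(object@data), object@provenance))
})

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform (", object@direction, ")\n", sep = "")
  cat("  translation (mm):", format(object@translation), "\n")
  if (max(abs(object@rotation - diag(3))) > 1e-12) {
    cat("  rotation:\n")
    print(object@rotation)
  } else cat("  rotation: identity\n")
})

setMethod("show", "GammaCriteria", function(object) {
  step <- if (is.na(object@interp_step_mm)) "auto (min(spacing)/3)"
          else if (object@interp_step_mm == 0) "integer grid"
          else paste0(object@interp_step_mm, " mm")
  cat(sprintf("GammaCriteria: DTA %g mm / %g HU (global), search radius %g mm, step %s\n",
              object@dta_mm, object@delta_hu, object@search_radius_mm, step))
})

setMethod("show", "GammaResult", function(object) {
  cat(sprintf("GammaResult: %d voxels evaluated (%d excluded), %d failed (gamma > 1)\n",
              object@n_evaluated, object@n_excluded,
              length(object@failed_values)))
  if (length(object@failed_values))
    cat(sprintf("  failed gamma: median %.3f, 80th pct %.3f, max %.3f\n",
                stats::median(object@failed_values),
                failedPercentile(object, 80), max(object@failed_values)))
})

setMethod("show", "CourseComparison", function(object) {
  cat(sprintf("CourseComparison plan %s: reference fraction %d, %d comparisons\n",
              object@plan_id, object@ref_fraction, length(object@fractions)))
})

setMethod("show", "MqpSeries", function(object) {
  cat(sprintf("MqpSeries plan %s (x = %g, gamma_ref = %.4f), %d entries\n",
              object@plan_id, object@x, object@gamma_ref, nrow(object@entries)))
  if (nrow(object@entries)) {
    cat(sprintf("  fractions %d..%d, MQP range [%.3f, %.3f]\n",
                min(object@entries$fraction), max(object@entries$fraction),
                min(object@entries$mqp), max(object@entries$mqp)))
  }
})

setMethod("show", "AlertConfig", function(object) {
  cat(sprintf("AlertConfig: %d consecutive MQP < %g\n",
              object@consecutive_required, object@threshold))
  if (is.finite(object@mute_after_fraction))
    cat(sprintf("  follow-ups muted after fraction %g\n",
                object@mute_after_fraction))
})

setMethod("show", "AlertEvent", function(object) {
  cat(sprintf("AlertEvent plan %s: triggered at fraction %d (acquisition %d)%s%s\n",
              object@plan_id, object@trigger_fraction,
              object@trigger_acquisition,
              if (object@is_followup) " [follow-up]" else "",
              if (object@suppressed) " [suppressed]" else ""))
})

setMethod("show", "ConfusionSummary", function(object) {
  cat(sprintf("ConfusionSummary: TP %d  TN %d  FP %d  FN %d\n",
              object@tp, object@tn, object@fp, object@fn))
  sens <- if (is.na(object@sensitivity)) "undefined"
          else sprintf("%.2f", roundHalfUp(object@sensitivity, 2))
  fpr <- if (is.na(object@false_positive_rate)) "undefined"
         else sprintf("%.2f", roundHalfUp(object@false_positive_rate, 2))
  cat(sprintf("  sensitivity %s, false positive rate %s\n", sens, fpr))
})
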