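#' @include utils.R
NULL

# ---- VolumeGrid -------------------------------------------------------------

#' VolumeGrid: a 3D intensity volume with physical geometry
#'
#' Holds a 3D scalar field of CT/CBCT intensities in Hounsfield units (HU)
#' together with its voxel spacing and origin in mm. Arrays are ordered
#' (slice, row, column); voxel (i, j, k) (0-based) sits at
#' `origin + c(i, j, k) * spacing`.
#'
#' @slot data 3D numeric array of intensities (HU), all finite.
#' @slot spacing numeric(3), per-axis voxel size in mm, all > 0.
#' @slot origin numeric(3), physical position of voxel (0, 0, 0) in mm.
#' @export
setClass("VolumeGrid",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L)
      msg <- c(msg, "data must be a 3D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values (mm)")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values (mm)")
    if (anyNA(object@data) || any(!is.finite(object@data)))
      msg <- c(msg, "volume contains non-finite voxels")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a VolumeGrid
#'
#' @param data 3D numeric array (HU), (slice, row, column) order.
#' @param spacing numeric(3) voxel size in mm.
#' @param origin numeric(3) position of voxel (0,0,0) in mm.
#' @return a [VolumeGrid-class] object.
#' @examples
#' v <- volumeGrid(array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
#' dim(voxelData(v))
#' @export
volumeGrid <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("VolumeGrid", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

# ---- MaskVolume -------------------------------------------------------------

#' MaskVolume: a binary mask on a volume grid
#'
#' @slot data 3D logical array on the same grid as its companion volume.
#' @slot spacing numeric(3) voxel size, mm.
#' @slot origin numeric(3) origin, mm.
#' @slot provenance character note on how the mask was obtained
#'   (e.g. "external_contour", "dilated(margin_mm=10)", "supplied").
#' @export
setClass("MaskVolume",
  representation(data = "array", spacing = "numeric", origin = "numeric",
                 provenance = "character"),
  validity = function(object) {
    msg <- NULL
    if (length(dim(object@data)) != 3L || !is.logical(object@data))
      msg <- c(msg, "mask data must be a 3D logical array")
    if (anyNA(object@data))
      msg <- c(msg, "mask contains NA voxels")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values (mm)")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a MaskVolume
#'
#' @param data 3D logical array.
#' @param spacing,origin grid geometry in mm (matching the companion volume).
#' @param provenance free-text provenance note.
#' @return a [MaskVolume-class] object.
#' @export
maskVolume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                       provenance = "supplied") {
  storage.mode(data) <- "logical"
  new("MaskVolume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin), provenance = provenance)
}

# ---- RigidTransform ---------------------------------------------------------

#' RigidTransform: rotation + translation between volume frames
#'
#' Maps physical points (mm) of one volume into the frame of another:
#' `p_out = rotation %*% p_in + translation`. The `direction` flag records
#' whether the transform maps moving-volume coordinates into the reference
#' frame (`"moving_to_reference"`) or the inverse.
#'
#' @slot rotation 3x3 orthonormal matrix, det +1 (to 1e-6).
#' @slot translation numeric(3), mm.
#' @slot direction `"moving_to_reference"` or `"reference_to_moving"`.
#' @export
setClass("RigidTransform",
  representation(rotation = "matrix", translation = "numeric",
                 direction = "character"),
  validity = function(object) {
    msg <- NULL
    R <- object@rotation
    if (!all(dim(R) == c(3, 3))) {
      msg <- c(msg, "rotation must be 3x3")
    } else {
      if (max(abs(crossprod(R) - diag(3))) > 1e-6)
        msg <- c(msg, "rotation is not orthonormal (tolerance 1e-6)")
      else if (abs(det(R) - 1) > 1e-6)
        msg <- c(msg, "rotation must be proper (det +1)")
    }
    if (length(object@translation) != 3L || any(!is.finite(object@translation)))
      msg <- c(msg, "translation must be 3 finite values (mm)")
    if (!object@direction %in% c("moving_to_reference", "reference_to_moving"))
      msg <- c(msg, "direction must be moving_to_reference or reference_to_moving")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct a RigidTransform
#'
#' @param rotation 3x3 orthonormal matrix (default identity).
#' @param translation numeric(3) in mm.
#' @param direction `"moving_to_reference"` (default) or
#'   `"reference_to_moving"`.
#' @return a [RigidTransform-class] object.
#' @examples
#' tr <- rigidTransform(translation = c(0, 0, 5))
#' applyTransform(tr, c(0, 0, 0))
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0),
                           direction = "moving_to_reference") {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation), direction = direction)
}

# ---- GammaCriteria ----------------------------------------------------------

#' GammaCriteria: acceptance criteria for the gamma-index comparison
#'
#' The gamma index is a global evaluation: the intensity term is always
#' normalised by the fixed `delta_hu`, never a local percentage.
#'
#' @slot dta_mm distance-to-agreement criterion, mm (> 0).
#' @slot delta_hu intensity-difference criterion, HU (> 0).
#' @slot search_radius_mm maximum DTA search distance, mm (>= dta_mm).
#' @slot interp_step_mm subvoxel search lattice pitch, mm. `NA` selects the
#'   automatic pitch `min(spacing)/3` at evaluation time; `0` selects the
#'   exact integer-grid search used by the oracle tests.
#' @export
setClass("GammaCriteria",
  representation(dta_mm = "numeric", delta_hu = "numeric",
                 search_radius_mm = "numeric", interp_step_mm = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (object@dta_mm <= 0) msg <- c(msg, "dta_mm must be > 0")
    if (object@delta_hu <= 0) msg <- c(msg, "delta_hu must be > 0")
    if (object@search_radius_mm < object@dta_mm)
      msg <- c(msg, "search_radius_mm must be >= dta_mm")
    if (!is.na(object@interp_step_mm) && object@interp_step_mm < 0)
      msg <- c(msg, "interp_step_mm must be NA, 0 or positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' Construct gamma criteria
#'
#' Defaults are the clinical operating point for CBCT anatomy comparison:
#' 3 mm distance to agreement and 30 HU, with the search capped at three
#' times the DTA.
#'
#' @param dta_mm distance-to-agreement, mm.
#' @param delta_hu intensity criterion, HU.
#' @param search_radius_mm DTA search cap, mm (default `3 * dta_mm`).
#' @param interp_step_mm subvoxel lattice pitch in mm; `NA` = `min(spacing)/3`
#'   chosen at evaluation time, `0` = integer-grid (no subvoxel) search.
#' @return a [GammaCriteria-class] object.
#' @export
gammaCriteria <- function(dta_mm = 3, delta_hu = 30,
                          search_radius_mm = 3 * dta_mm,
                          interp_step_mm = NA_real_) {
  new("GammaCriteria", dta_mm = as.numeric(dta_mm),
      delta_hu = as.numeric(delta_hu),
      search_radius_mm = as.numeric(search_radius_mm),
      interp_step_mm = as.numeric(interp_step_mm))
}

# ---- GammaResult ------------------------------------------------------------

#' GammaResult: a masked gamma map and its failed-voxel values
#'
#' @slot gamma 3D numeric array of gamma values; `NA` outside the mask and at
#'   excluded (non-finite reference) voxels.
#' @slot mask the [MaskVolume-class] the map was evaluated on.
#' @slot failed_values numeric vector of the gamma values > 1 inside the mask
#'   (the failed-voxel multiset from which percentiles are taken).
#' @slot n_evaluated number of voxels actually evaluated.
#' @slot n_excluded masked voxels excluded as non-finite/out-of-field.
#' @slot criteria the [GammaCriteria-class] used.
#' @export
setClass("GammaResult",
  representation(gamma = "array", mask = "MaskVolume",
                 failed_values = "numeric", n_evaluated = "integer",
                 n_excluded = "integer", criteria = "GammaCriteria"),
  validity = function(object) {
    msg <- NULL
    g <- object@gamma[!is.na(object@gamma)]
    if (any(g < 0)) msg <- c(msg, "gamma values must be >= 0")
    if (any(object@failed_values <= 1))
      msg <- c(msg, "failed_values must all exceed 1")
    if (is.null(msg)) TRUE else msg
  }
)

# ---- CourseComparison -------------------------------------------------------

#' CourseComparison: per-acquisition gamma summaries for one plan
#'
#' The result of comparing every usable CBCT of a plan against the plan's
#' reference CBCT (the earliest usable one). Entry 1 — reference CBCT versus
#' the second usable CBCT — is the reference match. Only the failed-voxel
#' gamma values are retained per entry, which is all that is needed to form
#' MQP series at any percentile without recomputing gamma maps.
#'
#' @slot plan_id plan identifier.
#' @slot ref_fraction treatment fraction of the reference CBCT.
#' @slot fractions integer vector of the fractions of the evaluated CBCTs
#'   (one per entry, strictly increasing).
#' @slot acquisitions integer ordinals of the evaluated usable CBCTs.
#' @slot failed_values list of numeric vectors, one per entry.
#' @slot n_evaluated integer vector, evaluated voxel counts per entry.
#' @slot criteria the [GammaCriteria-class] used.
#' @export
setClass("CourseComparison",
  representation(plan_id = "character", ref_fraction = "integer",
                 fractions = "integer", acquisitions = "integer",
                 failed_values = "list", n_evaluated = "integer",
                 criteria = "GammaCriteria"),
  validity = function(object) {
    msg <- NULL
    n <- length(object@fractions)
    if (length(object@failed_values) != n || length(object@acquisitions) != n)
      msg <- c(msg, "fractions, acquisitions and failed_values lengths differ")
    if (n > 1 && any(diff(object@fractions) <= 0))
      msg <- c(msg, "fractions must be strictly increasing")
    if (is.null(msg)) TRUE else msg
  }
)

# ---- MqpSeries --------------------------------------------------------------

#' MqpSeries: the match quality parameter over one plan
#'
#' MQP for entry i is `gamma_ref - gamma_i`, where both are the xth
#' percentile of the failed-voxel gamma histogram; negative values mean a
#' poorer CBCT match than the reference match. The first entry (the
#' reference match itself) is exactly 0 by construction. A re-plan starts a
#' new series.
#'
#' @slot plan_id plan identifier.
#' @slot x percentile of the failed-voxel histogram used (default 80).
#' @slot gamma_ref the reference-match percentile gamma value.
#' @slot entries data.frame with columns `acquisition`, `fraction`, `mqp`,
#'   sorted by strictly increasing fraction.
#' @export
setClass("MqpSeries",
  representation(plan_id = "character", x = "numeric", gamma_ref = "numeric",
                 entries = "data.frame"),
  validity = function(object) {
    msg <- NULL
    e <- object@entries
    if (!all(c("acquisition", "fraction", "mqp") %in% names(e)))
      msg <- c(msg, "entries needs columns acquisition, fraction, mqp")
    else {
      if (nrow(e) > 0 && e$mqp[1] != 0)
        msg <- c(msg, "reference-match MQP must be exactly 0")
      if (nrow(e) > 1 && any(diff(e$fraction) <= 0))
        msg <- c(msg, "entries must be strictly increasing in fraction")
    }
    if (object@x <= 0 || object@x >= 100)
      msg <- c(msg, "x must be in (0, 100)")
    if (is.null(msg)) TRUE else msg
  }
)

# ---- AlertConfig ------------------------------------------------------------

#' AlertConfig: the consecutive-threshold alert trigger
#'
#' An alert fires at the first acquisition completing
#' `consecutive_required` consecutive usable acquisitions whose MQP is
#' strictly below `threshold`; one at-or-above entry resets the run.
#'
#' @slot threshold MQP cutoff (default -0.11, the calibrated clinical value).
#' @slot consecutive_required run length required (default 3).
#' @slot mute_after_fraction optional suppression: follow-up alerts at
#'   fractions beyond this are flagged suppressed (default `Inf`, off).
#' @export
setClass("AlertConfig",
  representation(threshold = "numeric", consecutive_required = "integer",
                 mute_after_fraction = "numeric"),
  validity = function(object) {
    if (object@consecutive_required < 1L) "consecutive_required must be >= 1"
    else TRUE
  }
)

#' Construct an alert configuration
#'
#' @param threshold MQP threshold; alerts need MQP strictly below it.
#' @param consecutive_required number of consecutive sub-threshold
#'   acquisitions required.
#' @param mute_after_fraction fractions after this have follow-up alerts
#'   flagged suppressed (default off).
#' @return an [AlertConfig-class] object.
#' @export
alertConfig <- function(threshold = -0.11, consecutive_required = 3,
                        mute_after_fraction = Inf) {
  new("AlertConfig", threshold = as.numeric(threshold),
      consecutive_required = as.integer(consecutive_required),
      mute_after_fraction = as.numeric(mute_after_fraction))
}

# ---- AlertEvent -------------------------------------------------------------

#' AlertEvent: a triggered anatomy-change alert
#'
#' @slot plan_id plan identifier.
#' @slot trigger_fraction fraction of the acquisition completing the run.
#' @slot trigger_acquisition its acquisition ordinal.
#' @slot contributing data.frame of the sub-threshold run
#'   (`acquisition`, `fraction`, `mqp`).
#' @slot is_followup TRUE for repeat alerts after the initial trigger.
#' @slot suppressed TRUE if muted by the suppression window.
#' @export
setClass("AlertEvent",
  representation(plan_id = "character", trigger_fraction = "integer",
                 trigger_acquisition = "integer", contributing = "data.frame",
                 is_followup = "logical", suppressed = "logical"))

# ---- ConfusionSummary -------------------------------------------------------

#' ConfusionSummary: alert-system performance over a cohort of plans
#'
#' @slot tp,tn,fp,fn integer counts over plans.
#' @slot sensitivity TP/(TP+FN); `NA` when there are no positive plans.
#' @slot false_positive_rate FP/(FP+TN); `NA` when there are no negatives.
#' @export
setClass("ConfusionSummary",
  representation(tp = "integer", tn = "integer", fp = "integer",
                 fn = "integer", sensitivity = "numeric",
                 false_positive_rate = "numeric"))
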