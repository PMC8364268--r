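#' @include mask.R
NULL

#' Phantom specification
#'
#' Describes a head-and-neck-like digital phantom: an ellipsoidal soft-tissue
#' body in air with bone-like and airway-like cylindrical inserts, additive
#' Gaussian HU noise, and optional ring-artifact texture confined to outside
#' the body-plus-margin region (so the evaluation mask can be shown to
#' exclude it). Axes follow the package convention (slice, row, column) =
#' (superior-inferior, anterior-posterior, left-right); half-axes are given
#' in that order, in mm.
#'
#' @param shape integer(3) grid shape (default 64^3).
#' @param spacing numeric(3) voxel size in mm (default 3 mm isotropic).
#' @param body_half_axes numeric(3) ellipsoid half-axes in mm.
#' @param soft_tissue_hu body intensity (default 40 HU).
#' @param air_hu background intensity (default -1000 HU).
#' @param inserts list of cylindrical inserts along the slice axis, each
#'   `list(center = c(row, col) offset from body centre in mm, radius = mm,
#'   hu = value)`.
#' @param noise_sigma marginal sd of the additive Gaussian acquisition
#'   noise, HU (default 20); the noise field carries a ~1 voxel correlation
#'   length, as CBCT noise does.
#' @param artifact_level amplitude of the out-of-body ring texture, HU
#'   (default 50; 0 disables).
#' @param mask_margin_mm margin used for the clearance check and for
#'   artifact placement (default 10).
#' @return a validated list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(shape = c(64, 64, 64), spacing = c(3, 3, 3),
                        body_half_axes = c(70, 60, 75),
                        soft_tissue_hu = 40, air_hu = -1000,
                        inserts = list(
                          list(center = c(25, 0), radius = 12, hu = 700),
                          list(center = c(-30, 0), radius = 8, hu = -1000)),
                        noise_sigma = 20, artifact_level = 50,
                        mask_margin_mm = 10) {
  if (noise_sigma < 0) stopPrecond("noise_sigma must be >= 0")
  extent <- (shape - 1) / 2 * spacing
  clearance <- extent - body_half_axes
  if (any(clearance < mask_margin_mm + 2 * spacing))
    stopPrecond("body does not fit in the grid with margin + 2 voxels ",
                "clearance (shortfall on axis ",
                which.min(clearance - mask_margin_mm - 2 * spacing), ")")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 body_half_axes = as.numeric(body_half_axes),
                 soft_tissue_hu = soft_tissue_hu, air_hu = air_hu,
                 inserts = inserts, noise_sigma = noise_sigma,
                 artifact_level = artifact_level,
                 mask_margin_mm = mask_margin_mm),
            class = "PhantomSpec")
}

#' Treatment-course specification
#'
#' Describes one synthetic course: which fractions receive a CBCT, when
#' progressive tissue regression begins and how fast it proceeds, the
#' per-acquisition random rigid setup offset (recorded as the true
#' transform, so online matching exactly undoes it), and an optional
#' re-plan split. Regression is monotone — tissue never regrows — and is
#' applied to the in-plane (row and column) half-axes, emulating the
#' weight-loss-driven lateral surface recession that dominates clinical
#' anatomy change.
#'
#' @param n_fractions number of treatment fractions (default 30).
#' @param cbct_fractions fractions at which a CBCT is acquired (default
#'   daily, i.e. every fraction).
#' @param onset_fraction fraction at which regression begins (`NA` for a
#'   stable, negative course).
#' @param regression_rate lateral surface recession per fraction, mm.
#' @param setup_jitter_mm maximum per-acquisition rigid offset magnitude,
#'   mm (default 2).
#' @param rotation_jitter_deg maximum per-acquisition rotation about the
#'   slice axis, degrees (default 0).
#' @param max_recession_mm plateau of the total recession depth, mm
#'   (default 10): weight-loss-driven surface change saturates rather than
#'   consuming the neck indefinitely.
#' @param replan_fraction optional fraction at which a re-plan splits the
#'   course into two plans (`NA` for none).
#' @param clinical_change_mm recession depth at which the course counts as
#'   positive (re-CT warranted); a synthetic-cohort convention, default 5.
#' @param seed RNG seed controlling jitter, noise and artifact phases.
#' @return a validated list of class `"CourseSpec"`.
#' @export
courseSpec <- function(n_fractions = 30, cbct_fractions = seq_len(n_fractions),
                       onset_fraction = NA, regression_rate = 0,
                       setup_jitter_mm = 2, rotation_jitter_deg = 0,
                       max_recession_mm = 10, replan_fraction = NA,
                       clinical_change_mm = 5, seed = 1) {
  if (!is.na(onset_fraction) && onset_fraction > n_fractions)
    stopPrecond("onset_fraction must be <= n_fractions")
  if (regression_rate < 0)
    stopPrecond("regression is monotone: regression_rate must be >= 0")
  structure(list(n_fractions = as.integer(n_fractions),
                 cbct_fractions = as.integer(sort(unique(cbct_fractions))),
                 onset_fraction = onset_fraction,
                 regression_rate = regression_rate,
                 setup_jitter_mm = setup_jitter_mm,
                 rotation_jitter_deg = rotation_jitter_deg,
                 max_recession_mm = max_recession_mm,
                 replan_fraction = replan_fraction,
                 clinical_change_mm = clinical_change_mm,
                 seed = as.integer(seed)),
            class = "CourseSpec")
}

# recession depth (mm) at fraction f: linear after onset, saturating
recessionAt <- function(course, f) {
  if (is.na(course$onset_fraction)) return(0 * f)
  pmin(course$regression_rate * pmax(0, f - course$onset_fraction),
       course$max_recession_mm)
}

# physical coordinate grids (mm) for a phantom, centred on the grid
phantomCoords <- function(phantom) {
  sh <- phantom$shape; sp <- phantom$spacing
  lapply(1:3, function(a) (seq_len(sh[a]) - 1 - (sh[a] - 1) / 2) * sp[a])
}

phantomOrigin <- function(phantom) {
  -(phantom$shape - 1) / 2 * phantom$spacing
}

# Noise-free anatomy at a given recession depth, optionally rigidly
# displaced (translation mm, rotation deg about the slice axis through the
# body centre). Returns the HU array and the body mask.
phantomAnatomy <- function(phantom, recession = 0, translation = c(0, 0, 0),
                           rotation_deg = 0) {
  ax <- phantom$body_half_axes - c(0, recession, recession)
  if (any(ax <= 0))
    stopPrecond("regression has consumed the body (non-positive half-axis)")
  cc <- phantomCoords(phantom)
  sh <- phantom$shape
  # anatomy-frame coordinates: u = Rj^T (p - t), rotation about body centre
  p1 <- cc[[1]] - translation[1]
  u2 <- outer(cc[[2]] - translation[2], rep(1, sh[3]))
  u3 <- outer(rep(1, sh[2]), cc[[3]] - translation[3])
  if (rotation_deg != 0) {
    th <- rotation_deg * pi / 180
    r2 <- cos(th) * u2 + sin(th) * u3
    r3 <- -sin(th) * u2 + cos(th) * u3
    u2 <- r2; u3 <- r3
  }
  hu <- array(phantom$air_hu, sh)
  body <- array(FALSE, sh)
  inplane_body <- (u2 / ax[2])^2 + (u3 / ax[3])^2   # shared across slices
  insides <- lapply(phantom$inserts, function(ins)
    (u2 - ins$center[1])^2 + (u3 - ins$center[2])^2 <= ins$radius^2)
  for (i in seq_len(sh[1])) {
    b <- inplane_body + (p1[i] / ax[1])^2 <= 1
    body[i, , ] <- b
    sl <- ifelse(b, phantom$soft_tissue_hu, phantom$air_hu)
    for (q in seq_along(insides))
      sl[b & insides[[q]]] <- phantom$inserts[[q]]$hu
    hu[i, , ] <- sl
  }
  list(hu = hu, body = body)
}

# Spatially correlated acquisition noise (~1 voxel correlation length):
# white noise smoothed per axis with a (1/4, 1/2, 1/4) kernel and rescaled
# to the requested marginal sd. CBCT noise is correlated, and correlated
# noise keeps its amplitude under the subvoxel interpolation of the online
# match, so acquisition-to-acquisition match quality stays comparable.
correlatedNoise <- function(shape, sigma) {
  a <- array(rnorm(prod(shape)), shape)
  shiftRep <- function(x, axis, by) {
    n <- dim(x)[axis]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    switch(axis, x[src, , , drop = FALSE], x[, src, , drop = FALSE],
           x[, , src, drop = FALSE])
  }
  for (ax in 1:3)
    a <- 0.5 * a + 0.25 * (shiftRep(a, ax, 1L) + shiftRep(a, ax, -1L))
  a * (sigma / sqrt(0.375)^3)
}

# ring-artifact texture outside the body + margin region
phantomArtifacts <- function(phantom, outside, phase) {
  if (phantom$artifact_level == 0) return(0)
  cc <- phantomCoords(phantom)
  sh <- phantom$shape
  r <- sqrt(outer(cc[[2]]^2, rep(1, sh[3])) + outer(rep(1, sh[2]), cc[[3]]^2))
  ring <- phantom$artifact_level * sin(2 * pi * r / 20 + phase)
  art <- array(0, sh)
  for (i in seq_len(sh[1])) art[i, , ] <- ring
  art * outside
}

#' Generate a synthetic CBCT treatment course with known ground truth
#'
#' Builds one CBCT volume per scheduled fraction: the phantom body's
#' in-plane half-axes shrink by `regression_rate * max(0, f - onset)` mm at
#' fraction f; each acquisition gets an independent random rigid setup
#' offset whose exact inverse is recorded as the registration transform;
#' Gaussian noise and (optionally) ring artifacts outside the body + margin
#' are added after geometry. The planning external contour is the
#' unshrunk, undisplaced body mask. An optional re-plan fraction splits the
#' course into two plans, the second with a fresh external contour from the
#' anatomy at the re-plan fraction (so its MQP series restarts at zero).
#'
#' The ground-truth record labels a plan positive when its total recession
#' reaches `clinical_change_mm` (default 5 mm), with the re-CT decision
#' fraction defined as the first fraction at which that depth is reached.
#'
#' @param phantom a [phantomSpec()].
#' @param course a [courseSpec()].
#' @param plan_id base plan identifier.
#' @return a list of plan records, each a list with elements `plan_id`,
#'   `volumes` (list of [VolumeGrid-class]), `fractions`, `transforms`
#'   (list of [RigidTransform-class]), `usable`, `external_mask`
#'   ([MaskVolume-class], undilated external contour), and `ground_truth`
#'   (`label`, `rect_fraction`, `positive_subtype`, `onset_fraction`,
#'   `regression_rate`, `recession_mm` per acquisition).
#' @examples
#' ph <- phantomSpec(shape = c(24, 24, 24), spacing = c(6, 6, 6),
#'                   body_half_axes = c(40, 35, 40), noise_sigma = 0,
#'                   artifact_level = 0)
#' cs <- courseSpec(n_fractions = 4, setup_jitter_mm = 0)
#' plans <- generateCourse(ph, cs)
#' length(plans[[1]]$volumes)
#' @export
generateCourse <- function(phantom, course, plan_id = "plan") {
  stopifnot(inherits(phantom, "PhantomSpec"), inherits(course, "CourseSpec"))
  fr <- course$cbct_fractions
  fr <- fr[fr <= course$n_fractions]
  origin <- phantomOrigin(phantom)

  planning_mask <- function(recession) {
    an <- phantomAnatomy(phantom, recession)
    maskVolume(an$body, phantom$spacing, origin,
               provenance = "external_contour")
  }

  # artifact region: outside planning body + margin, fixed for the course
  # (the body only shrinks, so artifacts never re-enter the patient volume)
  outside <- NULL
  if (phantom$artifact_level > 0) {
    planning <- phantomAnatomy(phantom, 0)
    outside <- !maskFromExternal(
      maskVolume(planning$body, phantom$spacing, origin),
      phantom$mask_margin_mm)@data
  }

  withSeed(course$seed, {
    vols <- vector("list", length(fr))
    trs <- vector("list", length(fr))
    for (q in seq_along(fr)) {
      f <- fr[q]
      # setup offset: random direction, magnitude uniform in [0, jitter]
      if (course$setup_jitter_mm > 0) {
        dirv <- rnorm(3)
        t_mm <- dirv / sqrt(sum(dirv^2)) * runif(1, 0, course$setup_jitter_mm)
      } else t_mm <- c(0, 0, 0)
      rot_deg <- if (course$rotation_jitter_deg > 0)
        runif(1, -course$rotation_jitter_deg, course$rotation_jitter_deg)
        else 0
      an <- phantomAnatomy(phantom, recessionAt(course, f), t_mm, rot_deg)
      hu <- an$hu
      if (phantom$artifact_level > 0)
        hu <- hu + phantomArtifacts(phantom, outside, runif(1, 0, 2 * pi))
      if (phantom$noise_sigma > 0)
        hu <- hu + correlatedNoise(phantom$shape, phantom$noise_sigma)
      vols[[q]] <- volumeGrid(hu, phantom$spacing, origin)
      # anatomy was displaced by t and rotated; the recorded transform maps
      # the moving acquisition back into the planning frame
      if (rot_deg != 0) {
        th <- -rot_deg * pi / 180  # inverse rotation
        Rj <- diag(3)
        Rj[2:3, 2:3] <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                               byrow = TRUE)
        trs[[q]] <- rigidTransform(Rj, as.numeric(-Rj %*% t_mm),
                                   "moving_to_reference")
      } else {
        trs[[q]] <- rigidTransform(translation = -t_mm,
                                   direction = "moving_to_reference")
      }
    }
  })

  groundTruth <- function(fr_sub, onset_shift_mm, plan_fr_last) {
    rec <- recessionAt(course, fr_sub) - onset_shift_mm
    rec <- pmax(rec, 0)
    total <- max(recessionAt(course, plan_fr_last) - onset_shift_mm, 0)
    positive <- total >= course$clinical_change_mm
    rect <- NA_integer_
    subtype <- NA_character_
    if (positive) {
      rect_depth <- course$clinical_change_mm + onset_shift_mm
      rect <- as.integer(ceiling(course$onset_fraction +
                                   rect_depth / course$regression_rate))
      subtype <- if (rect > course$n_fractions - 5) "too_late" else "actual_rect"
    }
    list(label = if (positive) "positive" else "negative",
         rect_fraction = rect, positive_subtype = subtype,
         onset_fraction = course$onset_fraction,
         regression_rate = course$regression_rate, recession_mm = rec)
  }

  mkPlan <- function(id, idx, onset_shift_mm, mask_recession) {
    fr_sub <- fr[idx]
    list(plan_id = id, volumes = vols[idx], fractions = fr_sub,
         transforms = trs[idx], usable = rep(TRUE, length(idx)),
         external_mask = planning_mask(mask_recession),
         ground_truth = groundTruth(fr_sub, onset_shift_mm,
                                    max(fr_sub)))
  }

  if (is.na(course$replan_fraction)) {
    list(mkPlan(plan_id, seq_along(fr), 0, 0))
  } else {
    i1 <- which(fr < course$replan_fraction)
    i2 <- which(fr >= course$replan_fraction)
    if (length(i1) < 2 || length(i2) < 2)
      stopPrecond("replan split leaves a plan with < 2 CBCTs")
    shift2 <- recessionAt(course, course$replan_fraction)
    list(mkPlan(plan_id, i1, 0, 0),
         mkPlan(paste0(plan_id, "-R1"), i2, shift2, shift2))
  }
}

#' Run the full comparison pipeline on one generated plan
#'
#' Dilates the plan's external contour by the evaluation margin, applies
#' the recorded registrations and compares every CBCT against the plan's
#' reference CBCT.
#'
#' @param plan one plan record from [generateCourse()].
#' @param criteria a [GammaCriteria-class].
#' @param mask_margin_mm evaluation-mask margin, mm (default 10).
#' @return a [CourseComparison-class].
#' @export
comparePlan <- function(plan, criteria = gammaCriteria(),
                        mask_margin_mm = 10) {
  usable <- plan$usable
  compareCourse(plan$volumes[usable], plan$fractions[usable],
                maskFromExternal(plan$external_mask, mask_margin_mm),
                plan$transforms[usable], criteria, plan$plan_id)
}
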