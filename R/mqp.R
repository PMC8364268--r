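#' @include gamma.R
NULL

#' Match quality parameter
#'
#' `MQP = gamma_ref - gamma_i`: the difference between the xth failed-voxel
#' gamma percentile of the reference match and that of the current match.
#' Negative values mean the current CBCT matches the reference CBCT worse
#' than the reference match did.
#'
#' @param gamma_ref reference-match percentile gamma value.
#' @param gamma_i current-match percentile gamma value.
#' @return the MQP (dimensionless).
#' @export
computeMqp <- function(gamma_ref, gamma_i) {
  if (!is.finite(gamma_ref) || !is.finite(gamma_i))
    stopPrecond("gamma values must be finite")
  gamma_ref - gamma_i
}

#' Compare every usable CBCT of a plan against the plan's reference CBCT
#'
#' The earliest usable CBCT (entry 0) is the reference. Every later usable
#' CBCT is rigidly resampled into the frame of the mask grid (using its
#' online-match transform, when given), as is the reference itself, and the
#' masked gamma map is computed. Only the failed-voxel gamma values are
#' kept per comparison, so MQP series at any percentile can be formed later
#' without recomputing gamma maps.
#'
#' @param volumes list of [VolumeGrid-class], in acquisition order
#'   (reference first); at least 2.
#' @param fractions integer treatment-fraction numbers, one per volume,
#'   strictly increasing.
#' @param mask the evaluation [MaskVolume-class] (external contour + margin)
#'   whose grid defines the comparison frame.
#' @param transforms optional list of [RigidTransform-class] (or `NULL`
#'   entries), one per volume, mapping each acquisition into the mask frame.
#' @param criteria a [GammaCriteria-class].
#' @param plan_id plan identifier.
#' @param fill_value HU used outside the moving extent when resampling.
#' @return a [CourseComparison-class] with one entry per non-reference
#'   acquisition (entry 1 is the reference match).
#' @export
compareCourse <- function(volumes, fractions, mask, transforms = NULL,
                          criteria = gammaCriteria(), plan_id = "plan",
                          fill_value = -1000) {
  n <- length(volumes)
  if (n < 2)
    stopPrecond("plan ", plan_id, ": needs at least 2 usable CBCTs, got ", n)
  if (length(fractions) != n)
    stopPrecond("plan ", plan_id, ": fractions must match volumes")
  if (any(diff(fractions) <= 0))
    stopPrecond("plan ", plan_id, ": fractions must be strictly increasing")
  if (is.null(transforms)) transforms <- vector("list", n)

  grid <- volumeGrid(array(0, dim(mask@data)), mask@spacing, mask@origin)
  align <- function(i) {
    v <- volumes[[i]]
    tr <- transforms[[i]]
    resampleOnto(v, grid, tr, fill_value = fill_value)
  }
  ref <- align(1)
  failed <- vector("list", n - 1)
  nev <- integer(n - 1)
  for (i in 2:n) {
    g <- computeGamma(ref, align(i), mask, criteria)
    failed[[i - 1]] <- g@failed_values
    nev[i - 1] <- g@n_evaluated
  }
  new("CourseComparison", plan_id = as.character(plan_id),
      ref_fraction = as.integer(fractions[1]),
      fractions = as.integer(fractions[-1]),
      acquisitions = as.integer(2:n), failed_values = failed,
      n_evaluated = nev, criteria = criteria)
}

#' MQP series from a course comparison
#'
#' Takes the xth percentile of each stored failed-voxel multiset and
#' subtracts it from the reference match's percentile. The first entry (the
#' reference match against itself) is exactly zero.
#'
#' @param comparison a [CourseComparison-class].
#' @param x percentile in (0, 100); default 80.
#' @return an [MqpSeries-class].
#' @export
mqpSeries <- function(comparison, x = 80) {
  stopifnot(is(comparison, "CourseComparison"))
  g <- vapply(comparison@failed_values, failedPercentile, numeric(1),
              percentile = x)
  gref <- g[1]
  mqp <- gref - g
  mqp[1] <- 0  # reference match: zero by definition
  new("MqpSeries", plan_id = comparison@plan_id, x = as.numeric(x),
      gamma_ref = gref,
      entries = data.frame(acquisition = comparison@acquisitions,
                           fraction = comparison@fractions, mqp = mqp))
}

#' One-call MQP series for a plan
#'
#' Convenience wrapper chaining [compareCourse()] and [mqpSeries()].
#'
#' @inheritParams compareCourse
#' @param x percentile of the failed-voxel histogram (default 80).
#' @return an [MqpSeries-class].
#' @export
buildSeries <- function(volumes, fractions, mask, transforms = NULL,
                        criteria = gammaCriteria(), x = 80,
                        plan_id = "plan") {
  mqpSeries(compareCourse(volumes, fractions, mask, transforms, criteria,
                          plan_id), x)
}

# ---- alert trigger ----------------------------------------------------------

runScan <- function(mqp, threshold, need) {
  # index completing each run of `need` consecutive entries strictly below
  # threshold; returns all completing indices in order
  below <- mqp < threshold
  run <- 0L
  hits <- integer(0)
  for (i in seq_along(below)) {
    run <- if (below[i]) run + 1L else 0L
    if (run >= need) hits <- c(hits, i)
  }
  hits
}

#' Detect the first anatomy-change alert in an MQP series
#'
#' Scans acquisitions in order and triggers at the first acquisition
#' completing `consecutive_required` consecutive entries with MQP strictly
#' below the threshold (an entry at or above the threshold resets the run;
#' runs never span a re-plan boundary because a re-plan starts a new
#' series). Returns `NULL` when the condition never holds.
#'
#' @param series an [MqpSeries-class].
#' @param config an [AlertConfig-class].
#' @return an [AlertEvent-class], or `NULL`.
#' @export
setMethod("detectAlert", "MqpSeries", function(series, config = alertConfig()) {
  ev <- alertEvents(series, config)
  if (length(ev) == 0) NULL else ev[[1]]
})

#' All alert events of an MQP series
#'
#' The first event is the initial trigger; every later acquisition whose
#' MQP is below the threshold is reported as a follow-up event (an audit
#' trail for repeat alerts), flagged suppressed when it falls beyond the
#' configured mute fraction.
#'
#' @param series an [MqpSeries-class].
#' @param config an [AlertConfig-class].
#' @return a list of [AlertEvent-class] objects (possibly empty).
#' @export
setMethod("alertEvents", "MqpSeries", function(series, config = alertConfig()) {
  e <- series@entries
  hits <- runScan(e$mqp, config@threshold, config@consecutive_required)
  if (length(hits) == 0) return(list())
  first <- hits[1]
  need <- config@consecutive_required
  mkEvent <- function(i, followup) {
    contrib <- if (followup) e[i, , drop = FALSE]
               else e[(i - need + 1):i, , drop = FALSE]
    new("AlertEvent", plan_id = series@plan_id,
        trigger_fraction = as.integer(e$fraction[i]),
        trigger_acquisition = as.integer(e$acquisition[i]),
        contributing = contrib, is_followup = followup,
        suppressed = followup && e$fraction[i] > config@mute_after_fraction)
  }
  events <- list(mkEvent(first, FALSE))
  later <- which(e$mqp < config@threshold)
  later <- later[later > first]
  c(events, lapply(later, mkEvent, followup = TRUE))
})

# ---- series / comparison files ---------------------------------------------

#' Write an MQP series as delimited text
#'
#' Tab-separated columns `fraction`, `acquisition`, `mqp` (the axes of the
#' per-plan MQP plot), with the plan id, percentile and reference gamma in
#' comment headers.
#'
#' @param series an [MqpSeries-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeMqpSeries <- function(series, path) {
  stopifnot(is(series, "MqpSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# plan_id: %s", series@plan_id),
               sprintf("# x: %.17g", series@x),
               sprintf("# gamma_ref: %.17g", series@gamma_ref),
               "fraction\tacquisition\tmqp"), con)
  e <- series@entries
  writeLines(sprintf("%d\t%d\t%.17g", e$fraction, e$acquisition, e$mqp), con)
  invisible(path)
}

#' Write / read a course comparison (failed gamma values per acquisition)
#'
#' Long-format tab-separated text: columns `acquisition`, `fraction`,
#' `gamma`, one row per failed voxel, with plan metadata in comment
#' headers. This is the persistent form that lets MQP series be rebuilt at
#' any percentile without touching image data again.
#'
#' @param comparison a [CourseComparison-class].
#' @param path file path.
#' @return `readCourseComparison()` returns a [CourseComparison-class].
#' @export
writeCourseComparison <- function(comparison, path) {
  stopifnot(is(comparison, "CourseComparison"))
  con <- file(path, "w")
  on.exit(close(con))
  cr <- comparison@criteria
  writeLines(c(sprintf("# plan_id: %s", comparison@plan_id),
               sprintf("# ref_fraction: %d", comparison@ref_fraction),
               sprintf("# criteria: dta_mm=%.17g delta_hu=%.17g", cr@dta_mm,
                       cr@delta_hu),
               sprintf("# n_evaluated: %s",
                       paste(comparison@n_evaluated, collapse = " ")),
               sprintf("# entries: %s",
                       paste(sprintf("%d:%d", comparison@acquisitions,
                                     comparison@fractions), collapse = " ")),
               "acquisition\tfraction\tgamma"), con)
  for (q in seq_along(comparison@fractions)) {
    v <- comparison@failed_values[[q]]
    if (length(v))
      writeLines(sprintf("%d\t%d\t%.17g", comparison@acquisitions[q],
                         comparison@fractions[q], v), con)
  }
  invisible(path)
}

#' @rdname writeCourseComparison
#' @export
readCourseComparison <- function(path) {
  if (!file.exists(path)) stopFormat("comparison file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getH <- function(key) {
    ln <- grep(paste0("^# ", key, ": "), hdr, value = TRUE)
    if (length(ln) != 1) stopFormat("comparison file missing header ", key)
    sub(paste0("^# ", key, ": "), "", ln)
  }
  plan_id <- getH("plan_id")
  ref_fraction <- as.integer(getH("ref_fraction"))
  nev <- as.integer(strsplit(getH("n_evaluated"), " ")[[1]])
  ent <- strsplit(strsplit(getH("entries"), " ")[[1]], ":")
  acqs <- vapply(ent, function(z) as.integer(z[1]), integer(1))
  fracs <- vapply(ent, function(z) as.integer(z[2]), integer(1))
  body <- lines[!grepl("^#", lines)][-1]
  failed <- rep(list(numeric(0)), length(acqs))
  if (length(body)) {
    parts <- read.delim(text = body, header = FALSE,
                        col.names = c("acquisition", "fraction", "gamma"))
    for (q in seq_along(acqs))
      failed[[q]] <- parts$gamma[parts$acquisition == acqs[q]]
  }
  new("CourseComparison", plan_id = plan_id, ref_fraction = ref_fraction,
      fractions = fracs, acquisitions = acqs, failed_values = failed,
      n_evaluated = nev, criteria = gammaCriteria())
}
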