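#' @include phantom.R evaluation.R
NULL

#' Default parameter ranges for synthetic cohorts
#'
#' Positive courses draw a regression onset uniformly over
#' `onset_fraction` and a recession rate over `regression_rate`
#' (mm/fraction); negative courses have no regression (stable anatomy,
#' noise and setup jitter only).
#'
#' @param onset_fraction integer range for the regression onset.
#' @param regression_rate numeric range for the recession rate.
#' @param n_fractions course length.
#' @return a list of ranges consumed by [generateCohort()].
#' @export
cohortRanges <- function(onset_fraction = c(8, 18),
                         regression_rate = c(0.8, 1.5),
                         n_fractions = 30) {
  list(onset_fraction = as.integer(unlist(onset_fraction)),
       regression_rate = as.numeric(unlist(regression_rate)),
       n_fractions = as.integer(unlist(n_fractions)))
}

#' Generate a synthetic cohort of treatment courses
#'
#' Draws per-case course parameters from the stated ranges, generates each
#' course, and assembles the case annotations. Deterministic given
#' `seed`. With `out_dir` set, everything is written to disk (research
#' volumes, transform files, external masks, a plan manifest and the
#' annotations file) and repeated runs with the same seed produce
#' byte-identical manifests.
#'
#' @param n_positive,n_negative numbers of positive and negative courses.
#' @param phantom a [phantomSpec()].
#' @param ranges parameter ranges from [cohortRanges()].
#' @param seed master RNG seed.
#' @param out_dir optional output directory.
#' @return a list with `plans` (list of plan records, see
#'   [generateCourse()]), `cases` (annotation data.frame) and, when
#'   written, `manifest` and `annotations` file paths.
#' @export
generateCohort <- function(n_positive, n_negative, phantom = phantomSpec(),
                           ranges = cohortRanges(), seed = 1,
                           out_dir = NULL) {
  stopifnot(n_positive >= 0, n_negative >= 0)
  n <- n_positive + n_negative
  seeds <- deriveSeeds(seed, n + 1)
  params <- withSeed(seeds[n + 1], {
    lapply(seq_len(n), function(q) {
      if (q <= n_positive)
        list(onset = sample(ranges$onset_fraction[1]:ranges$onset_fraction[2], 1),
             rate = runif(1, ranges$regression_rate[1],
                          ranges$regression_rate[2]))
      else list(onset = NA, rate = 0)
    })
  })
  plans <- list()
  for (q in seq_len(n)) {
    id <- sprintf("case%03d", q)
    cs <- courseSpec(n_fractions = ranges$n_fractions,
                     onset_fraction = params[[q]]$onset,
                     regression_rate = params[[q]]$rate,
                     seed = seeds[q])
    plans <- c(plans, generateCourse(phantom, cs, plan_id = id))
  }
  names(plans) <- vapply(plans, `[[`, character(1), "plan_id")
  cases <- do.call(rbind, lapply(plans, function(p)
    data.frame(plan_id = p$plan_id, label = p$ground_truth$label,
               rect_fraction = p$ground_truth$rect_fraction,
               positive_subtype = p$ground_truth$positive_subtype,
               rt_review_fraction = NA_integer_)))
  rownames(cases) <- NULL
  out <- list(plans = plans, cases = cases)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    manifest <- do.call(rbind, lapply(plans, writeCourse, dir = out_dir))
    mpath <- file.path(out_dir, "manifest.tsv")
    writeManifest(manifest, mpath)
    apath <- file.path(out_dir, "annotations.tsv")
    writeCaseAnnotations(cases, apath,
      comment = paste("synthetic cohort; positive label convention: total",
                      "lateral recession >= 5 mm"))
    out$manifest <- mpath
    out$annotations <- apath
  }
  out
}

#' Write one generated plan to disk
#'
#' Writes each acquisition's volume (research pair) and transform (plain
#' text) plus the plan's external contour mask, and returns the manifest
#' rows describing them (paths relative to `dir`).
#'
#' @param plan a plan record from [generateCourse()].
#' @param dir output directory.
#' @return a manifest data.frame (one row per acquisition).
#' @export
writeCourse <- function(plan, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  id <- plan$plan_id
  maskrel <- sprintf("%s_external", id)
  saveMask(plan$external_mask, file.path(dir, maskrel))
  rows <- lapply(seq_along(plan$volumes), function(q) {
    volrel <- sprintf("%s_f%02d_vol", id, plan$fractions[q])
    trrel <- sprintf("%s_f%02d_reg.txt", id, plan$fractions[q])
    saveVolume(plan$volumes[[q]], file.path(dir, volrel))
    saveTransform(plan$transforms[[q]], file.path(dir, trrel))
    data.frame(plan_id = id, acquisition = q,
               fraction = plan$fractions[q],
               usable = plan$usable[q], volume = volrel,
               transform = trrel, mask = maskrel)
  })
  do.call(rbind, rows)
}
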