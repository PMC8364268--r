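#' @include AllGenerics.R
NULL

#' Masked 3D global gamma-index comparison of two volumes
#'
#' Computes, at every masked voxel r of the reference volume, the global
#' gamma index
#' \deqn{\gamma(r) = \min_{r'} \sqrt{|r'-r|^2/\mathrm{DTA}^2 +
#'   (I_e(r') - I_r(r))^2/\Delta^2}}
#' where the minimisation runs over a sphere of radius `search_radius_mm`
#' around r, sampled on a regular lattice of pitch `interp_step_mm` with
#' trilinear interpolation of the evaluated volume (global method: the
#' intensity denominator is the fixed `delta_hu`, never a local
#' percentage). With `interp_step_mm = 0` the search visits integer voxel
#' offsets only — the exact discretisation used by the brute-force oracle.
#' Candidates are scanned in order of increasing distance, so the search
#' stops as soon as the distance term alone exceeds the running minimum.
#'
#' Masked voxels whose reference intensity is non-finite (e.g. outside a
#' limited field of view) are excluded from evaluation and from
#' `nEvaluated()`, with the count recorded in the result.
#'
#' @param reference,evaluated [VolumeGrid-class] objects on one common grid
#'   (resample first if needed).
#' @param mask a non-empty [MaskVolume-class] on the same grid.
#' @param criteria a [GammaCriteria-class] (default 3 mm / 30 HU).
#' @return a [GammaResult-class].
#' @examples
#' v <- volumeGrid(array(rnorm(64, sd = 10), c(4, 4, 4)))
#' m <- maskVolume(array(TRUE, c(4, 4, 4)))
#' g <- computeGamma(v, v, m)          # identical volumes: gamma == 0
#' range(voxelData(g))
#' @export
computeGamma <- function(reference, evaluated, mask,
                         criteria = gammaCriteria()) {
  stopifnot(is(reference, "VolumeGrid"), is(evaluated, "VolumeGrid"),
            is(mask, "MaskVolume"), is(criteria, "GammaCriteria"))
  sameGrid <- function(a, b)
    identical(dim(voxelData(a)), dim(voxelData(b))) &&
      max(abs(voxelSpacing(a) - voxelSpacing(b))) < 1e-9 &&
      max(abs(voxelOrigin(a) - voxelOrigin(b))) < 1e-9
  if (!sameGrid(reference, evaluated) || !sameGrid(reference, mask))
    stopPrecond("reference, evaluated and mask must share one grid")
  if (!any(mask@data)) stopPrecond("mask is empty")

  sp <- reference@spacing
  step <- criteria@interp_step_mm
  if (is.na(step)) step <- min(sp) / 3
  if (step > 0 && step > min(sp) / 2)
    stopPrecond("interp_step_mm must be <= min(spacing)/2")

  ref <- reference@data
  finite_ref <- is.finite(ref)
  eff_mask <- mask@data & finite_ref
  n_excluded <- sum(mask@data & !finite_ref)
  if (n_excluded > 0)
    message(sprintf("computeGamma: excluded %d non-finite masked voxels",
                    n_excluded))

  g <- .gamma_kernel(as.vector(ref), as.vector(evaluated@data),
                     as.vector(eff_mask), dim(ref), sp,
                     criteria@dta_mm, criteria@delta_hu,
                     criteria@search_radius_mm, step)
  g <- array(g, dim(ref))
  vals <- g[eff_mask]
  new("GammaResult", gamma = g, mask = mask,
      failed_values = as.numeric(vals[vals > 1]),
      n_evaluated = sum(eff_mask), n_excluded = as.integer(n_excluded),
      criteria = criteria)
}

#' Percentile of the failed-voxel gamma histogram
#'
#' Returns the empirical xth percentile (linear interpolation between order
#' statistics, the bin-free limit of the histogram-based definition) of the
#' gamma values > 1 inside the mask. When no voxel failed, returns the
#' sentinel 1.0 — the pass/fail boundary — so a perfect match can never pull
#' the MQP below an alert threshold.
#'
#' @param x a [GammaResult-class] or a numeric vector of failed gamma values.
#' @param percentile percentile in (0, 100); default 80.
#' @return a single gamma value (dimensionless).
#' @export
setMethod("failedPercentile", "GammaResult", function(x, percentile = 80) {
  failedPercentile(x@failed_values, percentile)
})

#' @rdname failedPercentile
#' @export
setMethod("failedPercentile", "numeric", function(x, percentile = 80) {
  if (percentile <= 0 || percentile >= 100)
    stopPrecond("percentile must be in (0, 100)")
  if (length(x) == 0) return(1.0)
  unname(quantile(x, percentile / 100, type = 7, names = FALSE))
})

#' Export a gamma map as a research-format volume
#'
#' Writes the gamma values as float64 with `NaN` at unmasked/excluded
#' voxels, on the same grid as the inputs.
#'
#' @param result a [GammaResult-class].
#' @param path base path of the `.json`/`.raw` pair.
#' @return invisibly, the written paths.
#' @export
writeGammaVolume <- function(result, path) {
  stopifnot(is(result, "GammaResult"))
  g <- result@gamma
  g[is.na(g)] <- NaN
  writeResearchPair(g, result@mask@spacing, result@mask@origin, path,
                    "float64", extra = list(content = "gamma"))
}

#' Export the failed-voxel histogram as delimited text
#'
#' Two tab-separated columns (bin centre, count) over equal-width bins of
#' the failed gamma values, for plotting.
#'
#' @param result a [GammaResult-class].
#' @param path output file.
#' @param bin_width histogram bin width in gamma units (default 0.05).
#' @return invisibly, the written path.
#' @export
writeFailedHistogram <- function(result, path, bin_width = 0.05) {
  stopifnot(is(result, "GammaResult"))
  v <- result@failed_values
  if (length(v) == 0) {
    writeLines("bin_center\tcount", path)
    return(invisible(path))
  }
  breaks <- seq(1, max(v) + bin_width, by = bin_width)
  h <- hist(v, breaks = breaks, plot = FALSE)
  write.table(data.frame(bin_center = h$mids, count = h$counts),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
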