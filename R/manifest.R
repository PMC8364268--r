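#' @include cohort.R
NULL

#' Read and write plan manifests
#'
#' A plan manifest is tab-separated text listing, per CBCT acquisition:
#' `plan_id`, `acquisition` (ordinal), `fraction` (treatment fraction
#' number), `usable` (TRUE/FALSE flag supplied by the caller — the tool
#' does not judge usability), `volume` (research volume base path),
#' `transform` (plain-text rigid transform path, empty for identity) and
#' `mask` (the plan's external-contour mask base path). Paths are relative
#' to the manifest's directory. Plan boundaries (re-plans) are expressed by
#' distinct `plan_id`s.
#'
#' @param path manifest file path.
#' @param manifest manifest data.frame.
#' @return `readManifest()` returns the manifest data.frame.
#' @export
readManifest <- function(path) {
  if (!file.exists(path)) stopFormat("manifest not found: ", path)
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("plan_id", "acquisition", "fraction", "usable", "volume",
            "transform", "mask")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopFormat("manifest ", path, " missing column(s): ",
               paste(miss, collapse = ", "))
  if (nrow(df) == 0) stopFormat("manifest is empty: ", path)
  df$usable <- as.logical(df$usable)
  df
}

#' @rdname readManifest
#' @export
writeManifest <- function(manifest, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# cbctalert plan manifest", con)
  write.table(manifest, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Track MQP series for every plan in a manifest
#'
#' Loads each plan's usable CBCTs, transforms and external mask, dilates
#' the mask by the evaluation margin, runs the gamma comparisons against
#' each plan's reference CBCT, and returns the course comparisons (from
#' which MQP series at any percentile follow without recomputation).
#'
#' @param manifest a manifest data.frame or file path.
#' @param base_dir directory that manifest paths are relative to (defaults
#'   to the manifest file's directory).
#' @param criteria a [GammaCriteria-class].
#' @param mask_margin_mm evaluation-mask margin in mm (default 10).
#' @return named list of [CourseComparison-class], one per plan.
#' @export
trackManifest <- function(manifest, base_dir = NULL,
                          criteria = gammaCriteria(), mask_margin_mm = 10) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- readManifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  out <- list()
  for (pid in unique(manifest$plan_id)) {
    rows <- manifest[manifest$plan_id == pid & manifest$usable, , drop = FALSE]
    rows <- rows[order(rows$fraction), , drop = FALSE]
    if (nrow(rows) < 2)
      stopPrecond("plan ", pid, ": needs at least 2 usable CBCTs, got ",
                  nrow(rows))
    vols <- lapply(file.path(base_dir, rows$volume), loadVolume,
                   format = "research")
    trs <- lapply(rows$transform, function(p)
      if (is.na(p) || p == "") NULL else loadTransform(file.path(base_dir, p)))
    mask <- maskFromExternal(loadMask(file.path(base_dir, rows$mask[1])),
                             mask_margin_mm)
    out[[pid]] <- compareCourse(vols, rows$fraction, mask, trs, criteria,
                                plan_id = pid)
  }
  out
}
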