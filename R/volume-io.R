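#' @include AllClasses.R
NULL

# Research volume format: a two-file pair <base>.json (sidecar metadata:
# dims, spacing, origin, dtype) + <base>.raw (little-endian voxel data,
# column-major in (slice, row, column) order). float64 round-trips
# bit-exactly; masks use uint8.

researchBase <- function(path) sub("\\.(json|raw)$", "", path)

writeResearchPair <- function(arr, spacing, origin, path, dtype,
                              extra = list()) {
  base <- researchBase(path)
  # sidecar written by hand so doubles carry 17 significant digits and the
  # save/load round trip is bit-stable
  nums <- function(x) paste(sprintf("%.17g", x), collapse = ", ")
  fields <- c(
    '"format": "cbctalert-volume-v1"',
    sprintf('"dims": [%s]', paste(dim(arr), collapse = ", ")),
    sprintf('"spacing": [%s]', nums(spacing)),
    sprintf('"origin": [%s]', nums(origin)),
    sprintf('"dtype": "%s"', dtype),
    '"axes_order": "slice,row,column"',
    vapply(names(extra), function(k)
      sprintf('"%s": "%s"', k, extra[[k]]), character(1)))
  writeLines(paste0("{\n  ", paste(fields, collapse = ",\n  "), "\n}"),
             paste0(base, ".json"))
  con <- file(paste0(base, ".raw"), "wb")
  on.exit(close(con))
  if (dtype == "float64") {
    writeBin(as.vector(arr), con, size = 8, endian = "little")
  } else if (dtype == "uint8") {
    writeBin(as.raw(as.integer(arr)), con)
  } else stopFormat("unsupported dtype: ", dtype)
  invisible(paste0(base, c(".json", ".raw")))
}

readResearchPair <- function(path) {
  base <- researchBase(path)
  sidecar <- paste0(base, ".json")
  rawfile <- paste0(base, ".raw")
  if (!file.exists(sidecar)) stopFormat("sidecar not found: ", sidecar)
  if (!file.exists(rawfile)) stopFormat("raw file not found: ", rawfile)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$format, "cbctalert-volume-v1"))
    stopFormat("not a research volume sidecar: ", sidecar)
  dims <- as.integer(meta$dims)
  n <- prod(dims)
  con <- file(rawfile, "rb")
  on.exit(close(con))
  vals <- switch(meta$dtype,
    float64 = readBin(con, "double", n = n, size = 8, endian = "little"),
    uint8 = as.integer(readBin(con, "raw", n = n)),
    stopFormat("unsupported dtype in sidecar: ", meta$dtype))
  if (length(vals) != n)
    stopFormat("raw file ", rawfile, " has ", length(vals),
               " voxels, sidecar declares ", n)
  list(data = array(vals, dims), spacing = as.numeric(meta$spacing),
       origin = as.numeric(meta$origin), meta = meta)
}

#' Save and load volumes
#'
#' `saveVolume()` writes a [VolumeGrid-class] as the research two-file pair
#' `<base>.json` + `<base>.raw` (bit-stable round trip). `loadVolume()`
#' reads either that pair or a DICOM CT series directory.
#'
#' @param volume a [VolumeGrid-class].
#' @param path for research format, the base path or either file of the
#'   pair; for `format = "dicom_series"`, the series directory.
#' @param format `"auto"` (directory implies DICOM), `"research"` or
#'   `"dicom_series"`.
#' @return `loadVolume()` returns a [VolumeGrid-class]; `saveVolume()`
#'   invisibly returns the written paths.
#' @examples
#' v <- volumeGrid(array(seq_len(64), c(4, 4, 4)), spacing = c(2, 1, 1))
#' p <- file.path(tempdir(), "ramp")
#' saveVolume(v, p)
#' identical(voxelData(loadVolume(p)), voxelData(v))
#' @export
saveVolume <- function(volume, path) {
  stopifnot(is(volume, "VolumeGrid"))
  writeResearchPair(volume@data, volume@spacing, volume@origin, path,
                    "float64")
}

#' @rdname saveVolume
#' @export
loadVolume <- function(path, format = c("auto", "research", "dicom_series")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "research"
  if (format == "dicom_series") return(readDicomSeries(path))
  p <- readResearchPair(path)
  if (anyNA(p$data) || any(!is.finite(p$data)))
    stopFormat("volume ", path, " contains non-finite voxels")
  volumeGrid(p$data, p$spacing, p$origin)
}

#' Save and load binary masks (research format, uint8)
#'
#' @param mask a [MaskVolume-class].
#' @param path base path (or either file) of the `.json`/`.raw` pair.
#' @return `loadMask()` returns a [MaskVolume-class].
#' @export
saveMask <- function(mask, path) {
  stopifnot(is(mask, "MaskVolume"))
  writeResearchPair(mask@data, mask@spacing, mask@origin, path, "uint8",
                    extra = list(provenance = mask@provenance))
}

#' @rdname saveMask
#' @export
loadMask <- function(path) {
  p <- readResearchPair(path)
  prov <- if (!is.null(p$meta$provenance)) p$meta$provenance else "supplied"
  maskVolume(array(p$data != 0, dim(p$data)), p$spacing, p$origin,
             provenance = prov)
}

# ---- rigid transform algebra -----------------------------------------------

#' Apply, invert and compose rigid transforms
#'
#' Points are in mm in array-axis order (slice, row, column).
#' `applyTransform()` maps points `p` to `rotation %*% p + translation`;
#' `invertTransform()` returns the inverse map with the direction flag
#' flipped; `composeTransforms(outer, inner)` returns the map
#' `p -> outer(inner(p))`.
#'
#' @param transform,outer,inner [RigidTransform-class] objects.
#' @param points numeric(3) or an n x 3 matrix of points (mm).
#' @return transformed points, or a new [RigidTransform-class].
#' @export
applyTransform <- function(transform, points) {
  stopifnot(is(transform, "RigidTransform"))
  if (is.null(dim(points))) points <- matrix(points, nrow = 1)
  out <- points %*% t(transform@rotation) +
    matrix(transform@translation, nrow(points), 3, byrow = TRUE)
  if (nrow(out) == 1) as.numeric(out) else out
}

#' @rdname applyTransform
#' @export
invertTransform <- function(transform) {
  stopifnot(is(transform, "RigidTransform"))
  Rt <- t(transform@rotation)
  dir <- if (transform@direction == "moving_to_reference")
    "reference_to_moving" else "moving_to_reference"
  rigidTransform(Rt, -as.numeric(Rt %*% transform@translation), dir)
}

#' @rdname applyTransform
#' @export
composeTransforms <- function(outer, inner) {
  rigidTransform(outer@rotation %*% inner@rotation,
                 as.numeric(outer@rotation %*% inner@translation) +
                   outer@translation,
                 outer@direction)
}

# ---- plain-text transform files --------------------------------------------

#' Save and load rigid transforms as plain text
#'
#' The research transform dialect is a small diffable text file: a header
#' line, the direction flag, the row-major 3x3 rotation and the translation
#' in mm, written at full double precision.
#'
#' @param transform a [RigidTransform-class].
#' @param path file path.
#' @return `loadTransform()` returns a [RigidTransform-class].
#' @export
saveTransform <- function(transform, path) {
  stopifnot(is(transform, "RigidTransform"))
  fmt <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  writeLines(c("cbctalert-transform-v1",
               paste("direction", transform@direction),
               paste("rotation", fmt(t(transform@rotation))),
               paste("translation", fmt(transform@translation))),
             path)
  invisible(path)
}

#' @rdname saveTransform
#' @export
loadTransform <- function(path) {
  if (!file.exists(path)) stopFormat("transform file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 4 || lines[1] != "cbctalert-transform-v1")
    stopFormat("not a research transform file: ", path)
  fields <- function(prefix) {
    ln <- grep(paste0("^", prefix, " "), lines, value = TRUE)
    if (length(ln) != 1) stopFormat("transform file missing '", prefix, "': ", path)
    strsplit(sub(paste0("^", prefix, " "), "", ln), " +")[[1]]
  }
  rot <- matrix(as.numeric(fields("rotation")), 3, 3, byrow = TRUE)
  tra <- as.numeric(fields("translation"))
  rigidTransform(rot, tra, fields("direction"))
}
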