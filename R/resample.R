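#' @include volume-io.R
NULL

#' Resample a moving volume onto a reference grid under a rigid transform
#'
#' Samples the moving volume at every reference voxel centre after mapping
#' it through the rigid transform, with trilinear interpolation for
#' intensities (or nearest-neighbour for masks). Reference voxels sampling
#' outside the moving extent take `fill_value`. When the transform is the
#' identity and the two grids coincide the result is an exact copy — sample
#' points are snapped to the lattice so coincident grids never blur.
#'
#' @param moving a [VolumeGrid-class] (or [MaskVolume-class] with
#'   `interpolation = "nearest"`).
#' @param reference a [VolumeGrid-class] or [MaskVolume-class] supplying the
#'   output grid.
#' @param transform a [RigidTransform-class] mapping moving coordinates into
#'   the reference frame (either direction flag is accepted; the needed
#'   inverse is derived). `NULL` means identity.
#' @param fill_value intensity for out-of-extent samples (default -1000 HU,
#'   air; for masks, `FALSE`).
#' @param interpolation `"trilinear"` or `"nearest"`.
#' @return a [VolumeGrid-class] (or [MaskVolume-class]) on the reference grid.
#' @export
resampleOnto <- function(moving, reference, transform = NULL,
                         fill_value = -1000,
                         interpolation = c("trilinear", "nearest")) {
  interpolation <- match.arg(interpolation)
  is_mask <- is(moving, "MaskVolume")
  if (is_mask) interpolation <- "nearest"
  if (is.null(transform)) transform <- rigidTransform()
  stopifnot(is(transform, "RigidTransform"))
  if (abs(det(transform@rotation) - 1) > 1e-6)
    stopPrecond("degenerate rotation (det != +1)")
  # kernel needs the reference -> moving map
  tr <- if (transform@direction == "moving_to_reference")
    invertTransform(transform) else transform
  mdata <- voxelData(moving)
  if (is_mask) storage.mode(mdata) <- "double"
  fill <- if (is_mask) 0 else as.numeric(fill_value)
  out <- .resample_kernel(as.vector(mdata), dim(mdata),
                          voxelSpacing(moving), voxelOrigin(moving),
                          dim(voxelData(reference)),
                          voxelSpacing(reference), voxelOrigin(reference),
                          tr@rotation, tr@translation, fill,
                          as.integer(interpolation == "nearest"))
  arr <- array(out, dim(voxelData(reference)))
  if (is_mask)
    maskVolume(arr != 0, voxelSpacing(reference), voxelOrigin(reference),
               provenance = paste0("resampled(", moving@provenance, ")"))
  else
    volumeGrid(arr, voxelSpacing(reference), voxelOrigin(reference))
}
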