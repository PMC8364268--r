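#' @include volume-io.R
NULL

#' Dilate an external-contour mask by a physical margin
#'
#' Expands a binary body mask by a ball of physical radius `margin_mm`
#' (converted per-axis into voxels by the grid spacing). Gamma evaluation is
#' restricted to this dilated region so that reconstruction artifacts
#' outside the patient volume never contribute failed voxels; the default
#' 1 cm margin keeps genuine surface change inside the evaluated region.
#'
#' @param contour_mask a non-empty [MaskVolume-class] (the external contour).
#' @param margin_mm dilation radius in mm (>= 0; default 10).
#' @return the dilated [MaskVolume-class].
#' @export
maskFromExternal <- function(contour_mask, margin_mm = 10) {
  stopifnot(is(contour_mask, "MaskVolume"))
  if (margin_mm < 0) stopPrecond("margin_mm must be >= 0")
  m <- contour_mask@data
  if (!any(m)) stopPrecond("external contour mask is empty")
  if (margin_mm == 0) {
    out <- contour_mask
    out@provenance <- "dilated(margin_mm=0)"
    return(out)
  }
  sp <- contour_mask@spacing
  d <- dim(m)
  # structuring element: all integer voxel offsets within the physical ball
  r <- floor(margin_mm / sp)
  offs <- expand.grid(a = -r[1]:r[1], b = -r[2]:r[2], c = -r[3]:r[3])
  dist2 <- (offs$a * sp[1])^2 + (offs$b * sp[2])^2 + (offs$c * sp[3])^2
  offs <- offs[dist2 <= margin_mm^2 + 1e-9, , drop = FALSE]
  out <- array(FALSE, d)
  for (q in seq_len(nrow(offs))) {
    a <- offs$a[q]; b <- offs$b[q]; c <- offs$c[q]
    si <- max(1, 1 - a):min(d[1], d[1] - a)
    sj <- max(1, 1 - b):min(d[2], d[2] - b)
    sk <- max(1, 1 - c):min(d[3], d[3] - c)
    out[si + a, sj + b, sk + c] <- out[si + a, sj + b, sk + c] |
      m[si, sj, sk, drop = FALSE]
  }
  maskVolume(out, sp, contour_mask@origin,
             provenance = sprintf("dilated(margin_mm=%g)", margin_mm))
}
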