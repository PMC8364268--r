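#' @include volume-io.R
NULL

# Minimal DICOM parser: little-endian explicit or implicit VR, uncompressed
# pixel data, nested sequences. Covers what the clinical inputs need — CT
# image series, RTSTRUCT external contours, Spatial Registration objects —
# and nothing more.

.dcmLongVRs <- c("OB", "OW", "OF", "SQ", "UT", "UN")

# VR lookup for implicit-VR files, restricted to the tags this package reads
.dcmDict <- c(
  "00080060" = "CS", "00180050" = "DS", "00200013" = "IS",
  "00200032" = "DS", "00200037" = "DS",
  "00280010" = "US", "00280011" = "US", "00280030" = "DS",
  "00280100" = "US", "00280103" = "US",
  "00281052" = "DS", "00281053" = "DS", "7fe00010" = "OW",
  "30060020" = "SQ", "30060022" = "IS", "30060026" = "LO",
  "30060039" = "SQ", "30060040" = "SQ", "30060042" = "CS",
  "30060050" = "DS", "30060084" = "IS",
  "00700308" = "SQ", "00700309" = "SQ", "0070030a" = "SQ",
  "0070030c" = "CS", "300600c6" = "DS")

.dcmU16 <- function(b, i) as.integer(b[i]) + 256L * as.integer(b[i + 1])
.dcmU32 <- function(b, i)
  sum(as.numeric(b[i:(i + 3)]) * c(1, 256, 65536, 16777216))

.dcmUndef <- 4294967295

# parse elements of one dataset in b[pos..end]; returns list(elements, pos)
.dcmParseDataset <- function(b, pos, end, explicit) {
  els <- list()
  while (pos + 7 <= end + 1 && pos < end) {
    grp <- .dcmU16(b, pos); ele <- .dcmU16(b, pos + 2)
    tag <- sprintf("%04x%04x", grp, ele)
    if (tag == "fffee00d") {  # item delimitation: caller handles
      pos <- pos + 8
      break
    }
    if (explicit && grp != 0xFFFE) {
      vr <- rawToChar(b[(pos + 4):(pos + 5)])
      if (vr %in% .dcmLongVRs) {
        len <- .dcmU32(b, pos + 8); pos <- pos + 12
      } else {
        len <- .dcmU16(b, pos + 6); pos <- pos + 8
      }
    } else {
      vr <- if (tag %in% names(.dcmDict)) .dcmDict[[tag]] else "UN"
      len <- .dcmU32(b, pos + 4); pos <- pos + 8
    }
    if (vr == "SQ" || len == .dcmUndef) {
      sq <- .dcmParseSQ(b, pos, len, explicit)
      els[[tag]] <- list(vr = "SQ", items = sq$items)
      pos <- sq$pos
    } else {
      els[[tag]] <- list(vr = vr,
                         raw = if (len > 0) b[pos:(pos + len - 1)] else raw(0))
      pos <- pos + len
    }
  }
  list(elements = els, pos = pos)
}

.dcmParseSQ <- function(b, pos, len, explicit) {
  items <- list()
  end <- if (len == .dcmUndef) length(b) else pos + len - 1
  while (pos + 7 <= end + 1) {
    grp <- .dcmU16(b, pos); ele <- .dcmU16(b, pos + 2)
    ilen <- .dcmU32(b, pos + 4)
    pos <- pos + 8
    if (grp == 0xFFFE && ele == 0xE0DD) break         # sequence delimiter
    if (!(grp == 0xFFFE && ele == 0xE000))
      stopFormat("malformed sequence item at byte ", pos - 8)
    iend <- if (ilen == .dcmUndef) end else pos + ilen - 1
    ds <- .dcmParseDataset(b, pos, iend, explicit)
    items[[length(items) + 1L]] <- ds$elements
    pos <- ds$pos
    if (len != .dcmUndef && pos > end) break
  }
  list(items = items, pos = pos)
}

# parse a DICOM file into a named element list
.dcmReadFile <- function(path) {
  if (!file.exists(path)) stopFormat("DICOM file not found: ", path)
  b <- readBin(path, "raw", n = file.size(path))
  if (length(b) < 140 || rawToChar(b[129:132]) != "DICM")
    stopFormat("not a DICOM part-10 file: ", path)
  pos <- 133
  # file meta group (0002,....) is always explicit VR little endian
  meta <- list()
  while (pos + 7 <= length(b) && .dcmU16(b, pos) == 0x0002) {
    ele <- .dcmU16(b, pos + 2)
    vr <- rawToChar(b[(pos + 4):(pos + 5)])
    if (vr %in% .dcmLongVRs) {
      len <- .dcmU32(b, pos + 8); pos <- pos + 12
    } else {
      len <- .dcmU16(b, pos + 6); pos <- pos + 8
    }
    meta[[sprintf("0002%04x", ele)]] <-
      list(vr = vr, raw = if (len > 0) b[pos:(pos + len - 1)] else raw(0))
    pos <- pos + len
  }
  ts <- .dcmString(meta, "00020010")
  explicit <- switch(ts,
    "1.2.840.10008.1.2.1" = TRUE,
    "1.2.840.10008.1.2" = FALSE,
    stopFormat("unsupported transfer syntax ", ts, " in ", path))
  .dcmParseDataset(b, pos, length(b), explicit)$elements
}

.dcmString <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  r <- e$raw
  while (length(r) && r[length(r)] %in% as.raw(c(0L, 32L)))
    r <- r[-length(r)]
  rawToChar(r)
}

.dcmStrings <- function(els, tag) {
  s <- .dcmString(els, tag)
  if (is.null(s)) NULL else strsplit(s, "\\\\")[[1]]
}

.dcmNumeric <- function(els, tag) {
  s <- .dcmStrings(els, tag)
  if (is.null(s)) NULL else as.numeric(s)
}

.dcmU16Value <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e)) return(NULL)
  readBin(e$raw, "integer", n = length(e$raw) / 2, size = 2,
          signed = FALSE, endian = "little")
}

.dcmSeq <- function(els, tag) {
  e <- els[[tag]]
  if (is.null(e) || e$vr != "SQ") return(NULL)
  e$items
}

# ---- CT image series --------------------------------------------------------

#' Read a DICOM CT/CBCT image series as a VolumeGrid
#'
#' Parses every file in the directory, checks that all slices share
#' orientation and in-plane spacing, sorts them by physical position,
#' verifies the stack is contiguous (a missing slice is an error naming the
#' gap), applies the rescale slope/intercept, and returns the volume in HU
#' on the package's (slice, row, column) axes. Only axis-aligned
#' orientations and uncompressed 16-bit little-endian pixel data are
#' supported.
#'
#' @param dir directory containing exactly one image series.
#' @return a [VolumeGrid-class].
#' @export
readDicomSeries <- function(dir) {
  if (!dir.exists(dir)) stopFormat("DICOM series directory not found: ", dir)
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(files) == 0) stopFormat("no files in DICOM directory: ", dir)
  slices <- lapply(files, function(f) {
    els <- .dcmReadFile(f)
    if (is.null(els[["7fe00010"]]))
      stopFormat("non-image DICOM object (no pixel data): ", f)
    list(file = f,
         ipp = .dcmNumeric(els, "00200032"),
         iop = .dcmNumeric(els, "00200037"),
         rows = .dcmU16Value(els, "00280010"),
         cols = .dcmU16Value(els, "00280011"),
         ps = .dcmNumeric(els, "00280030"),
         bits = .dcmU16Value(els, "00280100"),
         signed = isTRUE(.dcmU16Value(els, "00280103") == 1L),
         slope = if (is.null(s <- .dcmNumeric(els, "00281053"))) 1 else s,
         intercept = if (is.null(s <- .dcmNumeric(els, "00281052"))) 0 else s,
         px = els[["7fe00010"]]$raw)
  })
  s1 <- slices[[1]]
  if (is.null(s1$iop) || max(abs(s1$iop - c(1, 0, 0, 0, 1, 0))) > 1e-4)
    stopFormat("unsupported image orientation (axis-aligned only)")
  for (s in slices) {
    if (max(abs(s$iop - s1$iop)) > 1e-6)
      stopFormat("inconsistent slice orientation in series")
    if (s$rows != s1$rows || s$cols != s1$cols ||
        max(abs(s$ps - s1$ps)) > 1e-6)
      stopFormat("inconsistent in-plane geometry in series")
    if (s$bits != 16L)
      stopFormat("only 16-bit pixel data supported")
  }
  z <- vapply(slices, function(s) s$ipp[3], numeric(1))
  ord <- order(z)
  slices <- slices[ord]; z <- z[ord]
  if (length(z) > 1) {
    dz <- diff(z)
    gap <- stats::median(dz)
    if (gap <= 0) stopFormat("duplicate slice positions in series")
    bad <- which(abs(dz - gap) > 0.01 * gap)
    if (length(bad))
      stopFormat("missing slice: gap of ", format(dz[bad[1]]),
                 " mm between z = ", format(z[bad[1]]), " and z = ",
                 format(z[bad[1] + 1]), " (expected ", format(gap), " mm)")
  } else gap <- 1
  arr <- array(0, c(length(slices), s1$rows, s1$cols))
  for (i in seq_along(slices)) {
    s <- slices[[i]]
    v <- readBin(s$px, "integer", n = s$rows * s$cols, size = 2,
                 signed = s$signed, endian = "little")
    arr[i, , ] <- s$slope * matrix(v, nrow = s$rows, byrow = TRUE) +
      s$intercept
  }
  # internal axes (slice, row, column) = (z, y, x)
  volumeGrid(arr, spacing = c(gap, s1$ps[1], s1$ps[2]),
             origin = c(z[1], s1$ipp[2], s1$ipp[1]))
}

# ---- RTSTRUCT external contour ---------------------------------------------

# even-odd point-in-polygon, vectorised over query points
.pipEvenOdd <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    dy <- vy[j] - vy[i]
    if (dy != 0) {
      crosses <- (vy[i] > py) != (vy[j] > py)
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / dy + vx[i]
      inside <- xor(inside, crosses & px < xint)
    }
    j <- i
  }
  inside
}

#' Rasterize an RTSTRUCT contour onto a volume grid as a binary mask
#'
#' Selects the named ROI (default: the first, typically the external/BODY
#' contour), and fills each closed planar contour by the even-odd rule on
#' its nearest slice; contours are not interpolated between slices.
#' Multiple contours on one slice combine by exclusive-or, so holes are
#' honoured.
#'
#' @param path RTSTRUCT DICOM file.
#' @param grid a [VolumeGrid-class] or [MaskVolume-class] supplying the
#'   target geometry.
#' @param roi_name optional ROI name (case-insensitive); `NULL` takes the
#'   first ROI.
#' @return a [MaskVolume-class] on `grid`'s geometry.
#' @export
readDicomRtstructMask <- function(path, grid, roi_name = NULL) {
  els <- .dcmReadFile(path)
  rois <- .dcmSeq(els, "30060020")
  if (is.null(rois)) stopFormat("no StructureSetROISequence in ", path)
  numbers <- vapply(rois, function(r) .dcmNumeric(r, "30060022"), numeric(1))
  names_ <- vapply(rois, function(r) .dcmString(r, "30060026"), character(1))
  pick <- if (is.null(roi_name)) 1L
          else which(tolower(names_) == tolower(roi_name))[1]
  if (is.na(pick)) stopFormat("ROI '", roi_name, "' not found in ", path)
  contours_by_roi <- .dcmSeq(els, "30060039")
  rc <- NULL
  for (item in contours_by_roi) {
    refnum <- .dcmNumeric(item, "30060084")
    if (!is.null(refnum) && refnum == numbers[pick]) { rc <- item; break }
  }
  if (is.null(rc)) stopFormat("no contour data for ROI ", names_[pick])
  sp <- voxelSpacing(grid); org <- voxelOrigin(grid)
  d <- dim(voxelData(grid))
  m <- array(FALSE, d)
  yc <- org[2] + (seq_len(d[2]) - 1) * sp[2]
  xc <- org[3] + (seq_len(d[3]) - 1) * sp[3]
  cells <- expand.grid(y = yc, x = xc)
  for (ct in .dcmSeq(rc, "30060040")) {
    pts <- matrix(.dcmNumeric(ct, "30060050"), ncol = 3, byrow = TRUE)
    i <- round((pts[1, 3] - org[1]) / sp[1]) + 1
    if (i < 1 || i > d[1]) next
    inside <- .pipEvenOdd(cells$x, cells$y, pts[, 1], pts[, 2])
    m[i, , ] <- xor(m[i, , ], matrix(inside, d[2], d[3]))
  }
  maskVolume(m, sp, org, provenance = paste0("rtstruct:", names_[pick]))
}

# ---- Spatial Registration ---------------------------------------------------

#' Read a DICOM Spatial Registration object as a RigidTransform
#'
#' Extracts the 4x4 frame-of-reference transformation matrix (row-major,
#' acting on (x, y, z) points), converts it to the package's
#' (slice, row, column) axis order, and returns it flagged as mapping
#' moving-volume coordinates into the reference frame. When the object
#' carries several matrices (commonly an identity for the fixed frame plus
#' the actual registration), the last non-identity matrix is used.
#'
#' @param path Spatial Registration DICOM file.
#' @return a [RigidTransform-class].
#' @export
readDicomRegistration <- function(path) {
  els <- .dcmReadFile(path)
  regs <- .dcmSeq(els, "00700308")
  if (is.null(regs)) stopFormat("no RegistrationSequence in ", path)
  mats <- list()
  for (reg in regs)
    for (mr in .dcmSeq(reg, "00700309") %||% list())
      for (mx in .dcmSeq(mr, "0070030a") %||% list()) {
        v <- .dcmNumeric(mx, "300600c6")
        if (!is.null(v) && length(v) == 16)
          mats[[length(mats) + 1L]] <- matrix(v, 4, 4, byrow = TRUE)
      }
  if (length(mats) == 0) stopFormat("no transformation matrix in ", path)
  nonid <- Filter(function(m) max(abs(m - diag(4))) > 1e-9, mats)
  M <- if (length(nonid)) nonid[[length(nonid)]] else diag(4)
  # (x, y, z) -> internal (slice, row, column) = (z, y, x)
  P <- matrix(0, 3, 3); P[1, 3] <- P[2, 2] <- P[3, 1] <- 1
  rigidTransform(P %*% M[1:3, 1:3] %*% t(P),
                 as.numeric(P %*% M[1:3, 4]),
                 direction = "moving_to_reference")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
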