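# Writes DICOM fixtures with pydicom (independent of the package's parser).
# Fixtures are generated at test time into a temp directory; nothing binary
# is stored in the repository.

dicomFixtureScript <- function() {
  script <- file.path(tempdir(), "make_dicom_fixtures.py")
  if (file.exists(script)) return(script)
  writeLines(c(
    "import sys, numpy as np",
    "import pydicom",
    "from pydicom.dataset import Dataset, FileDataset, FileMetaDataset",
    "from pydicom.uid import ExplicitVRLittleEndian, ImplicitVRLittleEndian, generate_uid",
    "",
    "out = sys.argv[1]",
    "mode = sys.argv[2] if len(sys.argv) > 2 else 'all'",
    "implicit = len(sys.argv) > 3 and sys.argv[3] == 'implicit'",
    "ts = ImplicitVRLittleEndian if implicit else ExplicitVRLittleEndian",
    "",
    "def base(sop_class):",
    "    meta = FileMetaDataset()",
    "    meta.MediaStorageSOPClassUID = sop_class",
    "    meta.MediaStorageSOPInstanceUID = generate_uid()",
    "    meta.TransferSyntaxUID = ts",
    "    ds = FileDataset(None, {}, file_meta=meta, preamble=b'\\x00' * 128)",
    "    ds.is_little_endian = True",
    "    ds.is_implicit_VR = implicit",
    "    ds.SOPClassUID = sop_class",
    "    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID",
    "    return ds",
    "",
    "if mode in ('all', 'ct'):",
    "    zs = [5.0, 7.0, 9.0, 11.0, 13.0, 15.0]",
    "    for s, z in enumerate(zs):",
    "        ds = base('1.2.840.10008.5.1.4.1.1.2')",
    "        ds.Modality = 'CT'",
    "        ds.Rows, ds.Columns = 12, 10",
    "        ds.PixelSpacing = [2.0, 1.5]",
    "        ds.ImagePositionPatient = [-20.0, -30.0, z]",
    "        ds.ImageOrientationPatient = [1, 0, 0, 0, 1, 0]",
    "        ds.BitsAllocated = 16",
    "        ds.BitsStored = 16",
    "        ds.HighBit = 15",
    "        ds.SamplesPerPixel = 1",
    "        ds.PhotometricInterpretation = 'MONOCHROME2'",
    "        ds.PixelRepresentation = 1",
    "        ds.RescaleSlope = 1.0",
    "        ds.RescaleIntercept = -1024.0",
    "        ds.InstanceNumber = s + 1",
    "        r, c = np.meshgrid(np.arange(12), np.arange(10), indexing='ij')",
    "        ds.PixelData = (100 * s + 10 * r + c).astype(np.int16).tobytes()",
    "        ds.save_as(f'{out}/ct_{s:02d}.dcm', enforce_file_format=True)",
    "",
    "if mode in ('all', 'rtstruct'):",
    "    ds = base('1.2.840.10008.5.1.4.1.1.481.3')",
    "    ds.Modality = 'RTSTRUCT'",
    "    roi = Dataset()",
    "    roi.ROINumber = 1",
    "    roi.ReferencedFrameOfReferenceUID = generate_uid()",
    "    roi.ROIName = 'External'",
    "    ds.StructureSetROISequence = [roi]",
    "    contour = Dataset()",
    "    contour.ContourGeometricType = 'CLOSED_PLANAR'",
    "    pts = [(-9.7, -13.7), (9.7, -13.7), (9.7, 5.7), (-9.7, 5.7)]",
    "    contour.ContourData = [v for (x, y) in pts for v in (x, y, 9.0)]",
    "    contour.NumberOfContourPoints = 4",
    "    rc = Dataset()",
    "    rc.ReferencedROINumber = 1",
    "    rc.ContourSequence = [contour]",
    "    ds.ROIContourSequence = [rc]",
    "    ds.save_as(f'{out}/rtstruct.dcm', enforce_file_format=True)",
    "",
    "if mode in ('all', 'reg'):",
    "    ds = base('1.2.840.10008.5.1.4.1.1.66.1')",
    "    ds.Modality = 'REG'",
    "    import math",
    "    th = math.radians(10.0)",
    "    M = [math.cos(th), -math.sin(th), 0, 3.0,",
    "         math.sin(th), math.cos(th), 0, -2.0,",
    "         0, 0, 1, 5.0,",
    "         0, 0, 0, 1]",
    "    def reg_item(matrix):",
    "        mx = Dataset()",
    "        mx.FrameOfReferenceTransformationMatrixType = 'RIGID'",
    "        mx.FrameOfReferenceTransformationMatrix = matrix",
    "        mr = Dataset()",
    "        mr.MatrixSequence = [mx]",
    "        it = Dataset()",
    "        it.MatrixRegistrationSequence = [mr]",
    "        return it",
    "    ident = [1.0, 0, 0, 0, 0, 1.0, 0, 0, 0, 0, 1.0, 0, 0, 0, 0, 1.0]",
    "    ds.RegistrationSequence = [reg_item(ident), reg_item(M)]",
    "    ds.save_as(f'{out}/reg.dcm', enforce_file_format=True)",
    "print('ok')"), script)
  script
}

makeDicomFixtures <- function(dir, mode = "all", implicit = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- system2("python", c(dicomFixtureScript(), dir, mode,
                             if (implicit) "implicit"),
                 stdout = TRUE, stderr = TRUE)
  if (!any(grepl("^ok$", out)))
    stop("pydicom fixture generation failed: ", paste(out, collapse = "\n"))
  invisible(dir)
}
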