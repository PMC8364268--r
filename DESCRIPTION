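Package: cbctalert
Title: Anatomy-Change Alerts from Serial Cone-Beam CT in Head-and-Neck
    Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monitors anatomy change over a head-and-neck radiotherapy course by
    comparing each treatment-day cone-beam CT (CBCT) against a reference CBCT
    with a masked 3D global gamma index (3 mm distance-to-agreement, 30 HU),
    summarising each comparison as a match quality parameter (MQP) derived from
    the failed-voxel gamma percentile, and triggering a re-CT alert when a
    configurable number of consecutive MQP values fall below a threshold.
    Includes confusion-matrix and ROC evaluation against clinical re-CT
    annotations, a synthetic phantom course generator with known anatomy-change
    ground truth, readers for DICOM CT series, RTSTRUCT external contours and
    spatial registrations alongside a lightweight research volume format, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate: 
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'cbctalert-package.R'
    'gamma.R'
    'mqp.R'
    'evaluation.R'
    'volume-io.R'
    'mask.R'
    'phantom.R'
    'cohort.R'
    'manifest.R'
    'cli.R'
    'dicom.R'
    'methods.R'
    'resample.R'
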