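---
title: "Monitoring anatomy change with serial CBCT: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring anatomy change with serial CBCT: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cbctalert)
```

## The problem and the model

Radical head-and-neck radiotherapy delivers 20 or more daily fractions under
image guidance. Weight loss, tumour response and changing setup gradually
invalidate the planning anatomy; a repeat CT simulation (re-CT) and re-plan
can restore target coverage and organ-at-risk sparing, but ordering one is
costly and currently rests on human judgment from daily imaging.

`cbctalert` treats the treatment-day CBCT stream as a time series of image
similarities. Every usable CBCT is compared against the plan's *reference
CBCT* — the earliest usable one, so the comparison needs no cross-modality
calibration against the planning CT — and each comparison is condensed to a
scalar, tracked over the course, and monitored by a trigger rule.

### The masked global gamma index

Two aligned volumes are compared voxel-by-voxel with the gamma index, the
radiotherapy-standard mixture of spatial and intensity tolerance. At each
reference voxel $r$ inside the evaluation mask,

$$\gamma(r) = \min_{r'} \sqrt{\frac{\lVert r' - r\rVert^2}{\mathrm{DTA}^2}
  + \frac{(I_e(r') - I_r(r))^2}{\Delta^2}},$$

with distance-to-agreement $\mathrm{DTA} = 3$ mm and intensity criterion
$\Delta = 30$ HU. The *global* method divides by the fixed $\Delta$
everywhere; a local (percentage) denominator would be meaningless for CT
numbers that pass through zero. A voxel with $\gamma \le 1$ is within
tolerance; $\gamma > 1$ fails. The minimisation runs over a sphere of radius
`search_radius_mm` (default $3 \times \mathrm{DTA} = 9$ mm — a visible cap,
because it bounds the largest attainable distance contribution), sampled on
a regular lattice of pitch `interp_step_mm` (default `min(spacing)/3`) with
trilinear interpolation of the evaluated volume. An exact integer-offset
mode (`interp_step_mm = 0`) exists so tests can compare the kernel against
an exhaustive brute-force search; the two must agree to $10^{-9}$ on any
grid, which pins the discretisation semantics.

Evaluation is restricted to the planning external contour dilated by
`mask_margin_mm` (default 10 mm, a physical ball converted per-axis by the
voxel spacing). The margin keeps genuine surface recession inside the
evaluated region while excluding the ring and streak artifacts that CBCT
reconstruction produces outside the patient. Masked voxels with non-finite
reference intensity (e.g. beyond a limited scan length) are excluded from
both the evaluation and the evaluated-voxel count, with the count logged.

### Match quality parameter and alert trigger

From each gamma map the failed voxels ($\gamma > 1$) form a multiset whose
$x$-th percentile $\gamma_x$ summarises how badly the comparison failed
(default $x = 80$). The match quality parameter of acquisition $i$ is

$$\mathrm{MQP}_{x,i} = \gamma_{x,\mathrm{ref}} - \gamma_{x,i},$$

where "ref" is the *reference match* between the first two usable CBCTs.
The reference match's own MQP is zero by definition; negative values mean
the current match is worse than the reference match. After a re-plan the
series restarts from zero with a fresh reference match and external contour.

The percentile is the empirical order-statistic percentile with linear
interpolation — the bin-free limit of a histogram percentile, chosen so no
arbitrary bin width enters the pipeline; anyone comparing against a binned
implementation should expect differences up to one bin. When a comparison
has *no* failed voxels the percentile is defined as the sentinel 1.0, the
pass/fail boundary: a perfect match then yields
$\mathrm{MQP} = \gamma_{x,\mathrm{ref}} - 1 \ge 0$ whenever the reference
match itself had failures, so a clean match can never drift toward an
alert. (In practice acquisition noise guarantees failed voxels.)

An alert fires at the first acquisition completing
`consecutive_required = 3` *consecutive usable acquisitions* with MQP
strictly below `threshold = -0.11`; a single at-or-above value resets the
run, ties at the threshold never count (pinned by a unit test), and runs
cannot span a re-plan boundary. Both constants are clinical calibrations
carried as defaults. "Consecutive" counts acquisitions, not calendar
fractions, because the trigger operates on the MQP series whose points are
acquisitions. After the initial trigger, later sub-threshold acquisitions
are reported as follow-up events; a configurable mute fraction
(`mute_after_fraction`) flags late-course follow-ups as suppressed, since
departments may prefer to silence alerts in the final week.

### Evaluation against clinical truth

The unit of evaluation is the *plan* (re-plans are separate plans). A
positive plan is one where re-CT was performed or, on review, warranted; its
`rect_fraction` is the decision fraction. At the operating point, a positive
counts as a true positive only when the alert lands within ±3 fractions
(inclusive, on treatment-fraction numbers) of `rect_fraction` — an alert
only before the window is a miss, following the timing definition
literally. Any alert on a negative plan is a false positive. Sensitivity is
TP/(TP+FN) and the false positive rate FP/(FP+TN); both are kept at full
precision and displayed rounded half-up to two decimals.

The ROC scan varies the threshold (default grid $-0.30$ to $0$ in steps of
$0.01$ *plus all observed MQP values*, so every vertex of the step-function
curve is visited) and the percentile $x$ from 50 to 95. Percentiles are
recomputed from the stored failed-voxel values; no gamma map is ever
recomputed. The scan scores detection *at any time*: with the ±3-fraction
rule, any loose threshold triggers every course within its first three
acquisitions — far before any plausible re-CT fraction — so window-scored
sensitivity would collapse toward zero at both ends of the threshold axis
and the curve would not be monotone. Any-time scoring preserves the
expected ROC properties (sensitivity and false positive rate both
non-increasing as the threshold decreases, corners at no-alerts and
all-alerts); the timing window remains the clinical rule for
operating-point confusion summaries.

## The synthetic phantom

Clinical CBCT series cannot be redistributed, so the package generates
treatment courses with closed-form ground truth.

* **Geometry.** A soft-tissue ellipsoid (default half-axes 70/60/75 mm in
  superior–inferior / anterior–posterior / left–right) in air, with a
  bone-like and an airway-like cylindrical insert, on a $64^3$ grid of 3 mm
  isotropic voxels (a ~19 cm field of view at deliberately coarse, fast
  resolution). Anatomy change is modelled as *lateral surface recession*:
  from `onset_fraction` the in-plane half-axes shrink by `regression_rate`
  mm per fraction — the dominant clinical change (weight loss) in a form
  whose ground truth is exact. Recession saturates at `max_recession_mm`
  (default 10 mm), since weight-loss-driven surface change plateaus rather
  than consuming the neck indefinitely. A course is labelled positive when
  total recession reaches `clinical_change_mm` (default 5 mm — a
  synthetic-cohort convention, stated in the annotation header, not a
  clinical constant), and the ground-truth re-CT fraction is the first
  fraction reaching that depth.
* **Acquisition.** Each scheduled fraction gets an independent rigid setup
  offset (direction uniform, magnitude uniform up to `setup_jitter_mm`,
  default 2 mm; optional rotation about the slice axis) whose exact inverse
  is recorded as the registration — emulating online matching that undoes
  the offset. Gaussian noise of marginal sd `noise_sigma` (default 20 HU)
  is added *after* geometry, with a ~1-voxel correlation length: white
  voxel noise would lose a random fraction of its variance to trilinear
  interpolation at each acquisition's random subvoxel offset, injecting
  acquisition-to-acquisition match-quality jitter that real, spatially
  correlated CBCT noise does not show. Optional ring artifacts
  (`artifact_level`, random phase per acquisition) are placed strictly
  outside the body-plus-margin region, so tests can verify the mask
  excludes them.
* **Schedule.** The default schedule is a CBCT at every fraction. With
  DTA = 3 mm the gamma map cannot see recession below about 3 mm, so at
  1 mm/fraction the first informative acquisition comes ~4 fractions after
  onset; resolving a three-consecutive-acquisition trigger at
  fraction-level timing then requires near-daily sampling, which clinics
  use for exactly the cases where organ-at-risk dose is of concern.
  Sparser schedules (e.g. twice weekly) are a `cbct_fractions` argument
  away; alert timing then quantises to the acquisition grid.
* **Cohorts.** `generateCohort()` draws positive courses with onset uniform
  on fractions 8–18 and rate uniform on 0.8–1.5 mm/fraction over 30
  fractions; negative courses are stable (noise and jitter only). All
  randomness derives from one master seed via derived sub-seeds; identical
  seeds give bit-identical volumes and byte-identical manifests.

What the phantom does *not* emulate: CBCT physics (scatter, beam hardening,
HU drift), deformable anatomy, internal low-contrast tumour change, and
gradual patient-specific trends such as shoulder-position drift in the
reference match. Passing the synthetic suite therefore demonstrates that
the pipeline recovers known geometric change under noise and setup error —
not that the clinical operating point transfers to any given scanner.

## Numerical choices

* All physical arithmetic is in mm in a fixed (slice, row, column) axis
  order; DICOM (x, y, z) quantities are permuted on read. One convention,
  applied everywhere, avoids the dominant class of imaging bugs.
* Resampling uses trilinear interpolation for intensities and
  nearest-neighbour for masks; sample coordinates are snapped to the voxel
  lattice at $10^{-9}$ voxels, so an identity transform on coincident grids
  is an exact copy rather than a blurred one.
* The gamma search visits candidate offsets sorted by distance and stops as
  soon as the distance term alone exceeds the running minimum; a
  precomputed-weight fast path covers interior voxels. Neither shortcut
  changes the exact minimisation semantics — the oracle-equivalence tests
  hold to $10^{-9}$.
* RTSTRUCT contours rasterise by the even-odd rule at each contour's
  nearest slice, combining multiple contours per slice by exclusive-or
  (holes work); contours are not interpolated between slices.
* Undefined metrics are `NA`, never 0: a cohort without positives has no
  sensitivity, and the code says so with a warning.

## Problem sizes used by the test suite

The suite exercises the full-size $64^3$ phantom where the claim is about
the system (parameter recovery over seeds 1–20 with onset at fraction 10,
1 mm/fraction, 20 HU noise; stable-course false-trigger audit; a 50-plan
ROC cohort at $x \in \{50, \dots, 95\}$), and compact $24^3$ phantoms where
the claim is mechanical (round trips, resets, CLI plumbing). Oracle
comparisons run on randomly sized grids up to $\sim 12^3$ against a pure-R
exhaustive search. The acceptance script generates a 25-plan cohort.

## Known limitations

* The reference match anchors everything: a poor reference match (large
  $\gamma_{x,\mathrm{ref}}$) compresses later MQP values toward zero and
  can hide real change — the mechanism behind clinical false negatives.
  Using the planning CT as reference would avoid this but needs
  cross-modality intensity calibration, deliberately out of scope.
* Gamma values are uncapped within the search radius, so catastrophic
  mismatch yields large $\gamma$ values whose absolute scale depends on the
  radius cap; only the percentile differences (MQP) are interpreted.
* The DICOM reader supports uncompressed little-endian CT series with
  axis-aligned orientation, which covers exported clinical CBCT but not
  every DICOM corner case.
* Alert timing can never precede recession visibility: with DTA = 3 mm and
  slow regression the trigger trails onset by several fractions, a floor
  set by the physics of the criterion, not by implementation.
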