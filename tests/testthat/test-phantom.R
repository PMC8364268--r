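test_that("course generation is deterministic and validated", {
  ph <- tinyPhantom(noise_sigma = 10, artifact_level = 30)
  cs <- courseSpec(n_fractions = 5, cbct_fractions = 1:5,
                   onset_fraction = 2, regression_rate = 1, seed = 42)
  a <- generateCourse(ph, cs)[[1]]
  b <- generateCourse(ph, cs)[[1]]
  for (q in seq_along(a$volumes))
    expect_identical(voxelData(a$volumes[[q]]), voxelData(b$volumes[[q]]))
  expect_identical(a$transforms[[3]]@translation,
                   b$transforms[[3]]@translation)
  # a different seed changes the realisation
  cs2 <- courseSpec(n_fractions = 5, cbct_fractions = 1:5,
                    onset_fraction = 2, regression_rate = 1, seed = 43)
  c2 <- generateCourse(ph, cs2)[[1]]
  expect_false(identical(voxelData(a$volumes[[1]]),
                         voxelData(c2$volumes[[1]])))

  # specs reject impossible geometry
  expect_error(phantomSpec(shape = c(16, 16, 16), spacing = c(3, 3, 3),
                           body_half_axes = c(40, 40, 40)),
               "clearance", class = "cbct_precondition_error")
  expect_error(courseSpec(n_fractions = 10, onset_fraction = 12),
               class = "cbct_precondition_error")
  expect_error(generateCourse(
    phantomSpec(), courseSpec(n_fractions = 80, onset_fraction = 1,
                              regression_rate = 2, max_recession_mm = 100)),
    "consumed", class = "cbct_precondition_error")
})

test_that("a null course is static and yields MQP identically zero", {
  ph <- tinyPhantom()  # no noise, no artifacts
  cs <- courseSpec(n_fractions = 4, cbct_fractions = 1:4,
                   setup_jitter_mm = 0, seed = 1)
  plan <- generateCourse(ph, cs)[[1]]
  for (q in 2:4)
    expect_identical(voxelData(plan$volumes[[q]]),
                     voxelData(plan$volumes[[1]]))
  s <- mqpSeries(comparePlan(plan), 80)
  expect_identical(mqpEntries(s)$mqp, rep(0, 3))
})

test_that("the measured surface recession matches the specification", {
  ph <- tinyPhantom()
  rate <- 1.5; onset <- 3
  cs <- courseSpec(n_fractions = 9, cbct_fractions = c(1, 5, 9),
                   onset_fraction = onset, regression_rate = rate,
                   setup_jitter_mm = 0, seed = 2)
  plan <- generateCourse(ph, cs)[[1]]
  # lateral body extent from the noise-free volumes (tissue > -500 HU)
  extent <- function(v) {
    body <- voxelData(v) > -500
    xs <- which(apply(body, 3, any))
    (max(xs) - min(xs) + 1) * voxelSpacing(v)[3]
  }
  for (q in 2:3) {
    f <- plan$fractions[q]
    expected <- rate * max(0, f - onset)
    measured <- (extent(plan$volumes[[1]]) - extent(plan$volumes[[q]])) / 2
    # one-voxel agreement with the commanded recession depth
    expect_lte(abs(measured - expected), voxelSpacing(plan$volumes[[q]])[3])
    expect_identical(plan$ground_truth$recession_mm[q], expected)
  }
})

test_that("ring artifacts are confined outside the evaluation mask", {
  ph_art <- tinyPhantom(noise_sigma = 0, artifact_level = 200)
  ph_none <- tinyPhantom(noise_sigma = 0, artifact_level = 0)
  mk <- function(ph) generateCourse(
    ph, courseSpec(n_fractions = 2, cbct_fractions = 1:2,
                   setup_jitter_mm = 0, seed = 6))[[1]]
  pa <- mk(ph_art); pn <- mk(ph_none)
  mask <- maskFromExternal(pa$external_mask, 10)
  # inside the mask the artifact-laden volume is identical to the clean one
  expect_identical(voxelData(pa$volumes[[1]])[voxelData(mask)],
                   voxelData(pn$volumes[[1]])[voxelData(mask)])
  # masked gamma ignores the artifacts entirely...
  g_masked <- computeGamma(pa$volumes[[1]], pa$volumes[[2]], mask)
  expect_length(failedValues(g_masked), 0)
  # ...while evaluating the whole grid picks them up materially
  g_full <- computeGamma(pa$volumes[[1]], pa$volumes[[2]],
                         fullMask(pa$volumes[[1]]))
  expect_gt(length(failedValues(g_full)), 100)
})

test_that("registered jitter is neutral: stable noisy courses keep MQP near zero", {
  # full-size phantom, zero regression: across seeds the per-course mean MQP
  # should straddle zero within two standard errors
  means <- vapply(1:20, function(s) {
    plan <- generateCourse(phantomSpec(),
                           courseSpec(n_fractions = 6, cbct_fractions = 1:6,
                                      seed = s))[[1]]
    mean(mqpEntries(mqpSeries(comparePlan(plan), 80))$mqp[-1])
  }, numeric(1))
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means)), 2 * se + 1e-3)
})

test_that("cohort generation writes consumable, byte-identical artefacts", {
  ph <- tinyPhantom(noise_sigma = 10)
  td <- withr::local_tempdir()
  rng <- cohortRanges(onset_fraction = c(1, 2), regression_rate = c(1.5, 2.5),
                      n_fractions = 6)
  coh <- generateCohort(2, 3, phantom = ph, ranges = rng, seed = 99,
                        out_dir = file.path(td, "run1"))
  expect_identical(sum(coh$cases$label == "positive"), 2L)
  expect_identical(sum(coh$cases$label == "negative"), 3L)
  expect_true(all(!is.na(coh$cases$rect_fraction[coh$cases$label == "positive"])))

  # same seed: byte-identical manifest and annotations
  generateCohort(2, 3, phantom = ph, ranges = rng, seed = 99,
                 out_dir = file.path(td, "run2"))
  expect_identical(readLines(file.path(td, "run1", "manifest.tsv")),
                   readLines(file.path(td, "run2", "manifest.tsv")))
  expect_identical(readLines(file.path(td, "run1", "annotations.tsv")),
                   readLines(file.path(td, "run2", "annotations.tsv")))

  # the written manifest feeds the tracker end to end
  comps <- trackManifest(file.path(td, "run1", "manifest.tsv"))
  expect_identical(sort(names(comps)), sort(coh$cases$plan_id))
  s <- mqpSeries(comps[[1]], 80)
  expect_identical(mqpEntries(s)$mqp[1], 0)

  # negatives-only cohort: FPR computable, sensitivity undefined
  neg <- generateCohort(0, 2, phantom = ph, ranges = rng, seed = 5)
  expect_true(all(neg$cases$label == "negative"))
})
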