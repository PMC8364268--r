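test_that("MQP arithmetic and degenerate series behave as defined", {
  expect_identical(computeMqp(1.4, 1.4), 0)
  expect_equal(computeMqp(1.4, 1.6), -0.2, tolerance = 1e-12)
  expect_error(computeMqp(Inf, 1), class = "cbct_precondition_error")
  expect_error(computeMqp(1, NA), class = "cbct_precondition_error")

  # identical noise-free volumes repeated: no failed voxels anywhere, the
  # sentinel cancels, and every MQP is exactly zero
  ph <- tinyPhantom()
  an <- cbctalert:::phantomAnatomy(ph, 0)
  v <- volumeGrid(an$hu, ph$spacing, cbctalert:::phantomOrigin(ph))
  mask <- maskFromExternal(maskVolume(an$body, ph$spacing, voxelOrigin(v)), 10)
  s <- buildSeries(rep(list(v), 5), 1:5, mask)
  expect_identical(mqpEntries(s)$mqp, rep(0, 4))
  expect_identical(gammaRef(s), 1.0)
  expect_null(detectAlert(s))
})

test_that("a noise-free shrinking course yields near-zero then decreasing MQP", {
  ph <- tinyPhantom()  # noise-free, artifact-free
  cs <- courseSpec(n_fractions = 8, cbct_fractions = 1:8,
                   onset_fraction = 4, regression_rate = 2,
                   setup_jitter_mm = 0, seed = 5)
  plan <- generateCourse(ph, cs)[[1]]
  cc <- comparePlan(plan)
  s <- mqpSeries(cc, 80)
  mqp <- mqpEntries(s)$mqp
  # before onset the anatomy is static: MQP exactly zero
  expect_identical(mqp[1:3], rep(0, 3))
  # once recession exceeds the DTA the match degrades monotonically: MQP
  # negative and non-increasing (ties come from the coarse noise-free
  # grid), failed-voxel counts strictly growing
  late <- mqp[mqpEntries(s)$fraction >= 6]
  expect_true(all(late < 0))
  expect_true(all(diff(late) <= 0))
  expect_lt(late[length(late)], late[1])
  nf <- lengths(failedValues(cc))[cc@fractions >= 5]
  expect_true(all(diff(nf) > 0))
})

test_that("pipeline MQP equals the hand-chained gamma percentile difference", {
  ph <- tinyPhantom(noise_sigma = 15)
  cs <- courseSpec(n_fractions = 3, cbct_fractions = 1:3,
                   onset_fraction = 1, regression_rate = 4, seed = 9)
  plan <- generateCourse(ph, cs)[[1]]
  s <- mqpSeries(comparePlan(plan), 80)

  # independently: resample, gamma, percentile, subtract
  mask <- maskFromExternal(plan$external_mask, 10)
  grid <- volumeGrid(array(0, dim(voxelData(mask))), voxelSpacing(mask),
                     voxelOrigin(mask))
  al <- lapply(1:3, function(i)
    resampleOnto(plan$volumes[[i]], grid, plan$transforms[[i]]))
  gref <- failedPercentile(computeGamma(al[[1]], al[[2]], mask), 80)
  g3 <- failedPercentile(computeGamma(al[[1]], al[[3]], mask), 80)
  expect_equal(mqpEntries(s)$mqp[2], gref - g3, tolerance = 1e-12)
  expect_equal(gammaRef(s), gref, tolerance = 1e-12)
})

test_that("a re-plan starts a fresh series at zero", {
  ph <- tinyPhantom()
  cs <- courseSpec(n_fractions = 10, cbct_fractions = 1:10,
                   onset_fraction = 2, regression_rate = 1.5,
                   setup_jitter_mm = 0, replan_fraction = 6, seed = 3)
  plans <- generateCourse(ph, cs)
  expect_length(plans, 2)
  expect_identical(plans[[2]]$plan_id, "plan-R1")
  expect_identical(plans[[1]]$fractions, 1:5)
  expect_identical(plans[[2]]$fractions, 6:10)
  s2 <- mqpSeries(comparePlan(plans[[2]]), 80)
  expect_identical(mqpEntries(s2)$mqp[1], 0)
  # the new plan's external contour is the shrunk anatomy
  expect_lt(sum(voxelData(plans[[2]]$external_mask)),
            sum(voxelData(plans[[1]]$external_mask)))
  expect_error(
    generateCourse(ph, courseSpec(n_fractions = 4, cbct_fractions = 1:4,
                                  replan_fraction = 4)),
    "< 2", class = "cbct_precondition_error")
  expect_error(compareCourse(list(rampVolume()), 1, fullMask(rampVolume()),
                             plan_id = "solo"),
               "solo", class = "cbct_precondition_error")
})

test_that("the alert trigger fires on runs of consecutive sub-threshold MQP", {
  cfg <- alertConfig(threshold = -0.11, consecutive_required = 3)
  # minimal triggering run: alert at the 4th entry
  a <- detectAlert(mkSeries(c(0, -0.12, -0.12, -0.12)), cfg)
  expect_identical(triggerFraction(a), 4L)
  expect_identical(a@trigger_acquisition, 5L)
  expect_identical(nrow(a@contributing), 3L)
  expect_true(all(a@contributing$mqp < -0.11))
  # one recovered entry resets the run
  expect_null(detectAlert(mkSeries(c(0, -0.12, -0.10, -0.12, -0.12)), cfg))
  # boundary semantics: equality is not "below"
  expect_null(detectAlert(mkSeries(c(0, -0.11, -0.11, -0.11)), cfg))
  expect_null(detectAlert(mkSeries(c(0, 0, 0)), cfg))
})

test_that("detectAlert agrees with a sliding-window scanner on random series", {
  set.seed(71)
  for (rep in 1:200) {
    n <- sample(3:20, 1)
    mqp <- c(0, round(rnorm(n - 1, -0.05, 0.12), 3))
    thr <- round(runif(1, -0.25, 0.05), 3)
    need <- sample(1:4, 1)
    s <- mkSeries(mqp)
    a <- detectAlert(s, alertConfig(thr, need))
    idx <- oracleAlertIndex(mqp, thr, need)
    if (is.na(idx)) expect_null(a)
    else expect_identical(a@trigger_acquisition,
                          mqpEntries(s)$acquisition[idx])
  }
})

test_that("the trigger is monotone in threshold and run length", {
  set.seed(81)
  for (rep in 1:60) {
    mqp <- c(0, rnorm(14, -0.08, 0.1))
    s <- mkSeries(mqp)
    idx <- function(thr, need) {
      a <- detectAlert(s, alertConfig(thr, need))
      if (is.null(a)) Inf else a@trigger_acquisition
    }
    # raising the threshold toward 0 never removes or delays an alert
    expect_gte(idx(-0.05, 3), idx(-0.02, 3))
    expect_gte(idx(-0.11, 3), idx(-0.05, 3))
    # requiring a longer run never gives an earlier trigger
    expect_lte(idx(-0.08, 2), idx(-0.08, 3))
    expect_lte(idx(-0.08, 3), idx(-0.08, 4))
  }
})

test_that("follow-up alerts are reported and can be muted late in the course", {
  mqp <- c(0, -0.2, -0.2, -0.2, -0.05, -0.2, -0.2)
  ev <- alertEvents(mkSeries(mqp, fractions = c(1, 4, 6, 9, 11, 27, 29)),
                    alertConfig(-0.11, 3, mute_after_fraction = 28))
  expect_length(ev, 3)
  expect_false(ev[[1]]@is_followup)
  expect_identical(triggerFraction(ev[[1]]), 9L)
  expect_true(ev[[2]]@is_followup)
  expect_false(ev[[2]]@suppressed)   # fraction 27, before the mute point
  expect_true(ev[[3]]@suppressed)    # fraction 29, muted
})

test_that("MQP series and course comparisons round-trip through text files", {
  cc <- mkComparison(c(0, -0.12, -0.3), fractions = c(2, 5, 8))
  td <- withr::local_tempdir()
  writeCourseComparison(cc, file.path(td, "t_comparison.tsv"))
  back <- readCourseComparison(file.path(td, "t_comparison.tsv"))
  expect_identical(planId(back), "t")
  expect_identical(back@fractions, c(2L, 5L, 8L))
  expect_equal(failedValues(back), failedValues(cc), tolerance = 1e-15)
  s <- mqpSeries(cc, 80)
  writeMqpSeries(s, file.path(td, "t_mqp.tsv"))
  df <- read.delim(file.path(td, "t_mqp.tsv"), comment.char = "#")
  expect_equal(df$mqp, mqpEntries(s)$mqp, tolerance = 1e-15)
})
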