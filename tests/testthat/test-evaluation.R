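mkAlert <- function(fraction, plan = "p") {
  new("AlertEvent", plan_id = plan, trigger_fraction = as.integer(fraction),
      trigger_acquisition = 1L,
      contributing = data.frame(acquisition = 1L,
                                fraction = as.integer(fraction),
                                mqp = -0.2),
      is_followup = FALSE, suppressed = FALSE)
}

test_that("plans classify by the +-3 fraction window and any-time rule", {
  expect_identical(classifyCase(mkAlert(14), "positive", 16), "TP")
  expect_identical(classifyCase(mkAlert(13), "positive", 16), "TP")  # boundary
  expect_identical(classifyCase(mkAlert(19), "positive", 16), "TP")
  expect_identical(classifyCase(mkAlert(10), "positive", 16), "FN")  # early alert
  expect_identical(classifyCase(NULL, "positive", 16), "FN")
  expect_identical(classifyCase(mkAlert(28), "negative"), "FP")
  expect_identical(classifyCase(NULL, "negative"), "TN")
  expect_error(classifyCase(mkAlert(5), "positive"),
               "rect_fraction", class = "cbct_precondition_error")
})

test_that("confusion metrics reproduce ratios at full and display precision", {
  s <- confusionSummary(c(tp = 26, tn = 37, fp = 22, fn = 8))
  expect_identical(confusionCounts(s), c(tp = 26L, tn = 37L, fp = 22L, fn = 8L))
  expect_equal(sensitivity(s), 26 / 34, tolerance = 1e-15)
  expect_equal(falsePositiveRate(s), 22 / 59, tolerance = 1e-15)
  expect_identical(roundHalfUp(sensitivity(s), 2), 0.76)
  expect_identical(roundHalfUp(falsePositiveRate(s), 2), 0.37)

  # classification-vector route agrees with the counts route
  cls <- c(rep("TP", 3), rep("FN", 1), rep("FP", 2), rep("TN", 4))
  s2 <- confusionSummary(cls)
  expect_identical(confusionCounts(s2), c(tp = 3L, tn = 4L, fp = 2L, fn = 1L))
  expect_equal(sensitivity(s2), 0.75)

  # degenerate cohorts: undefined metrics are NA with a warning, never 0
  expect_warning(s3 <- confusionSummary(c(tp = 0, tn = 5, fp = 2, fn = 0)),
                 "sensitivity undefined")
  expect_true(is.na(sensitivity(s3)))
  expect_equal(falsePositiveRate(s3), 2 / 7)
  expect_warning(s4 <- confusionSummary(rep("TP", 5)), "false positive rate")
  expect_equal(sensitivity(s4), 1)
  expect_true(is.na(falsePositiveRate(s4)))
  expect_error(confusionSummary(character(0)),
               class = "cbct_precondition_error")
})

test_that("case annotations are validated on read and write", {
  td <- withr::local_tempdir()
  cases <- data.frame(plan_id = c("a", "b"),
                      label = c("positive", "negative"),
                      rect_fraction = c(15L, NA),
                      positive_subtype = c("actual_rect", NA),
                      rt_review_fraction = c(12L, NA))
  p <- file.path(td, "ann.tsv")
  writeCaseAnnotations(cases, p, comment = "fixture")
  back <- readCaseAnnotations(p)
  expect_identical(back$plan_id, cases$plan_id)
  expect_identical(back$rect_fraction, cases$rect_fraction)

  bad <- cases; bad$rect_fraction <- c(NA, NA)
  writeCaseAnnotations(bad, p)
  expect_error(readCaseAnnotations(p), "without rect_fraction",
               class = "cbct_format_error")
  bad2 <- cases; bad2$rect_fraction <- c(15L, 20L)
  writeCaseAnnotations(bad2, p)
  expect_error(readCaseAnnotations(p), "negative",
               class = "cbct_format_error")
})

test_that("ROC scan covers degenerate corners and reuses stored failed values", {
  # three positive plans that alert at their re-CT fraction, two negatives
  # that dip below only mild thresholds
  comps <- list(
    p1 = mkComparison(c(0, -0.2, -0.2, -0.2, -0.2), plan_id = "p1"),
    p2 = mkComparison(c(0, -0.05, -0.2, -0.2, -0.2), plan_id = "p2"),
    p3 = mkComparison(c(0, -0.2, -0.2, -0.2, -0.2), plan_id = "p3"),
    n1 = mkComparison(c(0, -0.05, -0.06, -0.07, -0.04), plan_id = "n1"),
    n2 = mkComparison(c(0, 0.01, 0.02, -0.01, 0.02), plan_id = "n2"))
  cases <- data.frame(
    plan_id = c("p1", "p2", "p3", "n1", "n2"),
    label = c("positive", "positive", "positive", "negative", "negative"),
    rect_fraction = c(4L, 5L, 2L, NA, NA),
    positive_subtype = NA, rt_review_fraction = NA)

  # below every MQP: no alerts at all
  lo <- rocScan(comps, cases, thresholds = -10, xs = 80)
  expect_identical(c(lo$sensitivity, lo$false_positive_rate), c(0, 0))
  # above every MQP (every plan has >= 3 entries): alerts everywhere
  hi <- rocScan(comps, cases, thresholds = 1, xs = 80)
  expect_identical(hi$false_positive_rate, 1)
  # at threshold 1 every plan triggers at its 3rd entry (fraction 3)
  expect_identical(hi$tp + hi$fn, 3L)

  # operating point: all three positives trigger, neither negative does
  op <- rocScan(comps, cases, thresholds = -0.11, xs = 80)
  expect_identical(op$tp, 3L)
  expect_identical(op$fp, 0L)

  # full grid: row count |thresholds| x |xs|, monotone per x
  grid <- rocScan(comps, cases, thresholds = seq(-0.3, 0, 0.01),
                  xs = c(50, 80))
  expect_identical(nrow(grid), 31L * 2L)
  for (x in c(50, 80)) {
    sub <- grid[grid$x == x, ]
    sub <- sub[order(sub$threshold), ]  # increasing threshold
    expect_true(all(diff(sub$sensitivity) >= 0))
    expect_true(all(diff(sub$false_positive_rate) >= 0))
  }
  expect_error(rocScan(comps[1:3], cases, thresholds = 0, xs = 80),
               "n1", class = "cbct_precondition_error")
})

test_that("the timing audit counts agreement quadrants", {
  alerts <- list(a = mkAlert(15, "a"), b = NULL, c = mkAlert(20, "c"),
                 d = NULL)
  cases <- data.frame(plan_id = c("a", "b", "c", "d"),
                      label = c("positive", "positive", "negative", "negative"),
                      rect_fraction = c(16L, 10L, NA, NA),
                      positive_subtype = NA,
                      rt_review_fraction = c(30L, 9L, NA, 5L))
  aud <- timingAudit(alerts, cases)
  get <- function(lab, al, rt)
    aud$count[aud$label == lab & aud$alert == al & aud$rt == rt]
  expect_identical(get("positive", "+", "-"), 1L)  # a: alert on time, RT late
  expect_identical(get("positive", "-", "+"), 1L)  # b: RT on time, no alert
  expect_identical(get("negative", "+", "-"), 1L)  # c: false alert only
  expect_identical(get("negative", "-", "+"), 1L)  # d: RT reviewed anyway
})
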