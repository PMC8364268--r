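test_that("gamma is zero for identical volumes and analytic for offsets", {
  set.seed(21)
  v <- volumeGrid(array(rnorm(10^3, sd = 80), c(10, 10, 10)))
  m <- fullMask(v)
  crit <- gammaCriteria(3, 30, 9, 0)
  g <- computeGamma(v, v, m, crit)
  expect_true(all(voxelData(g)[voxelData(m)] == 0))
  expect_length(failedValues(g), 0)
  expect_identical(nEvaluated(g), 1000L)

  # uniform offsets on a constant volume force gamma = |dHU| / 30 exactly
  u <- volumeGrid(array(50, c(10, 10, 10)))
  for (off in c(15, 30, 60)) {
    ue <- volumeGrid(voxelData(u) + off)
    gg <- computeGamma(u, ue, fullMask(u), crit)
    expect_identical(unique(as.vector(voxelData(gg)[voxelData(m)])), off / 30)
  }
  # failed set is exactly the gamma > 1 voxels
  ge <- computeGamma(u, volumeGrid(voxelData(u) + 60), fullMask(u), crit)
  expect_identical(failedValues(ge), rep(2, 1000))
})

test_that("integer-grid gamma matches the exhaustive brute-force oracle", {
  set.seed(31)
  for (rep in 1:8) {
    d <- sample(6:12, 3, replace = TRUE)
    sp <- runif(3, 0.8, 3)
    ref <- array(rnorm(prod(d), sd = 60), d)
    ev <- array(rnorm(prod(d), sd = 60), d)
    mask <- array(runif(prod(d)) > 0.2, d)
    if (!any(mask)) mask[1] <- TRUE
    crit <- gammaCriteria(3, 30, 6, 0)
    g <- computeGamma(volumeGrid(ref, sp), volumeGrid(ev, sp),
                      maskVolume(mask, sp), crit)
    o <- oracleGamma(ref, ev, mask, sp, 3, 30, 6)
    expect_lt(max(abs(voxelData(g) - o), na.rm = TRUE), 1e-9)
  }
})

test_that("gamma respects shift invariance, criteria monotonicity and the zero-offset bound", {
  set.seed(41)
  d <- c(10, 10, 10)
  ref <- array(rnorm(prod(d), sd = 70), d)
  ev <- array(rnorm(prod(d), sd = 70), d)
  m <- maskVolume(array(TRUE, d))
  gam <- function(r, e, crit) voxelData(
    computeGamma(volumeGrid(r), volumeGrid(e), m, crit))

  crit <- gammaCriteria(3, 30, 9, 0)
  base <- gam(ref, ev, crit)
  # adding a constant to BOTH volumes leaves the map unchanged (up to
  # floating-point rounding of the shifted intensities)
  expect_equal(base, gam(ref + 120, ev + 120, crit), tolerance = 1e-12)
  # enlarging either criterion never increases any gamma value
  expect_true(all(gam(ref, ev, gammaCriteria(4, 30, 9, 0)) <= base + 1e-12))
  expect_true(all(gam(ref, ev, gammaCriteria(3, 45, 9, 0)) <= base + 1e-12))
  # the zero-offset candidate bounds the minimum
  expect_true(all(base <= abs(ev - ref) / 30 + 1e-12))
  # a finer (subvoxel) lattice that contains the integer offsets can only
  # lower the minimum
  sub <- voxelData(computeGamma(volumeGrid(ref, c(2, 2, 2)),
                                volumeGrid(ev, c(2, 2, 2)),
                                maskVolume(array(TRUE, d), c(2, 2, 2)),
                                gammaCriteria(3, 30, 6, 1)))
  int <- voxelData(computeGamma(volumeGrid(ref, c(2, 2, 2)),
                                volumeGrid(ev, c(2, 2, 2)),
                                maskVolume(array(TRUE, d), c(2, 2, 2)),
                                gammaCriteria(3, 30, 6, 0)))
  expect_true(all(sub <= int + 1e-12))
})

test_that("gamma preconditions and exclusions are enforced", {
  v <- rampVolume(c(6, 6, 6))
  m <- fullMask(v)
  expect_error(computeGamma(v, rampVolume(c(6, 6, 7)), m),
               class = "cbct_precondition_error")
  expect_error(computeGamma(v, rampVolume(c(6, 6, 6), spacing = c(2, 1, 1)), m),
               "grid", class = "cbct_precondition_error")
  empty <- maskVolume(array(FALSE, c(6, 6, 6)))
  expect_error(computeGamma(v, v, empty), "empty",
               class = "cbct_precondition_error")
  # interp step coarser than half the voxel is refused
  expect_error(computeGamma(v, v, m, gammaCriteria(3, 30, 9, 0.8)),
               class = "cbct_precondition_error")

  # masked non-finite reference voxels are excluded, with a logged count
  arr <- voxelData(v); arr[1, 1, 1] <- NaN
  vg <- new("VolumeGrid", data = array(0, c(6, 6, 6)),
            spacing = c(1, 1, 1), origin = c(0, 0, 0))
  vg@data <- arr  # bypass constructor: emulate a limited field of view
  expect_message(g <- computeGamma(vg, v, m), "excluded 1")
  expect_identical(g@n_excluded, 1L)
  expect_identical(nEvaluated(g), 215L)
  expect_true(is.na(voxelData(g)[1, 1, 1]))
})

test_that("failed-voxel percentiles follow the order-statistic definition", {
  # constant multiset: any percentile returns the constant
  expect_identical(failedPercentile(rep(1.5, 7), 33), 1.5)
  # median of an odd-length set
  expect_identical(failedPercentile(c(1.1, 1.2, 1.3, 1.4, 1.5), 50), 1.3)
  # large sample against the independent sort-and-index oracle
  set.seed(51)
  draws <- 1 + rexp(10000, 2)
  for (x in c(50, 80, 95))
    expect_lt(abs(failedPercentile(draws, x) - oraclePercentile(draws, x)),
              1e-12)
  # monotone in x
  xs <- seq(5, 95, by = 5)
  vals <- vapply(xs, function(x) failedPercentile(draws, x), numeric(1))
  expect_true(all(diff(vals) >= 0))
  # empty failed set: sentinel 1.0 (the pass/fail boundary)
  expect_identical(failedPercentile(numeric(0), 80), 1.0)
  expect_error(failedPercentile(draws, 0), class = "cbct_precondition_error")
  expect_error(failedPercentile(draws, 100), class = "cbct_precondition_error")
})

test_that("gamma maps and failed histograms export round-trip", {
  set.seed(61)
  v <- volumeGrid(array(rnorm(6^3, sd = 60), c(6, 6, 6)))
  e <- volumeGrid(voxelData(v) + rnorm(6^3, sd = 40))
  mask <- maskVolume(array(runif(6^3) > 0.3, c(6, 6, 6)))
  g <- computeGamma(v, e, mask, gammaCriteria(3, 30, 9, 0))
  td <- withr::local_tempdir()
  writeGammaVolume(g, file.path(td, "gamma"))
  back <- cbctalert:::readResearchPair(file.path(td, "gamma"))
  expect_true(all(is.nan(back$data[!voxelData(mask)])))
  inmask <- voxelData(mask)
  expect_identical(back$data[inmask], voxelData(g)[inmask])
  writeFailedHistogram(g, file.path(td, "hist.tsv"))
  h <- read.delim(file.path(td, "hist.tsv"))
  expect_identical(sum(h$count), length(failedValues(g)))
})
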