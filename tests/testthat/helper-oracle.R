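# Independent oracles: brute-force implementations kept deliberately
# separate from the package's kernels.

# Exhaustive integer-offset gamma search, pure R. Same discretisation as
# computeGamma with interp_step_mm = 0.
oracleGamma <- function(ref, ev, mask, spacing, dta, delta, radius) {
  d <- dim(ref)
  r <- floor(radius / spacing)
  out <- array(NA_real_, d)
  idx <- which(mask, arr.ind = TRUE)
  for (v in seq_len(nrow(idx))) {
    i <- idx[v, 1]; j <- idx[v, 2]; k <- idx[v, 3]
    best <- Inf
    for (a in -r[1]:r[1]) for (b in -r[2]:r[2]) for (cc in -r[3]:r[3]) {
      d2 <- (a * spacing[1])^2 + (b * spacing[2])^2 + (cc * spacing[3])^2
      if (d2 > radius^2 + 1e-12) next
      ii <- i + a; jj <- j + b; kk <- k + cc
      if (ii < 1 || jj < 1 || kk < 1 || ii > d[1] || jj > d[2] || kk > d[3])
        next
      g2 <- d2 / dta^2 + ((ev[ii, jj, kk] - ref[i, j, k]) / delta)^2
      if (g2 < best) best <- g2
    }
    out[i, j, k] <- sqrt(best)
  }
  out
}

# Sort-and-index empirical percentile (linear interpolation between the two
# closest order statistics).
oraclePercentile <- function(v, x) {
  s <- sort(v)
  n <- length(s)
  h <- (n - 1) * x / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Sliding-window alert scanner: first index whose trailing window of `need`
# entries is entirely strictly below the threshold.
oracleAlertIndex <- function(mqp, threshold, need) {
  for (i in seq_along(mqp)) {
    if (i < need) next
    if (all(mqp[(i - need + 1):i] < threshold)) return(i)
  }
  NA_integer_
}
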