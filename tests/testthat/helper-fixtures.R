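# Small in-code fixtures shared across test files.

# compact phantom for unit tests (full-size defaults are exercised in the
# acceptance suite)
tinyPhantom <- function(noise_sigma = 0, artifact_level = 0, ...) {
  phantomSpec(shape = c(24, 24, 24), spacing = c(6, 6, 6),
              body_half_axes = c(42, 36, 42),
              inserts = list(list(center = c(12, 0), radius = 9, hu = 700)),
              noise_sigma = noise_sigma, artifact_level = artifact_level,
              ...)
}

rampVolume <- function(d = c(8, 8, 8), spacing = c(1, 1, 1),
                       origin = c(0, 0, 0)) {
  volumeGrid(array(seq_len(prod(d)), d), spacing, origin)
}

fullMask <- function(volume)
  maskVolume(array(TRUE, dim(voxelData(volume))), voxelSpacing(volume),
             voxelOrigin(volume))

# MqpSeries with prescribed MQP values (first entry must be 0)
mkSeries <- function(mqp, fractions = seq_along(mqp), plan_id = "t") {
  new("MqpSeries", plan_id = plan_id, x = 80, gamma_ref = 1.5,
      entries = data.frame(acquisition = seq_along(mqp) + 1L,
                           fraction = as.integer(fractions), mqp = mqp))
}

# CourseComparison whose x = 80 MQP series equals `mqp` exactly: each
# entry's failed set is a single value, so every percentile equals it.
mkComparison <- function(mqp, fractions = seq_along(mqp), plan_id = "t",
                         gamma_ref = 1.5) {
  new("CourseComparison", plan_id = plan_id, ref_fraction = 0L,
      fractions = as.integer(fractions),
      acquisitions = seq_along(mqp) + 1L,
      failed_values = lapply(gamma_ref - mqp, function(g) g),
      n_evaluated = rep(100L, length(mqp)), criteria = gammaCriteria())
}
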