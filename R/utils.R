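# Internal helpers: error condition classes, seeded RNG scope, display rounding.

stopFormat <- function(...) {
  stop(errorCondition(paste0(...), class = c("cbct_format_error", "error", "condition")))
}

stopPrecond <- function(...) {
  stop(errorCondition(paste0(...), class = c("cbct_precondition_error", "error", "condition")))
}

# Evaluate expr with a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval(expr, envir = parent.frame())
}

# Derive a stream of sub-seeds from one master seed, each < 2^31.
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Round half-up for display
#'
#' Rounds half-way cases away from zero (so 0.765 displays as 0.77), matching
#' the reporting convention used for sensitivity and false positive rate.
#' Full precision is always retained internally; this only formats output.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
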