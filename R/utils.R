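#' Derive a reproducible child seed from a root seed
#'
#' All stochastic stages draw their RNG state from one root seed through this
#' derivation, so a pipeline run is fully determined by the root seed while the
#' stages remain statistically decoupled. Character keys (subject identifiers,
#' stage names) are hashed by code-point sum.
#'
#' @param seed integer root seed.
#' @param ... integer or character keys identifying the consumer
#'   (e.g. subject id, timepoint, synergy order, restart index).
#' @return a single integer in `[0, 2^31 - 20)`.
#' @export
derive_seed <- function(seed, ...) {
  keys <- list(...)
  acc <- as.numeric(seed) %% 2147483629
  for (k in keys) {
    if (is.character(k)) {
      # position-dependent fold so permuted labels hash differently
      k <- unlist(lapply(k, utf8ToInt))
    }
    for (v in as.numeric(k)) {
      acc <- (acc * 48271 + v + 1) %% 2147483629
    }
  }
  as.integer(acc)
}

with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "kicksyn_invalid_parameter")
  }
}

#' @noRd
check_nonneg_matrix <- function(x, name = "data") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", name),
          class = "kicksyn_invalid_parameter")
  }
  if (any(!is.finite(x)) || any(x < 0)) {
    abort(sprintf("`%s` must be finite and non-negative.", name),
          class = "kicksyn_invalid_parameter")
  }
  invisible(x)
}
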