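#' Activation-timing metrics of one synergy activation profile
#'
#' Reduces a non-negative activation coefficient over the normalised cycle to
#' three timing parameters, all expressed as fractions of the cycle:
#'
#' * **peak time** (`Tmax`): index of the maximum, as `(argmax - 1)/(n - 1)`;
#'   ties resolve to the earliest index.
#' * **duration** (`T`): fraction of samples at or above
#'   `threshold_frac * max` (the threshold is relative, so timing is invariant
#'   to rescaling the activation).
#' * **onset** (`Tstart`): start of the longest contiguous supra-threshold
#'   run, treating the cycle as circular - a burst spanning the cycle wrap is
#'   one burst, and its onset can numerically follow its peak.
#'
#' @param activation non-negative numeric vector (typically length 100), not
#'   identically zero.
#' @param threshold_frac burst-detection threshold as a fraction of the
#'   profile maximum.
#' @return tibble with `duration`, `peak_time`, `onset_time`, all in `[0, 1]`.
#' @export
activation_timing <- function(activation, threshold_frac = 0.20) {
  if (any(!is.finite(activation)) || any(activation < 0)) {
    abort("`activation` must be finite and non-negative.",
          class = "kicksyn_invalid_parameter")
  }
  n <- length(activation)
  if (n < 2 || all(activation == 0)) {
    abort("`activation` must be non-degenerate (length >= 2, not all zero).",
          class = "kicksyn_degenerate_activation")
  }
  peak_idx <- which.max(activation)
  active <- activation >= threshold_frac * activation[peak_idx]
  duration <- sum(active) / n
  if (all(active)) {
    onset_idx <- 1L
  } else {
    # rotate so the series starts inside an inactive stretch, then the longest
    # TRUE run in the rotated series is the longest circular run
    shift <- which(!active)[1] - 1L
    rotated <- active[((seq_len(n) - 1L + shift) %% n) + 1L]
    r <- rle(rotated)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    true_runs <- which(r$values)
    best <- true_runs[which.max(r$lengths[true_runs])]
    onset_idx <- ((starts[best] - 1L + shift) %% n) + 1L
  }
  tibble(duration = duration,
         peak_time = (peak_idx - 1) / (n - 1),
         onset_time = (onset_idx - 1) / (n - 1))
}

#' Timing metrics for every matched synergy of a study
#'
#' Applies [activation_timing()] to the activation coefficient of each
#' matched synergy, labelling rows by the matched reference index so that
#' timing parameters are comparable across subjects and timepoints.
#'
#' @param synergies an [extract_synergies()] tibble.
#' @param matches the corresponding [match_study()] tibble.
#' @param threshold_frac burst-detection threshold.
#' @return tidy tibble: `subject_id`, `group`, `timepoint`, `ref`,
#'   `duration`, `peak_time`, `onset_time`.
#' @export
activation_timings <- function(synergies, matches, threshold_frac = 0.20) {
  matched <- matches[!is.na(matches$ref), ]
  if (nrow(matched) == 0) {
    return(tibble(subject_id = character(), group = character(),
                  timepoint = character(), ref = integer(),
                  duration = numeric(), peak_time = numeric(),
                  onset_time = numeric()))
  }
  rows <- purrr::pmap(matched, function(subject_id, group, timepoint,
                                        synergy, ref, r) {
    fit <- synergies$fit[[which(synergies$subject_id == subject_id &
                                  synergies$timepoint == timepoint)[1]]]
    activation_timing(fit$activations[synergy, ], threshold_frac) |>
      dplyr::mutate(subject_id = subject_id, group = group,
                    timepoint = timepoint, ref = ref, .before = 1)
  })
  dplyr::bind_rows(rows)
}
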