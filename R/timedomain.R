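#' Integrated EMG of a rectified series
#'
#' Time-integral of the rectified signal. In `"integral"` mode (the default)
#' the sample sum is multiplied by the sampling interval so the result carries
#' microvolt-second units; `"sum"` mode returns the bare sample sum, matching
#' the discrete textbook formula without the time step.
#'
#' @param x rectified (non-negative) numeric series, microvolts.
#' @param fs sampling rate, Hz.
#' @param mode `"integral"` (microvolt-seconds) or `"sum"`.
#' @return scalar iEMG.
#' @export
iemg <- function(x, fs, mode = c("integral", "sum")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || any(!is.finite(x))) {
    abort("`x` must be a non-empty finite series.",
          class = "kicksyn_invalid_parameter")
  }
  if (any(x < 0)) {
    abort("iEMG expects a rectified (non-negative) series.",
          class = "kicksyn_invalid_parameter")
  }
  s <- sum(x)
  if (mode == "integral") s / fs else s
}

#' Root-mean-square amplitude
#'
#' @param x numeric series, microvolts.
#' @return `sqrt(mean(x^2))`.
#' @export
rms_amplitude <- function(x) {
  if (length(x) == 0 || any(!is.finite(x))) {
    abort("`x` must be a non-empty finite series.",
          class = "kicksyn_invalid_parameter")
  }
  sqrt(mean(x^2))
}

#' Phase-wise iEMG and RMS for one cycle of one recording
#'
#' Computes both time-domain metrics on the rectified band-passed signal
#' (microvolt scale, not MVC-normalised) restricted to each phase's half-open
#' sample range. Phase windows are taken on the original-rate signal, not on
#' the 100-point resampled cycle.
#'
#' @param filt matrix `n_muscles x n_samples` of band-passed EMG (rows named).
#' @param cycle one row of [segment_cycles()] output.
#' @param fs sampling rate, Hz.
#' @param mode iEMG mode, see [iemg()].
#' @return tibble with one row per phase x muscle: `phase`, `muscle`, `iemg`,
#'   `rms`.
#' @export
phase_metrics <- function(filt, cycle, fs, mode = "integral") {
  bounds <- c(cycle$start, cycle$phase1, cycle$phase2, cycle$end)
  if (is.unsorted(bounds, strictly = TRUE)) {
    abort("Phase boundaries must strictly partition the cycle.",
          class = "kicksyn_degenerate_segment")
  }
  phases <- c("up_swing", "downward", "transition")
  rows <- purrr::map(seq_along(phases), function(p) {
    rng <- (bounds[p] + 1):bounds[p + 1] # half-open [bounds[p], bounds[p+1])
    seg <- abs(filt[, rng, drop = FALSE])
    tibble(phase = phases[p], muscle = rownames(filt),
           iemg = unname(apply(seg, 1, iemg, fs = fs, mode = mode)),
           rms = unname(apply(seg, 1, rms_amplitude)))
  })
  dplyr::bind_rows(rows)
}

#' Phase-wise time-domain metrics for every recording of a study
#'
#' Band-passes each recording, selects the representative (median-duration)
#' cycle, and tabulates per-phase iEMG and RMS per muscle on the rectified
#' microvolt-scale signal.
#'
#' @param study a [simulate_kick_study()] object.
#' @param mode iEMG mode, see [iemg()].
#' @return tidy tibble: `subject_id`, `group`, `timepoint`, `phase`,
#'   `muscle`, `iemg` (microvolt-seconds), `rms` (microvolts).
#' @export
time_domain_table <- function(study, mode = "integral") {
  stopifnot(inherits(study, "kick_study"))
  cfg <- study$config
  rows <- purrr::pmap(study$recordings, function(subject_id, group, timepoint,
                                                 emg, events, ...) {
    filt <- t(apply(emg, 1, bandpass_filter, fs = cfg$fs,
                    low = cfg$band[1], high = cfg$band[2],
                    order = cfg$filter_order))
    dimnames(filt) <- dimnames(emg)
    rep_cyc <- representative_cycle(segment_cycles(events, cfg$fs, ncol(emg)))
    phase_metrics(filt, rep_cyc, cfg$fs, mode) |>
      dplyr::mutate(subject_id = subject_id, group = group,
                    timepoint = timepoint, .before = 1)
  })
  dplyr::bind_rows(rows)
}
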