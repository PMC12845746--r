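#' Zero-phase Butterworth band-pass filter
#'
#' Applies a Butterworth band-pass (design order `order`, default 20-400 Hz)
#' forwards and backwards (`signal::filtfilt`), removing DC/drift and
#' high-frequency noise without phase lag. Zero-phase filtering squares the
#' magnitude response, which matters when predicting pass-band gain.
#'
#' @param x numeric vector, one EMG channel.
#' @param fs sampling rate, Hz.
#' @param low,high band edges, Hz; must satisfy `0 < low < high < fs/2`.
#' @param order Butterworth design order.
#' @return filtered series, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, low = 20, high = 400, order = 4) {
  if (!is.numeric(x) || length(x) < 2) {
    abort("`x` must be a numeric series.", class = "kicksyn_invalid_parameter")
  }
  if (!(low > 0 && low < high && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < fs/2.",
          class = "kicksyn_invalid_band")
  }
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Linear envelope of a band-passed EMG channel
#'
#' Full-wave rectifies the signal and smooths it with a zero-phase Butterworth
#' low-pass (default 20 Hz, design order 4). Filter ringing can dip slightly
#' below zero, so the result is clipped at 0 to keep downstream factorisation
#' inputs non-negative.
#'
#' @param x numeric vector; expected to be band-passed already.
#' @param fs sampling rate, Hz.
#' @param cutoff low-pass cutoff, Hz; must be below `fs/2`.
#' @param order Butterworth design order.
#' @return non-negative envelope, same length as `x`.
#' @export
linear_envelope <- function(x, fs, cutoff = 20, order = 4) {
  if (!(cutoff > 0 && cutoff < fs / 2)) {
    abort("`cutoff` must lie in (0, fs/2).", class = "kicksyn_invalid_band")
  }
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  pmax(0, as.numeric(signal::filtfilt(bf, abs(x))))
}

#' Maximum sliding-window RMS of a series
#'
#' @param x numeric vector.
#' @param window window length in samples.
#' @return largest RMS over all full windows.
#' @keywords internal
#' @noRd
max_sliding_rms <- function(x, window) {
  n <- length(x)
  if (window > n) {
    abort("Trial shorter than the RMS window.", class = "kicksyn_invalid_mvc")
  }
  cs <- cumsum(c(0, x^2))
  sqrt(max(cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window)
}

#' MVC normalisation reference per muscle
#'
#' Implements the calibration rule: per muscle, each MVC trial is band-pass
#' filtered, the RMS amplitude is computed over every 1 s sliding window, and
#' the normalisation denominator is the largest windowed RMS across trials.
#' "Stable" is operationalised as the window maximising RMS, which is
#' deterministic and needs no manual stability judgement.
#'
#' @param mvc_trials named list (one element per muscle) of lists of numeric
#'   trial vectors.
#' @param fs sampling rate, Hz.
#' @param window_s window length, seconds.
#' @param band,order band-pass settings applied before the RMS.
#' @return tibble with columns `muscle`, `mvc` (microvolt RMS).
#' @export
mvc_reference <- function(mvc_trials, fs, window_s = 1.0,
                          band = c(20, 400), order = 4) {
  if (!is.list(mvc_trials) || is.null(names(mvc_trials)) ||
      any(names(mvc_trials) == "")) {
    abort("`mvc_trials` must be a named list keyed by muscle.",
          class = "kicksyn_invalid_mvc")
  }
  window <- round(window_s * fs)
  vals <- purrr::map_dbl(mvc_trials, function(trials) {
    if (!is.list(trials)) trials <- list(trials)
    if (length(trials) == 0) {
      abort("Each muscle needs at least one MVC trial.",
            class = "kicksyn_invalid_mvc")
    }
    max(purrr::map_dbl(trials, function(tr) {
      filt <- bandpass_filter(tr, fs, band[1], band[2], order)
      max_sliding_rms(filt, window)
    }))
  })
  if (any(vals <= 0)) {
    abort("All-zero MVC trials would produce a divide-by-zero denominator.",
          class = "kicksyn_invalid_mvc")
  }
  tibble(muscle = names(mvc_trials), mvc = unname(vals))
}

#' Segment a recording into kick cycles from event timestamps
#'
#' Cycles run from one `cycle_start` to the next (half-open, 0-based sample
#' indices); the final cycle may be closed by a `cycle_end` event. Each cycle
#' must contain exactly one `phase1_end` and one `phase2_end` mark splitting
#' it into up-swing / downward / transition phases.
#'
#' @param events tibble with columns `event`
#'   (`cycle_start`/`phase1_end`/`phase2_end`/`cycle_end`) and `time_s`.
#' @param fs sampling rate, Hz.
#' @param n_samples number of samples in the recording (bounds check).
#' @return tibble with one row per cycle: `cycle`, `start`, `end`, `phase1`,
#'   `phase2` (0-based sample indices, `[start, end)`), `duration_s`.
#' @export
segment_cycles <- function(events, fs, n_samples = Inf) {
  req <- c("event", "time_s")
  if (!all(req %in% names(events))) {
    abort("`events` needs columns event and time_s.",
          class = "kicksyn_event_stream")
  }
  # one-sample slack: event times digitised independently of the sample grid
  if (any(events$time_s < 0 | events$time_s > (n_samples + 1) / fs)) {
    abort("Event times fall outside the recording.",
          class = "kicksyn_event_stream")
  }
  starts <- sort(events$time_s[events$event == "cycle_start"])
  ends <- events$time_s[events$event == "cycle_end"]
  bounds <- c(starts, if (length(ends)) max(ends))
  if (length(bounds) < 2) {
    abort("Need at least two cycle boundaries (cycle_start/cycle_end events).",
          class = "kicksyn_event_stream")
  }
  if (is.unsorted(bounds, strictly = TRUE)) {
    abort("Cycle boundary events are not strictly increasing.",
          class = "kicksyn_event_stream")
  }
  n_cyc <- length(bounds) - 1
  p1 <- sort(events$time_s[events$event == "phase1_end"])
  p2 <- sort(events$time_s[events$event == "phase2_end"])
  out <- vector("list", n_cyc)
  for (i in seq_len(n_cyc)) {
    lo <- bounds[i]; hi <- bounds[i + 1]
    m1 <- p1[p1 >= lo & p1 < hi]
    m2 <- p2[p2 >= lo & p2 < hi]
    if (length(m1) != 1 || length(m2) != 1 || m2 <= m1) {
      abort(sprintf("Cycle %d lacks ordered phase1_end/phase2_end marks.", i),
            class = "kicksyn_event_stream")
    }
    out[[i]] <- tibble(cycle = i,
                       start = round(lo * fs),
                       end = min(round(hi * fs), n_samples),
                       phase1 = round(m1 * fs), phase2 = round(m2 * fs),
                       duration_s = hi - lo)
  }
  dplyr::bind_rows(out)
}

#' MVC- and time-normalise one envelope cycle
#'
#' Divides each muscle's envelope by its MVC reference, resamples every row to
#' exactly 100 points by linear interpolation on a uniform grid over the
#' cycle, and rescales the phase-boundary samples proportionally (rounded to
#' the nearest grid index). Constant rows and row endpoints are preserved
#' exactly by linear interpolation.
#'
#' @param env matrix `n_muscles x n_cycle_samples` of envelopes (rows named by
#'   muscle), microvolts.
#' @param mvc tibble from [mvc_reference()] (or named vector), covering every
#'   row of `env`.
#' @param phase_samples two within-cycle sample offsets (0-based) of the phase
#'   boundaries.
#' @return a `kick_envelope` with a non-negative `n_muscles x 100` `activity`
#'   matrix (MVC units) and `phase_idx` on the 1..100 grid.
#' @export
normalize_cycle <- function(env, mvc, phase_samples) {
  check_nonneg_matrix(env, "env")
  n <- ncol(env)
  if (n < 2) {
    abort("A cycle needs at least two samples.",
          class = "kicksyn_invalid_parameter")
  }
  if (is.data.frame(mvc)) mvc <- setNames(mvc$mvc, mvc$muscle)
  missing <- setdiff(rownames(env), names(mvc))
  if (is.null(rownames(env)) || length(missing)) {
    abort(sprintf("MVC reference missing for: %s",
                  paste(missing, collapse = ", ")),
          class = "kicksyn_missing_mvc")
  }
  scaled <- env / mvc[rownames(env)]
  grid <- seq(0, n - 1, length.out = 100)
  act <- t(apply(scaled, 1, function(row) approx(0:(n - 1), row, grid)$y))
  act[act < 0] <- 0
  dimnames(act) <- list(rownames(env), NULL)
  idx <- as.integer(round(phase_samples / (n - 1) * 99) + 1)
  structure(list(activity = act, phase_idx = idx,
                 subject_id = NA_character_, group = NA_character_,
                 timepoint = NA_character_),
            class = "kick_envelope")
}

#' Pick the representative cycle (median duration)
#' @noRd
representative_cycle <- function(cycles) {
  ord <- order(cycles$duration_s)
  cycles[ord[ceiling(length(ord) / 2)], , drop = FALSE]
}

#' MVC references for every subject of a synthetic study
#'
#' @param study a [simulate_kick_study()] object.
#' @return tibble `subject_id`, `muscle`, `mvc`.
#' @export
mvc_references <- function(study) {
  stopifnot(inherits(study, "kick_study"))
  cfg <- study$config
  study$mvc |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::group_modify(function(df, key) {
      trials <- split(df$signal, df$muscle)
      mvc_reference(trials[unique(df$muscle)], fs = cfg$fs,
                    window_s = cfg$mvc_window, band = cfg$band,
                    order = cfg$filter_order)
    }) |>
    dplyr::ungroup()
}

#' Preprocess every recording of a study into normalised envelope cycles
#'
#' Runs the full preprocessing chain per recording: band-pass, rectification +
#' envelope low-pass, cycle segmentation from the event stream, selection of
#' the representative (median-duration) cycle, MVC normalisation and 100-point
#' time normalisation.
#'
#' @param study a [simulate_kick_study()] object.
#' @param mvc optional precomputed [mvc_references()] tibble.
#' @return tibble of class `kick_envelopes`: one row per subject x timepoint
#'   with list-columns `envelope` (`kick_envelope`) and `cycle` (the chosen
#'   cycle's segmentation row).
#' @export
preprocess_study <- function(study, mvc = NULL) {
  stopifnot(inherits(study, "kick_study"))
  cfg <- study$config
  if (is.null(mvc)) mvc <- mvc_references(study)
  rows <- purrr::pmap(study$recordings, function(subject_id, group, timepoint,
                                                 emg, events, ...) {
    filt <- t(apply(emg, 1, bandpass_filter, fs = cfg$fs,
                    low = cfg$band[1], high = cfg$band[2],
                    order = cfg$filter_order))
    env <- t(apply(filt, 1, linear_envelope, fs = cfg$fs,
                   cutoff = cfg$envelope_cutoff, order = cfg$filter_order))
    dimnames(env) <- dimnames(emg)
    cycles <- segment_cycles(events, cfg$fs, ncol(emg))
    rep_cyc <- representative_cycle(cycles)
    rng <- (rep_cyc$start + 1):rep_cyc$end
    sub_mvc <- mvc[mvc$subject_id == subject_id, c("muscle", "mvc")]
    ec <- normalize_cycle(env[, rng, drop = FALSE], sub_mvc,
                          c(rep_cyc$phase1, rep_cyc$phase2) - rep_cyc$start)
    ec$subject_id <- subject_id; ec$group <- group; ec$timepoint <- timepoint
    tibble(subject_id = subject_id, group = group, timepoint = timepoint,
           envelope = list(ec), cycle = list(rep_cyc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("kick_envelopes", class(out))
  out
}

#' @export
tidy.kick_envelope <- function(x, ...) {
  act <- x$activity
  tibble(muscle = rep(rownames(act), each = ncol(act)),
         t = rep(seq_len(ncol(act)), nrow(act)),
         value = as.vector(t(act)))
}
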