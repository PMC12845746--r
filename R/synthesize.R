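#' Band-limited unit-RMS carrier noise
#' @noRd
carrier_noise <- function(n, fs, band = c(20, 400), order = 4) {
  raw <- rnorm(n)
  filt <- bandpass_filter(raw, fs, band[1], band[2], order)
  r <- sqrt(mean(filt^2))
  if (r == 0) filt else filt / r
}

#' Synthesise a raw multichannel sEMG trial from envelope cycles
#'
#' Emulates raw interference-pattern EMG by amplitude-modulating a
#' band-limited (20-400 Hz) Gaussian carrier with each muscle's time-stretched
#' envelope. Cycle-start, phase-boundary and cycle-end event timestamps are
#' emitted alongside the samples, mirroring how event marks digitised from
#' synchronised video accompany real recordings.
#'
#' @param envelopes list of `kick_envelope` objects, one per cycle (activity
#'   in MVC-normalised units).
#' @param fs sampling rate, Hz (>= 1000).
#' @param cycle_durations cycle durations in seconds, one per envelope.
#' @param gain_uV per-muscle MVC-level amplitude in microvolts; the raw signal
#'   is `envelope * gain_uV * carrier`.
#' @param phase_bounds phase-split fractions used for the event marks.
#' @param seed integer seed for the carrier noise.
#' @return list with `emg` (matrix `n_muscles x n_samples`, microvolts) and
#'   `events` (tibble `event`, `time_s`).
#' @export
synthesize_raw_trial <- function(envelopes, fs, cycle_durations, gain_uV,
                                 phase_bounds = c(0.4, 0.8), seed = 1) {
  if (fs < 1000) {
    abort("`fs` must be at least 1000 Hz.", class = "kicksyn_invalid_parameter")
  }
  if (inherits(envelopes, "kick_envelope")) envelopes <- list(envelopes)
  if (any(cycle_durations <= 0)) {
    abort("Cycle durations must be positive.",
          class = "kicksyn_invalid_parameter")
  }
  if (length(cycle_durations) != length(envelopes)) {
    abort("Need one duration per envelope cycle.",
          class = "kicksyn_invalid_parameter")
  }
  muscles <- rownames(envelopes[[1]]$activity)
  n_mus <- length(muscles)
  if (length(gain_uV) == 1) gain_uV <- rep(gain_uV, n_mus)
  ns <- round(cycle_durations * fs)
  total <- sum(ns)
  with_seed(seed, {
    emg <- matrix(0, n_mus, total, dimnames = list(muscles, NULL))
    for (m in seq_len(n_mus)) {
      stretched <- unlist(purrr::map2(envelopes, ns, function(ec, n) {
        approx(0:99, ec$activity[m, ], seq(0, 99, length.out = n))$y
      }))
      if (all(stretched == 0)) next
      emg[m, ] <- stretched * gain_uV[m] * carrier_noise(total, fs)
    }
    starts_s <- cumsum(c(0, cycle_durations))
    events <- dplyr::bind_rows(
      tibble(event = "cycle_start", time_s = starts_s[seq_along(ns)]),
      tibble(event = "phase1_end",
             time_s = starts_s[seq_along(ns)] + phase_bounds[1] * cycle_durations),
      tibble(event = "phase2_end",
             time_s = starts_s[seq_along(ns)] + phase_bounds[2] * cycle_durations),
      tibble(event = "cycle_end", time_s = starts_s[length(starts_s)]))
    list(emg = emg, events = dplyr::arrange(events, .data$time_s))
  })
}

#' Session-level truth for one subject x timepoint
#' @noRd
session_truth <- function(base, subj, group, timepoint, cfg, seed) {
  with_seed(seed, {
    w <- subj$weights * matrix(rlnorm(length(subj$weights), 0,
                                      cfg$session_jitter_sdlog),
                               nrow(subj$weights)) +
      matrix(rnorm(length(subj$weights), 0, cfg$session_jitter_add),
             nrow(subj$weights))
    w[w < 0] <- 0
    centers <- (subj$centers + rnorm(length(subj$centers), 0, 0.015)) %% 1
    widths <- subj$widths * rlnorm(length(subj$widths), 0,
                                   cfg$session_jitter_sdlog)
    eff <- cfg$effects
    if (!is.null(eff) && eff$enabled && group == "EXP" && timepoint == "post") {
      idx <- match(eff$weight_muscles, rownames(w))
      w[idx, eff$weight_synergy] <- w[idx, eff$weight_synergy] *
        eff$weight_multiplier
      widths[eff$duration_synergy] <- widths[eff$duration_synergy] *
        eff$width_multiplier
    }
    list(weights = normalize_columns(w),
         activations = activation_bumps(centers, widths),
         centers = centers, widths = widths)
  })
}

#' Simulate a complete two-group pre/post kick study
#'
#' Generates the full synthetic dataset the analysis pipeline consumes:
#' per-subject ground-truth synergies (a seeded jitter of the template truth),
#' MVC calibration trials whose plateau matches each subject's MVC-level
#' amplitude, and per-timepoint raw multichannel trials of several kick cycles
#' with event timestamps. Experimental-group post-intervention sessions apply
#' the configured [kick_effects()]; every other arm differs only by session
#' jitter and noise.
#'
#' @param config a [kick_config()].
#' @param seed root seed (defaults to `config$seed`).
#' @return object of class `kick_study`: nested tibbles `recordings`
#'   (`subject_id`, `group`, `timepoint`, `emg`, `events`), `mvc`
#'   (`subject_id`, `muscle`, `trial`, `signal`), and `truth` (per-session
#'   weights/activations/scale and the modulating envelopes of every cycle,
#'   plus the representative-cycle index).
#' @examples
#' \donttest{
#' study <- simulate_kick_study(kick_config(n_per_group = 2), seed = 1)
#' study$recordings
#' }
#' @export
simulate_kick_study <- function(config = kick_config(), seed = config$seed) {
  stopifnot(inherits(config, "kick_config"))
  cfg <- config
  n_mus <- length(cfg$muscles)
  template <- if (n_mus == 10 && cfg$n_syn == 3) "freestyle" else "random"
  base <- make_ground_truth(n_mus, cfg$n_syn, seed = derive_seed(seed, "truth"),
                            template = template, muscles = cfg$muscles,
                            phase_bounds = cfg$phase_bounds,
                            noise_sd = cfg$noise_sd)
  subjects <- tibble(
    subject_id = c(sprintf("EXP%02d", seq_len(cfg$n_per_group)),
                   sprintf("CON%02d", seq_len(cfg$n_per_group))),
    group = rep(c("EXP", "CON"), each = cfg$n_per_group))

  rec_rows <- list(); mvc_rows <- list(); truth_rows <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]; grp <- subjects$group[i]
    s_seed <- derive_seed(seed, "subject", sid)
    subj <- with_seed(s_seed, {
      w <- base$weights * matrix(rlnorm(length(base$weights), 0,
                                        cfg$weight_jitter_sdlog), n_mus) +
        matrix(rnorm(length(base$weights), 0, cfg$weight_jitter_add), n_mus)
      w[w < 0] <- 0
      list(weights = normalize_columns(w),
           centers = (base$centers + rnorm(cfg$n_syn, 0, 0.02)) %% 1,
           widths = base$widths * rlnorm(cfg$n_syn, 0, 0.10),
           scale = rlnorm(1, cfg$subject_scale_meanlog,
                          cfg$subject_scale_sdlog),
           mvc_uV = cfg$mvc_uV * rlnorm(n_mus, 0, 0.2))
    })

    # MVC calibration trials: ramp up, hold a stable plateau > 1 s, ramp down
    mvc_n <- round(cfg$mvc_duration * cfg$fs)
    ramp <- round(0.5 * cfg$fs)
    profile <- c(seq(0, 1, length.out = ramp),
                 rep(1, mvc_n - 2 * ramp),
                 seq(1, 0, length.out = ramp))
    trial_peaks <- with_seed(derive_seed(s_seed, "mvcpeaks"),
                             c(1, runif(cfg$mvc_trials - 1, 0.85, 0.98)))
    for (m in seq_len(n_mus)) {
      for (tr in seq_len(cfg$mvc_trials)) {
        sig <- with_seed(derive_seed(s_seed, "mvc", m, tr), {
          profile * trial_peaks[tr] * subj$mvc_uV[m] *
            carrier_noise(mvc_n, cfg$fs, cfg$band, cfg$filter_order)
        })
        mvc_rows[[length(mvc_rows) + 1]] <-
          tibble(subject_id = sid, muscle = cfg$muscles[m], trial = tr,
                 signal = list(sig))
      }
    }

    for (tp in c("pre", "post")) {
      t_seed <- derive_seed(s_seed, tp)
      st <- session_truth(base, subj, grp, tp, cfg, t_seed)
      sess_truth <- list(weights = st$weights, activations = st$activations,
                         centers = st$centers, widths = st$widths)
      # one lead-in and one lead-out cycle flank the digitised cycles so the
      # analysed data sit away from the recording edges (trials are continuous
      # swimming; the digitised cycles come from the middle of the lap)
      n_all <- cfg$n_cycles + 2L
      durations <- with_seed(derive_seed(t_seed, "dur"),
        cfg$cycle_duration *
          (1 + runif(n_all, -cfg$cycle_jitter, cfg$cycle_jitter)))
      sess_tr <- structure(c(sess_truth,
                             list(phase_bounds = cfg$phase_bounds,
                                  muscles = cfg$muscles,
                                  n_syn = cfg$n_syn, noise_sd = cfg$noise_sd)),
                           class = "kick_truth")
      envs <- purrr::map(seq_len(n_all), function(cyc) {
        synthesize_envelope_cycle(sess_tr, subject_scale = subj$scale,
                                  noise_sd = cfg$noise_sd,
                                  seed = derive_seed(t_seed, "env", cyc))
      })
      raw <- synthesize_raw_trial(envs, cfg$fs, durations, subj$mvc_uV,
                                  cfg$phase_bounds,
                                  seed = derive_seed(t_seed, "carrier"))
      keep <- 2:(n_all - 1L)
      starts_s <- cumsum(c(0, durations))
      events <- dplyr::bind_rows(
        tibble(event = "cycle_start", time_s = starts_s[keep]),
        tibble(event = "phase1_end",
               time_s = starts_s[keep] + cfg$phase_bounds[1] * durations[keep]),
        tibble(event = "phase2_end",
               time_s = starts_s[keep] + cfg$phase_bounds[2] * durations[keep]),
        tibble(event = "cycle_end", time_s = starts_s[n_all])) |>
        dplyr::arrange(.data$time_s)
      rep_idx <- order(durations[keep])[ceiling(cfg$n_cycles / 2)]
      envs <- envs[keep]
      rec_rows[[length(rec_rows) + 1]] <-
        tibble(subject_id = sid, group = grp, timepoint = tp,
               emg = list(raw$emg), events = list(events))
      truth_rows[[length(truth_rows) + 1]] <-
        tibble(subject_id = sid, group = grp, timepoint = tp,
               weights = list(st$weights), activations = list(st$activations),
               widths = list(st$widths), centers = list(st$centers),
               scale = subj$scale,
               envelopes = list(purrr::map(envs, "activity")),
               representative = rep_idx)
    }
  }
  structure(list(recordings = dplyr::bind_rows(rec_rows),
                 mvc = dplyr::bind_rows(mvc_rows),
                 truth = list(base = base,
                              sessions = dplyr::bind_rows(truth_rows)),
                 config = cfg, seed = as.integer(seed)),
            class = "kick_study")
}

#' @export
print.kick_study <- function(x, ...) {
  cat(sprintf("<kick_study> %d recordings (%d subjects x 2 timepoints), %d muscles @ %g Hz\n",
              nrow(x$recordings), nrow(x$recordings) / 2,
              length(x$config$muscles), x$config$fs))
  invisible(x)
}
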