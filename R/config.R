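#' Muscles monitored in the freestyle-kick montage
#'
#' The ten-muscle right-side montage used throughout the package: ankle
#' dorsiflexor/plantarflexors, hip adductors, knee flexor, hip extensor and
#' trunk muscles. The generator and the analysis treat labels as opaque
#' ordered strings, so any montage of the same length works.
#'
#' @return character vector of ten muscle labels.
#' @export
kick_muscles <- function() {
  c("tibialis_anterior", "gastrocnemius_medialis", "gastrocnemius_lateralis",
    "adductor_longus", "adductor_magnus", "biceps_femoris", "gluteus_maximus",
    "rectus_abdominis", "latissimus_dorsi", "trapezius")
}

#' Intervention effect specification for the synthetic study
#'
#' Describes how the experimental group's post-intervention sessions differ
#' from every other arm. Effects are multiplicative: selected muscle weights of
#' one synergy are scaled up (the weight is then re-normalised with the rest of
#' its column), and the activation-burst width of another synergy is scaled
#' down, shortening its supra-threshold duration. The defaults mirror the kind
#' of adaptation a combined electrical-stimulation + in-water resistance
#' program is reported to produce: stronger weighting of hip
#' adductor/knee-flexor prime movers inside the propulsion-like synergy and a
#' more transient postural-like burst.
#'
#' @param weight_synergy index of the synergy whose weights are boosted.
#' @param weight_muscles muscles (labels) whose weights are multiplied.
#' @param weight_multiplier multiplier applied to those weights (> 0).
#' @param duration_synergy index of the synergy whose burst is shortened.
#' @param width_multiplier multiplier applied to that synergy's burst width.
#' @param enabled logical; `FALSE` gives a null intervention (noise only).
#' @return a list of class `kick_effects`.
#' @export
kick_effects <- function(weight_synergy = 3,
                         weight_muscles = c("adductor_longus", "biceps_femoris"),
                         weight_multiplier = 1.8,
                         duration_synergy = 2,
                         width_multiplier = 0.55,
                         enabled = TRUE) {
  stopifnot_scalar_number(weight_multiplier, "weight_multiplier")
  stopifnot_scalar_number(width_multiplier, "width_multiplier")
  if (weight_multiplier <= 0 || width_multiplier <= 0) {
    abort("Effect multipliers must be positive.",
          class = "kicksyn_invalid_parameter")
  }
  structure(
    list(weight_synergy = as.integer(weight_synergy),
         weight_muscles = weight_muscles,
         weight_multiplier = weight_multiplier,
         duration_synergy = as.integer(duration_synergy),
         width_multiplier = width_multiplier,
         enabled = isTRUE(enabled)),
    class = "kick_effects")
}

#' Pipeline configuration with study defaults
#'
#' One flat configuration object drives both the synthetic-data generator and
#' every analysis stage. Defaults reproduce the study conditions: 15 subjects
#' per group measured pre and post, ten muscles sampled at 2000 Hz, a
#' three-synergy kick cycle split at 40 % / 80 % into up-swing, downward and
#' transition phases, a 20-400 Hz 4th-order band-pass with a 20 Hz envelope
#' low-pass, MVC normalisation by the best 1 s sliding-window RMS, NMF order
#' selection at VAF > 90 %, K-means repeated 1000 times, a Gap statistic with
#' B = 100 uniform reference draws, a 0.6 Pearson matching threshold, a 20 %
#' burst-detection threshold, and alpha = 0.05.
#'
#' @param n_per_group subjects per group (EXP / CON).
#' @param muscles ordered muscle labels.
#' @param n_syn number of ground-truth synergies in the generator.
#' @param fs sampling rate, Hz.
#' @param cycle_duration nominal kick-cycle duration, seconds.
#' @param cycle_jitter relative jitter of individual cycle durations.
#' @param n_cycles cycles recorded per trial (the median-duration one is
#'   analysed).
#' @param phase_bounds two fractions in (0,1) splitting the cycle into
#'   up-swing / downward / transition.
#' @param noise_sd additive envelope noise SD, MVC-normalised units.
#' @param subject_scale_meanlog,subject_scale_sdlog log-normal parameters of
#'   the per-subject envelope amplitude (fraction of MVC).
#' @param weight_jitter_sdlog,weight_jitter_add between-subject jitter on
#'   synergy weights: multiplicative log-normal SD plus an additive Gaussian
#'   SD (weights are clipped at zero and re-normalised). The additive part
#'   makes small weights vary on the absolute scale too, as weight tables
#'   from real cohorts do.
#' @param session_jitter_sdlog,session_jitter_add session-to-session (pre vs
#'   post) jitter on weights and burst widths, same two-part form; this is
#'   the within-subject error the ANOVA sees.
#' @param mvc_trials,mvc_duration number and length (s) of MVC trials per
#'   muscle.
#' @param mvc_uV nominal MVC-level EMG amplitude, microvolt RMS.
#' @param effects a [kick_effects()] object, or `NULL` for no intervention.
#' @param band band-pass edges, Hz.
#' @param filter_order Butterworth design order for the band-pass.
#' @param envelope_cutoff envelope low-pass cutoff, Hz.
#' @param mvc_window MVC sliding-window length, seconds.
#' @param k_range synergy orders swept during model-order selection.
#' @param vaf_threshold VAF order-selection threshold.
#' @param n_restarts NMF restarts per (input, order).
#' @param max_iter,tol NMF iteration cap and VAF convergence tolerance.
#' @param kmeans_repeats random restarts of K-means for reference clustering.
#' @param gap_B Gap-statistic reference draws.
#' @param gap_k_max largest cluster count evaluated by the Gap statistic.
#' @param gap_repeats K-means restarts used inside the Gap statistic.
#' @param n_reference_clusters fixed number of reference synergies, or `NULL`
#'   (the default) to select it with the Gap statistic.
#' @param match_threshold Pearson threshold for synergy matching.
#' @param timing_threshold burst-detection threshold as a fraction of each
#'   activation's maximum.
#' @param alpha significance level of the ANOVA stage.
#' @param seed root seed; every stochastic stage derives its seed from it.
#' @return a list of class `kick_config`.
#' @export
kick_config <- function(n_per_group = 15,
                        muscles = kick_muscles(),
                        n_syn = 3,
                        fs = 2000,
                        cycle_duration = 0.5,
                        cycle_jitter = 0.08,
                        n_cycles = 3,
                        phase_bounds = c(0.40, 0.80),
                        noise_sd = 0.015,
                        subject_scale_meanlog = log(0.55),
                        subject_scale_sdlog = 0.15,
                        weight_jitter_sdlog = 0.15,
                        weight_jitter_add = 0.05,
                        session_jitter_sdlog = 0.08,
                        session_jitter_add = 0.02,
                        mvc_trials = 3,
                        mvc_duration = 3,
                        mvc_uV = 250,
                        effects = kick_effects(),
                        band = c(20, 400),
                        filter_order = 4,
                        envelope_cutoff = 20,
                        mvc_window = 1.0,
                        k_range = 1:10,
                        vaf_threshold = 0.90,
                        n_restarts = 20,
                        max_iter = 1000,
                        tol = 1e-6,
                        kmeans_repeats = 1000,
                        gap_B = 100,
                        gap_k_max = 6,
                        gap_repeats = 100,
                        n_reference_clusters = NULL,
                        match_threshold = 0.6,
                        timing_threshold = 0.20,
                        alpha = 0.05,
                        seed = 1) {
  if (!is.null(effects) && !inherits(effects, "kick_effects")) {
    abort("`effects` must be NULL or a kick_effects() object.",
          class = "kicksyn_invalid_parameter")
  }
  if (length(phase_bounds) != 2 || any(phase_bounds <= 0) ||
      any(phase_bounds >= 1) || diff(phase_bounds) <= 0) {
    abort("`phase_bounds` must be two strictly increasing fractions in (0, 1).",
          class = "kicksyn_invalid_parameter")
  }
  cfg <- list(
    n_per_group = as.integer(n_per_group), muscles = muscles,
    n_syn = as.integer(n_syn), fs = fs, cycle_duration = cycle_duration,
    cycle_jitter = cycle_jitter, n_cycles = as.integer(n_cycles),
    phase_bounds = phase_bounds, noise_sd = noise_sd,
    subject_scale_meanlog = subject_scale_meanlog,
    subject_scale_sdlog = subject_scale_sdlog,
    weight_jitter_sdlog = weight_jitter_sdlog,
    weight_jitter_add = weight_jitter_add,
    session_jitter_sdlog = session_jitter_sdlog,
    session_jitter_add = session_jitter_add,
    mvc_trials = as.integer(mvc_trials), mvc_duration = mvc_duration,
    mvc_uV = mvc_uV, effects = effects, band = band,
    filter_order = as.integer(filter_order),
    envelope_cutoff = envelope_cutoff, mvc_window = mvc_window,
    k_range = as.integer(k_range), vaf_threshold = vaf_threshold,
    n_restarts = as.integer(n_restarts), max_iter = as.integer(max_iter),
    tol = tol, kmeans_repeats = as.integer(kmeans_repeats),
    gap_B = as.integer(gap_B), gap_k_max = as.integer(gap_k_max),
    gap_repeats = as.integer(gap_repeats),
    n_reference_clusters = if (!is.null(n_reference_clusters))
      as.integer(n_reference_clusters),
    match_threshold = match_threshold,
    timing_threshold = timing_threshold, alpha = alpha,
    seed = as.integer(seed))
  structure(cfg, class = "kick_config")
}

#' @export
print.kick_config <- function(x, ...) {
  cat("<kick_config>\n")
  cat(sprintf("  design: %d per group x {pre, post}, %d muscles, %d synergies\n",
              x$n_per_group, length(x$muscles), x$n_syn))
  cat(sprintf("  acquisition: %g Hz, %d cycles of ~%.2f s, phases at %.0f%%/%.0f%%\n",
              x$fs, x$n_cycles, x$cycle_duration,
              100 * x$phase_bounds[1], 100 * x$phase_bounds[2]))
  cat(sprintf("  synergy: k in %d..%d, VAF > %.0f%%, %d restarts\n",
              min(x$k_range), max(x$k_range), 100 * x$vaf_threshold,
              x$n_restarts))
  cat(sprintf("  clustering: %d K-means repeats, Gap B = %d, match r >= %.2f\n",
              x$kmeans_repeats, x$gap_B, x$match_threshold))
  cat(sprintf("  effects: %s\n",
              if (is.null(x$effects) || !x$effects$enabled) "none (null study)"
              else sprintf("weights x%.2f on %s (synergy %d); burst width x%.2f (synergy %d)",
                           x$effects$weight_multiplier,
                           paste(x$effects$weight_muscles, collapse = ", "),
                           x$effects$weight_synergy,
                           x$effects$width_multiplier,
                           x$effects$duration_synergy)))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
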