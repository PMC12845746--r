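#' Wrapped Gaussian activation bursts on the normalised cycle
#'
#' Burst profiles are Gaussian bumps in normalised-cycle coordinates, wrapped
#' circularly because the kick is cyclic (a burst centred near the cycle
#' boundary spans the wrap).
#'
#' @param centers burst peak locations, fractions of the cycle.
#' @param widths burst SDs, fractions of the cycle.
#' @param n_points samples per cycle.
#' @return matrix `length(centers) x n_points`, peak value 1 per row.
#' @keywords internal
#' @noRd
activation_bumps <- function(centers, widths, n_points = 100) {
  t <- (seq_len(n_points) - 1) / n_points
  out <- matrix(0, length(centers), n_points)
  for (i in seq_along(centers)) {
    d <- abs(t - centers[i] %% 1)
    d <- pmin(d, 1 - d)
    out[i, ] <- exp(-d^2 / (2 * widths[i]^2))
  }
  out
}

normalize_columns <- function(w) {
  nrm <- sqrt(colSums(w^2))
  nrm[nrm == 0] <- 1
  sweep(w, 2, nrm, "/")
}

#' Ground-truth synergy structure for the synthetic generator
#'
#' Builds a known set of synergy weight vectors and burst-like activation
#' profiles. Each synergy is dominated by a small group of muscles (dominant
#' weights of at least 0.5 before column normalisation, all others at most
#' 0.3) and has a wrapped-Gaussian activation burst with a peak location
#' distinct from every other synergy.
#'
#' Two templates are available. `"random"` deals a shuffled partition of the
#' muscles into dominant groups of 2-4 and spreads burst peaks around the
#' cycle; it is the generic recovery-testing truth. `"freestyle"` (requires
#' the standard ten-muscle montage and three synergies) fixes the dominant
#' groups and peak locations to the pattern described for the flutter kick: a
#' plantarflexor synergy peaking in the mid-to-late cycle (around 65 %), a
#' postural tibialis-anterior/rectus-abdominis synergy peaking near the end of
#' the cycle, and a propulsion-like adductor/knee-flexor/hip-extensor synergy
#' peaking early (around 12 %) whose burst spans the cycle wrap.
#'
#' @param n_muscles number of muscles.
#' @param n_syn number of synergies; must not exceed `n_muscles`.
#' @param seed integer seed; the same seed always yields the same truth.
#' @param template `"random"` or `"freestyle"` (see Details).
#' @param muscles optional muscle labels (defaults to [kick_muscles()] when
#'   `n_muscles` is 10, else `m1..mN`).
#' @param phase_bounds cycle-phase split fractions.
#' @param noise_sd default envelope-noise SD carried with the truth.
#' @return an object of class `kick_truth`: unit-norm weight matrix
#'   (`n_muscles x n_syn`), activation matrix (`n_syn x 100`), burst centres
#'   and widths, phase bounds and noise level.
#' @examples
#' tr <- make_ground_truth(10, 3, seed = 7)
#' colSums(tr$weights^2) # unit-norm columns
#' @export
make_ground_truth <- function(n_muscles = 10, n_syn = 3, seed = 1,
                              template = c("random", "freestyle"),
                              muscles = NULL,
                              phase_bounds = c(0.40, 0.80),
                              noise_sd = 0.015) {
  template <- match.arg(template)
  n_muscles <- as.integer(n_muscles)
  n_syn <- as.integer(n_syn)
  if (n_syn < 1 || n_syn > n_muscles) {
    abort("`n_syn` must satisfy 1 <= n_syn <= n_muscles.",
          class = "kicksyn_invalid_design")
  }
  if (is.null(muscles)) {
    muscles <- if (n_muscles == 10) kick_muscles()
               else paste0("m", seq_len(n_muscles))
  }
  if (length(muscles) != n_muscles) {
    abort("`muscles` must have length `n_muscles`.",
          class = "kicksyn_invalid_design")
  }
  if (template == "freestyle" && (n_muscles != 10 || n_syn != 3)) {
    abort("The freestyle template requires 10 muscles and 3 synergies.",
          class = "kicksyn_invalid_design")
  }

  with_seed(seed, {
    if (template == "freestyle") {
      dominant <- list(
        c("gastrocnemius_medialis", "gastrocnemius_lateralis"),
        c("tibialis_anterior", "rectus_abdominis"),
        c("adductor_longus", "adductor_magnus", "biceps_femoris",
          "gluteus_maximus"))
      dominant <- lapply(dominant, function(d) match(d, kick_muscles()))
      centers <- c(0.65, 0.90, 0.12)
      widths <- c(0.09, 0.10, 0.08)
    } else {
      base <- n_muscles %/% n_syn
      sizes <- pmin(4L, pmax(2L, base + (seq_len(n_syn) <= n_muscles %% n_syn)))
      pool <- rep(sample.int(n_muscles), length.out = sum(sizes))
      dominant <- split(pool, rep(seq_len(n_syn), sizes))
      centers <- ((sample.int(n_syn) - 0.5) / n_syn +
                    rnorm(n_syn, 0, 0.03)) %% 1
      widths <- runif(n_syn, 0.07, 0.12)
    }
    # every muscle is phasically recruited: a dominant role in one synergy
    # where it has one, otherwise one moderate secondary role; remaining
    # weights stay small so envelopes are burst-like, not tonic
    w <- matrix(runif(n_muscles * n_syn, 0.05, 0.15), n_muscles, n_syn)
    for (i in seq_len(n_syn)) {
      w[dominant[[i]], i] <- runif(length(dominant[[i]]), 0.55, 0.95)
    }
    no_role <- setdiff(seq_len(n_muscles), unlist(dominant))
    for (m in no_role) {
      w[m, sample.int(n_syn, 1)] <- runif(1, 0.18, 0.30)
    }
    # perturb centres away from exact collisions in tiny-n edge cases
    if (anyDuplicated(round(centers * 100))) {
      centers <- (centers + seq_len(n_syn) * 0.015) %% 1
    }
    acts <- activation_bumps(centers, widths)
    rownames(w) <- muscles
    structure(
      list(weights = normalize_columns(w),
           activations = acts,
           centers = centers, widths = widths,
           dominant = dominant,
           phase_bounds = phase_bounds,
           noise_sd = noise_sd,
           muscles = muscles, n_syn = n_syn,
           template = template, seed = as.integer(seed)),
      class = "kick_truth")
  })
}

#' @export
print.kick_truth <- function(x, ...) {
  cat(sprintf("<kick_truth> %d muscles, %d synergies (%s template)\n",
              length(x$muscles), x$n_syn, x$template))
  cat(sprintf("  burst peaks at %s of the cycle\n",
              paste(sprintf("%.0f%%", 100 * x$centers), collapse = ", ")))
  invisible(x)
}

#' Synthesise one noisy MVC-normalised envelope cycle
#'
#' Reconstructs the muscle-by-time activity matrix as the non-negative
#' synergy mixture `subject_scale * W %*% C`, adds i.i.d. Gaussian envelope
#' noise and clips at zero.
#'
#' @param truth a [make_ground_truth()] object.
#' @param subject_scale positive envelope amplitude (fraction of MVC).
#' @param noise_sd non-negative noise SD; defaults to the truth's value.
#' @param seed integer seed.
#' @return a list of class `kick_envelope`: `activity` (`n_muscles x 100`,
#'   non-negative) and `phase_idx` (two sample indices on the 100-point grid).
#' @export
synthesize_envelope_cycle <- function(truth, subject_scale = 1,
                                      noise_sd = truth$noise_sd, seed = 1) {
  if (!inherits(truth, "kick_truth")) {
    abort("`truth` must be a kick_truth object.",
          class = "kicksyn_invalid_parameter")
  }
  stopifnot_scalar_number(subject_scale, "subject_scale")
  stopifnot_scalar_number(noise_sd, "noise_sd")
  if (noise_sd < 0) {
    abort("`noise_sd` must be non-negative.",
          class = "kicksyn_invalid_parameter")
  }
  if (subject_scale <= 0) {
    abort("`subject_scale` must be positive.",
          class = "kicksyn_invalid_parameter")
  }
  clean <- subject_scale * truth$weights %*% truth$activations
  act <- with_seed(seed, pmax(0, clean + rnorm(length(clean), 0, noise_sd)))
  act <- matrix(act, nrow(clean), ncol(clean),
                dimnames = list(truth$muscles, NULL))
  structure(list(activity = act,
                 phase_idx = pmax(1L, round(truth$phase_bounds * 100)),
                 subject_id = NA_character_, group = NA_character_,
                 timepoint = NA_character_),
            class = "kick_envelope")
}
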