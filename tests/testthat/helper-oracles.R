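# Independent oracles used across the suite. These are deliberately written
# from first principles (cell means, polynomial frequency response, plain
# loops) so they share no code path with the package implementation.

# Brute-force cell-means decomposition of the balanced 2x2 mixed design:
# between stratum SS_group vs subjects-within-groups, within stratum SS_time
# and SS_group:time vs time-by-subjects-within-groups.
oracle_mixed_anova <- function(df) {
  groups <- sort(unique(df$group))
  tps <- unique(df$timepoint)
  subs <- unique(df$subject_id)
  grand <- mean(df$value)
  n_sub <- length(subs)

  m_g <- sapply(groups, function(g) mean(df$value[df$group == g]))
  m_t <- sapply(tps, function(tp) mean(df$value[df$timepoint == tp]))
  m_s <- sapply(subs, function(s) mean(df$value[df$subject_id == s]))
  g_of_s <- sapply(subs, function(s) df$group[df$subject_id == s][1])

  n_per_group <- sapply(groups, function(g) sum(g_of_s == g))
  ss_group <- sum(2 * n_per_group * (m_g - grand)^2)
  ss_subj <- sum(2 * (m_s - m_g[g_of_s])^2)
  ss_time <- n_sub * sum((m_t - grand)^2)
  m_gt <- outer(groups, tps, Vectorize(function(g, tp) {
    mean(df$value[df$group == g & df$timepoint == tp])
  }))
  ss_int <- sum(rep(n_per_group, length(tps)) *
                  (m_gt - outer(m_g, rep(grand, 2), "-") - grand -
                     matrix(m_t - grand, length(groups), length(tps),
                            byrow = TRUE))^2)
  ss_total <- sum((df$value - grand)^2)
  ss_err <- ss_total - ss_group - ss_subj - ss_time - ss_int

  df_subj <- n_sub - 2
  f_of <- function(ss, ss_e, df_e) {
    f <- (ss / 1) / (ss_e / df_e)
    list(F = f, p = stats::pf(f, 1, df_e, lower.tail = FALSE),
         eta = ss / (ss + ss_e))
  }
  list(group = f_of(ss_group, ss_subj, df_subj),
       time = f_of(ss_time, ss_err, df_subj),
       interaction = f_of(ss_int, ss_err, df_subj),
       ss = c(group = ss_group, subj = ss_subj, time = ss_time,
              interaction = ss_int, error = ss_err, total = ss_total))
}

# random balanced 2x2 table
random_anova_table <- function(n_per_group, seed, effect_int = 0) {
  withr::with_seed(seed, {
    subs <- c(paste0("a", seq_len(n_per_group)),
              paste0("b", seq_len(n_per_group)))
    grp <- rep(c("A", "B"), each = n_per_group)
    out <- NULL
    for (i in seq_along(subs)) {
      base <- rnorm(1, 10, 2)
      for (tp in c("pre", "post")) {
        bump <- if (grp[i] == "A" && tp == "post") effect_int else 0
        out <- rbind(out, data.frame(
          subject_id = subs[i], group = grp[i], timepoint = tp,
          value = base + bump + rnorm(1)))
      }
    }
    tibble::as_tibble(out)
  })
}

# squared magnitude response of a zero-phase (forward-backward) filter,
# evaluated directly from the transfer-function polynomials
filtfilt_gain <- function(bf, f, fs) {
  z <- exp(-1i * 2 * pi * f / fs)
  h <- sum(bf$b * z^(seq_along(bf$b) - 1)) /
    sum(bf$a * z^(seq_along(bf$a) - 1))
  Mod(h)^2
}

# steady-state amplitude of a sinusoidal response, ignoring edge transients
steady_amplitude <- function(y, fs, skip_s = 0.25) {
  idx <- seq(round(skip_s * fs), length(y) - round(skip_s * fs))
  max(abs(y[idx]))
}

# small cached study so several test files can share one simulation
.fixture_env <- new.env(parent = emptyenv())
small_study <- function() {
  if (is.null(.fixture_env$study)) {
    cfg <- kick_config(n_per_group = 2)
    .fixture_env$study <- simulate_kick_study(cfg, seed = 404)
  }
  .fixture_env$study
}

# cached full-size pipeline runs shared by the acceptance blocks
.acceptance_pipeline <- function(null = FALSE) {
  key <- if (null) "null" else "effects"
  if (is.null(.fixture_env[[key]])) {
    cfg <- if (null) kick_config(effects = NULL) else kick_config()
    .fixture_env[[key]] <- run_kick_pipeline(cfg, seed = 2026)
  }
  .fixture_env[[key]]
}

activation_bumps_for_test <- function(center, width, as_matrix = FALSE) {
  t <- (0:99) / 100
  d <- abs(t - center)
  v <- exp(-pmin(d, 1 - d)^2 / (2 * width^2))
  if (as_matrix) matrix(v, 1, 100) else v
}

representative_cycle_for_test <- function(study, i) {
  cyc <- segment_cycles(study$recordings$events[[i]], study$config$fs,
                        ncol(study$recordings$emg[[i]]))
  cyc[order(cyc$duration_s)[ceiling(nrow(cyc) / 2)], ]
}

best_permutation_cosines <- function(west, wtrue) {
  k <- ncol(wtrue)
  cosm <- t(west) %*% wtrue /
    outer(sqrt(colSums(west^2)), sqrt(colSums(wtrue^2)))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- -Inf; best_cos <- NULL
  for (p in perms(seq_len(k))) {
    cc <- cosm[cbind(p, seq_len(k))]
    if (sum(cc) > best) { best <- sum(cc); best_cos <- cc }
  }
  best_cos
}
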