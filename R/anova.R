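#' Classify a partial eta squared into conventional effect-size bands
#'
#' Cut points 0.01 / 0.06 / 0.14 (closed on the left): values below 0.01 are
#' `below_small`, then `small`, `medium`, and `large` from 0.14 upwards.
#'
#' @param eta_p2 numeric vector of partial eta squared values in `[0, 1]`.
#' @return character vector of bands.
#' @export
effect_band <- function(eta_p2) {
  if (any(!is.finite(eta_p2)) || any(eta_p2 < 0) || any(eta_p2 > 1)) {
    abort("`eta_p2` must lie in [0, 1].", class = "kicksyn_invalid_parameter")
  }
  cut(eta_p2, breaks = c(-Inf, 0.01, 0.06, 0.14, Inf), right = FALSE,
      labels = c("below_small", "small", "medium", "large")) |>
    as.character()
}

f_ratio <- function(ss_eff, df_eff, ss_err, df_err, tol = 0) {
  # sums of squares below the numerical-noise floor are exact zeros
  if (ss_eff < tol) ss_eff <- 0
  if (ss_err < tol) ss_err <- 0
  ms_eff <- ss_eff / df_eff
  ms_err <- ss_err / df_err
  if (ms_err <= 0) {
    f <- if (ms_eff <= 0) 0 else Inf
  } else {
    f <- ms_eff / ms_err
  }
  p <- if (is.infinite(f)) 0 else pf(f, df_eff, df_err, lower.tail = FALSE)
  eta <- if (ss_eff + ss_err <= 0) 0 else ss_eff / (ss_eff + ss_err)
  list(f = f, p = p, eta = eta)
}

validate_anova_table <- function(data) {
  req <- c("subject_id", "group", "timepoint", "value")
  if (!all(req %in% names(data))) {
    abort(sprintf("ANOVA table needs columns %s.", paste(req, collapse = ", ")),
          class = "kicksyn_invalid_parameter")
  }
  groups <- unique(data$group); tps <- unique(data$timepoint)
  if (length(groups) != 2 || length(tps) != 2) {
    abort("The design must have exactly two groups and two timepoints.",
          class = "kicksyn_unbalanced_design")
  }
  counts <- table(data$subject_id, data$timepoint)
  if (any(counts != 1)) {
    abort("Every subject needs exactly one value per timepoint.",
          class = "kicksyn_unbalanced_design")
  }
  subj_grp <- unique(data[, c("subject_id", "group")])
  if (any(table(subj_grp$group) < 2)) {
    abort("Each group needs at least two subjects.",
          class = "kicksyn_unbalanced_design")
  }
  invisible(data)
}

#' Two-by-two mixed repeated-measures ANOVA
#'
#' Mixed-design ANOVA with one between-subject factor (group) and one
#' within-subject factor (timepoint), fitted with
#' `stats::aov(value ~ group * timepoint + Error(subject))`. The group effect
#' is tested against subjects-within-groups; the time and group-by-time
#' effects against the time-by-subjects-within-groups residual. Partial eta
#' squared is `SS_effect / (SS_effect + SS_error_of_that_effect)`. With only
#' two within-subject levels sphericity holds trivially, so no correction is
#' applied. Degenerate strata (zero error mean square) are resolved to
#' `F = 0, p = 1` when the effect sum of squares is also zero.
#'
#' @param data tibble with columns `subject_id`, `group`, `timepoint`,
#'   `value`; balanced and complete (every subject measured at both
#'   timepoints).
#' @param timepoint_levels order of the within-subject levels.
#' @return object of class `kick_anova` with an `effects` tibble (`effect`,
#'   `F`, `df1`, `df2`, `p`, `eta_p2`, `band`) and the cell means.
#' @export
mixed_anova_2x2 <- function(data, timepoint_levels = c("pre", "post")) {
  validate_anova_table(data)
  d <- data.frame(
    subject = factor(data$subject_id),
    group = factor(data$group),
    timepoint = factor(data$timepoint, levels = timepoint_levels),
    value = data$value)
  fit <- stats::aov(value ~ group * timepoint + Error(subject), data = d)
  s <- summary(fit)
  between <- as.data.frame(s[["Error: subject"]][[1]])
  within <- as.data.frame(s[["Error: Within"]][[1]])
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))
  ss_g <- between[rn_b == "group", "Sum Sq"]
  ss_s <- between[rn_b == "Residuals", "Sum Sq"]
  df_s <- between[rn_b == "Residuals", "Df"]
  ss_t <- within[rn_w == "timepoint", "Sum Sq"]
  ss_gt <- within[rn_w == "group:timepoint", "Sum Sq"]
  ss_e <- within[rn_w == "Residuals", "Sum Sq"]
  df_e <- within[rn_w == "Residuals", "Df"]
  tol <- 1e-12 * max(sum((d$value - mean(d$value))^2), 1)
  rows <- purrr::pmap(
    list(effect = c("group", "time", "group:time"),
         ss = list(ss_g, ss_t, ss_gt),
         ss_err = list(ss_s, ss_e, ss_e),
         df_err = list(df_s, df_e, df_e)),
    function(effect, ss, ss_err, df_err) {
      r <- f_ratio(ss, 1, ss_err, df_err, tol)
      tibble(effect = effect, F = r$f, df1 = 1, df2 = df_err, p = r$p,
             eta_p2 = r$eta, band = effect_band(r$eta))
    })
  cells <- dplyr::summarise(dplyr::group_by(as_tibble(d), .data$group,
                                            .data$timepoint),
                            mean = mean(.data$value), sd = sd(.data$value),
                            n = dplyr::n(), .groups = "drop")
  structure(list(effects = dplyr::bind_rows(rows), cells = cells,
                 data = as_tibble(d)),
            class = "kick_anova")
}

#' @export
print.kick_anova <- function(x, ...) {
  cat("<kick_anova> 2x2 mixed repeated-measures ANOVA\n")
  print(as.data.frame(x$effects), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @describeIn mixed_anova_2x2 tidy method: the effects table.
#' @param x,... broom-interface arguments.
#' @export
tidy.kick_anova <- function(x, ...) x$effects

#' @describeIn mixed_anova_2x2 glance method: one row focused on the
#'   interaction term.
#' @export
glance.kick_anova <- function(x, ...) {
  int <- x$effects[x$effects$effect == "group:time", ]
  tibble(n_subjects = dplyr::n_distinct(x$data$subject),
         F_interaction = int$F, p_interaction = int$p,
         eta_p2_interaction = int$eta_p2)
}

guarded_t_p <- function(test) {
  tryCatch(test()$p.value, error = function(e) NA_real_)
}

#' Bonferroni-adjusted simple effects for the 2x2 mixed design
#'
#' Within-group contrasts compare pre vs post with a paired t-test per group;
#' between-group contrasts compare the two groups with a pooled-variance
#' two-sample t-test per timepoint. Raw p-values are multiplied by `m`
#' (default: the number of contrasts in the family, 2) and capped at 1.
#' Constant differences are resolved without a t-test: an all-zero difference
#' gives p = 1, a constant non-zero difference p = 0.
#'
#' @param data tibble with `subject_id`, `group`, `timepoint`, `value`.
#' @param which `"within"` (pre vs post per group) or `"between"` (group
#'   difference per timepoint).
#' @param alpha significance level recorded alongside each contrast.
#' @param m Bonferroni multiplier (>= 1).
#' @param timepoint_levels order of the within-subject levels.
#' @return tibble: `contrast`, `estimate` (mean difference), `p_raw`,
#'   `p_adj`, `significant`.
#' @export
simple_effects <- function(data, which = c("within", "between"), alpha = 0.05,
                           m = 2, timepoint_levels = c("pre", "post")) {
  which <- match.arg(which)
  if (m < 1) {
    abort("`m` must be at least 1.", class = "kicksyn_invalid_parameter")
  }
  validate_anova_table(data)
  groups <- sort(unique(data$group))
  out <- list()
  if (which == "within") {
    for (g in groups) {
      dg <- data[data$group == g, ]
      wide <- tidyr::pivot_wider(dg[, c("subject_id", "timepoint", "value")],
                                 names_from = "timepoint",
                                 values_from = "value")
      diffs <- wide[[timepoint_levels[2]]] - wide[[timepoint_levels[1]]]
      p <- if (sd(diffs) == 0) {
        if (mean(diffs) == 0) 1 else 0
      } else {
        t.test(diffs)$p.value
      }
      out[[g]] <- tibble(contrast = sprintf("%s: %s vs %s", g,
                                            timepoint_levels[2],
                                            timepoint_levels[1]),
                         estimate = mean(diffs), p_raw = p)
    }
  } else {
    for (tp in timepoint_levels) {
      dt <- data[data$timepoint == tp, ]
      v1 <- dt$value[dt$group == groups[1]]
      v2 <- dt$value[dt$group == groups[2]]
      p <- if (sd(v1) == 0 && sd(v2) == 0) {
        if (mean(v1) == mean(v2)) 1 else 0
      } else {
        t.test(v1, v2, var.equal = TRUE)$p.value
      }
      out[[tp]] <- tibble(contrast = sprintf("%s: %s vs %s", tp, groups[1],
                                             groups[2]),
                          estimate = mean(v1) - mean(v2), p_raw = p)
    }
  }
  dplyr::bind_rows(out) |>
    dplyr::mutate(p_adj = pmin(1, .data$p_raw * m),
                  significant = .data$p_adj < alpha)
}

#' Run the mixed ANOVA across every outcome of a tidy table
#'
#' Iterates [mixed_anova_2x2()] over the `outcome` column of a long table.
#' Subjects missing either timepoint for an outcome are dropped for that
#' outcome (complete-case analysis); outcomes left with fewer than two
#' subjects per group are skipped. For outcomes whose interaction is
#' significant at `alpha`, Bonferroni simple effects (within-group pre vs
#' post and between-group per timepoint) are attached.
#'
#' @param data tibble with `subject_id`, `group`, `timepoint`, `outcome`,
#'   `value`.
#' @param alpha significance level.
#' @param timepoint_levels order of the within-subject levels.
#' @return tibble of class `kick_anova_table`: one row per outcome x effect,
#'   with an attribute `simple_effects` (tibble keyed by `outcome`).
#' @export
anova_outcomes <- function(data, alpha = 0.05,
                           timepoint_levels = c("pre", "post")) {
  req <- c("subject_id", "group", "timepoint", "outcome", "value")
  if (!all(req %in% names(data))) {
    abort(sprintf("Need columns %s.", paste(req, collapse = ", ")),
          class = "kicksyn_invalid_parameter")
  }
  res <- list(); simple <- list()
  for (oc in unique(data$outcome)) {
    d <- data[data$outcome == oc, ]
    complete <- d |>
      dplyr::count(.data$subject_id) |>
      dplyr::filter(.data$n == 2) |>
      dplyr::pull(.data$subject_id)
    d <- d[d$subject_id %in% complete, ]
    per_group <- d |>
      dplyr::distinct(.data$subject_id, .data$group) |>
      dplyr::count(.data$group)
    if (nrow(per_group) < 2 || any(per_group$n < 2)) next
    fit <- mixed_anova_2x2(d, timepoint_levels)
    res[[oc]] <- dplyr::mutate(fit$effects, outcome = oc, .before = 1)
    int_p <- fit$effects$p[fit$effects$effect == "group:time"]
    if (is.finite(int_p) && int_p < alpha) {
      simple[[oc]] <- dplyr::bind_rows(
        dplyr::mutate(simple_effects(d, "within", alpha, 2, timepoint_levels),
                      family = "within"),
        dplyr::mutate(simple_effects(d, "between", alpha, 2, timepoint_levels),
                      family = "between")) |>
        dplyr::mutate(outcome = oc, .before = 1)
    }
  }
  out <- dplyr::bind_rows(res)
  attr(out, "simple_effects") <- dplyr::bind_rows(simple)
  class(out) <- c("kick_anova_table", class(out))
  out
}
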