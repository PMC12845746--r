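test_that("effect-size bands use the 0.01/0.06/0.14 cut points, closed on the left", {
  expect_equal(effect_band(c(0.005, 0.01, 0.06, 0.14, 0.5)),
               c("below_small", "small", "medium", "large", "large"))
  expect_error(effect_band(-0.1), class = "kicksyn_invalid_parameter")
  expect_error(effect_band(1.1), class = "kicksyn_invalid_parameter")
})

test_that("the mixed ANOVA agrees with the cell-means brute-force oracle", {
  for (seed in c(1, 2, 3, 17, 99)) {
    tab <- random_anova_table(4, seed)
    fit <- mixed_anova_2x2(tab)
    oc <- oracle_mixed_anova(tab)
    eff <- fit$effects
    expect_equal(eff$F[eff$effect == "group"], oc$group$F, tolerance = 1e-8)
    expect_equal(eff$p[eff$effect == "group"], oc$group$p, tolerance = 1e-8)
    expect_equal(eff$eta_p2[eff$effect == "group"], oc$group$eta,
                 tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "time"], oc$time$F, tolerance = 1e-8)
    expect_equal(eff$F[eff$effect == "group:time"], oc$interaction$F,
                 tolerance = 1e-8)
    expect_equal(eff$p[eff$effect == "group:time"], oc$interaction$p,
                 tolerance = 1e-8)
    expect_equal(eff$eta_p2[eff$effect == "group:time"], oc$interaction$eta,
                 tolerance = 1e-8)
    # sums of squares decompose the total about the grand mean
    expect_equal(sum(oc$ss[c("group", "subj", "time", "interaction",
                             "error")]),
                 oc$ss[["total"]], tolerance = 1e-9 * oc$ss[["total"]])
  }
})

test_that("degenerate designs resolve to exact null statistics", {
  # both groups shift by exactly +d: interaction F = 0, p = 1
  tab <- random_anova_table(4, 5)
  wide <- tidyr::pivot_wider(tab, names_from = "timepoint",
                             values_from = "value")
  wide$post <- wide$pre + 2.5
  tab2 <- tidyr::pivot_longer(wide, c("pre", "post"),
                              names_to = "timepoint", values_to = "value")
  fit <- mixed_anova_2x2(tab2)
  expect_equal(fit$effects$F[fit$effects$effect == "group:time"], 0)
  expect_equal(fit$effects$p[fit$effects$effect == "group:time"], 1)
  # mirrored groups with pre = post: every effect F = 0
  tab3 <- tibble::tibble(
    subject_id = rep(c("a1", "a2", "b1", "b2"), each = 2),
    group = rep(c("A", "A", "B", "B"), each = 2),
    timepoint = rep(c("pre", "post"), 4),
    value = rep(c(1, 1, 3, 3, 1, 1, 3, 3)))
  fit3 <- mixed_anova_2x2(tab3)
  expect_equal(fit3$effects$F, rep(0, 3))
  expect_equal(fit3$effects$p, rep(1, 3))
})

test_that("F statistics are invariant to permuting subject labels within groups", {
  tab <- random_anova_table(5, 11)
  relabel <- c(a1 = "a3", a3 = "a1", b2 = "b5", b5 = "b2")
  tab2 <- tab
  hit <- tab2$subject_id %in% names(relabel)
  tab2$subject_id[hit] <- relabel[tab2$subject_id[hit]]
  expect_equal(mixed_anova_2x2(tab)$effects$F,
               mixed_anova_2x2(tab2)$effects$F, tolerance = 1e-12)
})

test_that("unbalanced or incomplete designs are rejected", {
  tab <- random_anova_table(3, 1)
  expect_error(mixed_anova_2x2(tab[-1, ]),
               class = "kicksyn_unbalanced_design")
  one_group <- tab[tab$group == "A", ]
  expect_error(mixed_anova_2x2(one_group),
               class = "kicksyn_unbalanced_design")
})

test_that("simple effects are Bonferroni-adjusted and guard degenerate contrasts", {
  # identical pre/post values in every group: adjusted p = 1
  tab <- random_anova_table(4, 21)
  wide <- tidyr::pivot_wider(tab, names_from = "timepoint",
                             values_from = "value")
  wide$post <- wide$pre
  flat <- tidyr::pivot_longer(wide, c("pre", "post"),
                              names_to = "timepoint", values_to = "value")
  se <- simple_effects(flat, "within", m = 2)
  expect_equal(se$p_adj, c(1, 1))
  # the multiplier caps at 1
  tabn <- random_anova_table(5, 22)
  sew <- simple_effects(tabn, "within", m = 4)
  expect_true(all(sew$p_adj <= 1))
  expect_equal(sew$p_adj, pmin(1, sew$p_raw * 4))
  expect_error(simple_effects(tabn, "within", m = 0),
               class = "kicksyn_invalid_parameter")
  # a large injected group-by-time effect shows up only in group A
  tabe <- random_anova_table(8, 23, effect_int = 6)
  see <- simple_effects(tabe, "within")
  expect_lt(see$p_adj[grepl("^A", see$contrast)], 0.05)
  expect_gt(see$p_adj[grepl("^B", see$contrast)], 0.05)
})

test_that("glance and tidy expose the fitted ANOVA", {
  fit <- mixed_anova_2x2(random_anova_table(4, 31))
  expect_equal(nrow(tidy(fit)), 3)
  g <- glance(fit)
  expect_equal(g$n_subjects, 8)
  expect_equal(g$F_interaction,
               fit$effects$F[fit$effects$effect == "group:time"])
})

test_that("anova_outcomes drops incomplete subjects and attaches simple effects", {
  tab1 <- dplyr::mutate(random_anova_table(6, 41, effect_int = 8),
                        outcome = "with_effect")
  tab2 <- dplyr::mutate(random_anova_table(6, 42), outcome = "null")
  long <- dplyr::bind_rows(tab1, tab2)
  # remove one timepoint of one subject: that subject is dropped, not fatal
  long <- long[!(long$outcome == "null" & long$subject_id == "a1" &
                   long$timepoint == "post"), ]
  res <- anova_outcomes(long, alpha = 0.05)
  expect_setequal(unique(res$outcome), c("with_effect", "null"))
  expect_lt(res$p[res$outcome == "with_effect" &
                    res$effect == "group:time"], 0.05)
  se <- attr(res, "simple_effects")
  expect_true("with_effect" %in% se$outcome)
  expect_equal(res$df2[res$outcome == "null" & res$effect == "group"], 9)
})
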