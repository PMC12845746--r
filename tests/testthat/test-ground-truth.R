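test_that("ground truth has unit-norm weights, dominant structure and distinct peaks", {
  tr <- make_ground_truth(10, 3, seed = 7)
  expect_equal(dim(tr$weights), c(10, 3))
  expect_equal(dim(tr$activations), c(3, 100))
  expect_equal(unname(colSums(tr$weights^2)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(tr$activations >= 0))
  peaks <- apply(tr$activations, 1, which.max)
  expect_equal(length(unique(peaks)), 3)
  # dominant muscles carry most of the column mass
  for (i in 1:3) {
    dom <- tr$dominant[[i]]
    expect_true(min(tr$weights[dom, i]) > max(tr$weights[-dom, i]))
  }
})

test_that("ground truth generation is seed-deterministic and validates the design", {
  expect_identical(make_ground_truth(10, 3, seed = 7),
                   make_ground_truth(10, 3, seed = 7))
  tr1 <- make_ground_truth(10, 1, seed = 1)
  expect_equal(ncol(tr1$weights), 1)
  expect_equal(sum(tr1$activations == max(tr1$activations)), 1)
  expect_error(make_ground_truth(10, 11, seed = 1),
               class = "kicksyn_invalid_design")
})

test_that("noiseless envelope synthesis reproduces the exact synergy mixture", {
  tr <- make_ground_truth(10, 3, seed = 5)
  ec <- synthesize_envelope_cycle(tr, subject_scale = 0.7, noise_sd = 0,
                                  seed = 3)
  expect_equal(ec$activity, 0.7 * tr$weights %*% tr$activations,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_lte(qr(ec$activity)$rank, 3)
})

test_that("noisy envelope synthesis is reproducible and close to the clean mixture", {
  tr <- make_ground_truth(10, 3, seed = 5)
  e1 <- synthesize_envelope_cycle(tr, 1, 0.05, seed = 9)
  e2 <- synthesize_envelope_cycle(tr, 1, 0.05, seed = 9)
  expect_identical(e1, e2)
  clean <- tr$weights %*% tr$activations
  mad <- mean(abs(e1$activity - clean))
  # clipping at zero biases the deviation slightly below E|N(0, sd)|
  expect_lt(mad, 3 * 0.05)
  expect_true(all(e1$activity >= 0))
  expect_error(synthesize_envelope_cycle(tr, 1, -0.01, seed = 1),
               class = "kicksyn_invalid_parameter")
})

test_that("raw-trial synthesis modulates a band-limited carrier and emits events", {
  tr <- make_ground_truth(10, 3, seed = 2)
  ec <- synthesize_envelope_cycle(tr, 1, 0, seed = 1)
  zero <- ec
  zero$activity[] <- 0
  raw0 <- synthesize_raw_trial(zero, fs = 2000, cycle_durations = 1,
                               gain_uV = 100, seed = 4)
  expect_true(all(raw0$emg == 0))

  const <- ec
  const$activity[] <- 1
  raw <- synthesize_raw_trial(const, fs = 2000, cycle_durations = 1,
                              gain_uV = 1, seed = 4)
  # unit envelope times unit-RMS carrier: overall RMS near 1
  expect_equal(rms_amplitude(raw$emg[1, ]), 1, tolerance = 0.15)
  expect_setequal(unique(raw$events$event),
                  c("cycle_start", "phase1_end", "phase2_end", "cycle_end"))

  raw_a <- synthesize_raw_trial(ec, 2000, 0.5, 100, seed = 11)
  raw_b <- synthesize_raw_trial(ec, 2000, 0.5, 100, seed = 11)
  expect_identical(raw_a$emg, raw_b$emg)
  expect_error(synthesize_raw_trial(ec, 2000, -1, 100, seed = 1),
               class = "kicksyn_invalid_parameter")
  expect_error(synthesize_raw_trial(ec, 500, 1, 100, seed = 1),
               class = "kicksyn_invalid_parameter")
})

test_that("study simulation has the right design shape and is byte-reproducible", {
  study <- small_study()
  expect_equal(nrow(study$recordings), 2 * 2 * 2) # subjects x groups x times
  expect_setequal(unique(study$recordings$group), c("EXP", "CON"))
  expect_setequal(unique(study$recordings$timepoint), c("pre", "post"))
  expect_equal(nrow(study$mvc), 4 * 10 * 3)
  # every recording carries at least one complete analysable cycle
  for (i in seq_len(nrow(study$recordings))) {
    cyc <- segment_cycles(study$recordings$events[[i]], study$config$fs,
                          ncol(study$recordings$emg[[i]]))
    expect_gte(nrow(cyc), 1)
  }
  again <- simulate_kick_study(kick_config(n_per_group = 2), seed = 404)
  expect_identical(study$recordings$emg, again$recordings$emg)
  expect_identical(study$truth$sessions$weights, again$truth$sessions$weights)
})

test_that("a null intervention leaves pre/post differing only by session noise", {
  cfg <- kick_config(n_per_group = 2, effects = NULL,
                     session_jitter_sdlog = 0)
  study <- simulate_kick_study(cfg, seed = 12)
  tru <- study$truth$sessions
  for (sid in unique(tru$subject_id)) {
    pre <- tru$widths[[which(tru$subject_id == sid & tru$timepoint == "pre")]]
    post <- tru$widths[[which(tru$subject_id == sid & tru$timepoint == "post")]]
    expect_equal(pre, post, tolerance = 1e-12)
  }
})
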