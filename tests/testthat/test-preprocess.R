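test_that("band-pass rejects DC and drift", {
  fs <- 2000
  y <- bandpass_filter(rep(5, fs), fs)
  mid <- y[500:1500]
  expect_lt(max(abs(mid)), 1e-3)
  expect_error(bandpass_filter(rnorm(100), fs, low = 20, high = 1200),
               class = "kicksyn_invalid_band")
  expect_error(bandpass_filter(rnorm(100), fs, low = 0, high = 400),
               class = "kicksyn_invalid_band")
})

test_that("band-pass gain matches the filter's squared magnitude response", {
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  bf <- signal::butter(4, c(20, 400) / (fs / 2), type = "pass")
  # 100 Hz: inside the pass band, amplitude within 1% of unity
  y100 <- bandpass_filter(sin(2 * pi * 100 * t), fs)
  amp100 <- steady_amplitude(y100, fs)
  expect_equal(amp100, 1, tolerance = 0.01)
  expect_equal(amp100, filtfilt_gain(bf, 100, fs), tolerance = 1e-3)
  # 5 Hz: deep in the stop band
  y5 <- bandpass_filter(sin(2 * pi * 5 * t), fs)
  expect_lt(steady_amplitude(y5, fs), 0.1)
  expect_equal(steady_amplitude(y5, fs, 0.5), filtfilt_gain(bf, 5, fs),
               tolerance = 1e-3)
})

test_that("linear envelope recovers rectified-mean levels", {
  fs <- 2000
  expect_equal(linear_envelope(rep(0, fs), fs), rep(0, fs))
  y1 <- linear_envelope(rep(1, fs), fs)
  expect_equal(y1[500:1500], rep(1, 1001), tolerance = 1e-6)
  # full-wave rectified unit sine has mean 2/pi
  t <- seq(0, 2, by = 1 / fs)
  y300 <- linear_envelope(sin(2 * pi * 300 * t), fs)
  expect_equal(mean(y300[1000:3000]), 2 / pi, tolerance = 0.01)
  expect_true(all(y300 >= 0))
  expect_error(linear_envelope(rnorm(100), fs, cutoff = 1200),
               class = "kicksyn_invalid_band")
})

test_that("MVC reference takes the largest 1 s sliding-window RMS across trials", {
  fs <- 2000
  t <- seq(0, 1.999, by = 1 / fs)
  carrier <- sin(2 * pi * 100 * t) # pass-band tone: RMS = amplitude / sqrt(2)
  trials <- list(m1 = list(0.5 * carrier, 0.8 * carrier, 0.6 * carrier))
  ref <- mvc_reference(trials, fs)
  expect_equal(ref$mvc, 0.8 / sqrt(2), tolerance = 0.01)
  # trial of exactly window length: single window = whole-trial RMS
  one <- list(m1 = list(0.4 * carrier[1:fs]))
  expect_equal(mvc_reference(one, fs)$mvc, 0.4 / sqrt(2), tolerance = 0.01)
  expect_error(mvc_reference(list(m1 = list(rep(0, fs))), fs),
               class = "kicksyn_invalid_mvc")
  expect_error(mvc_reference(list(m1 = list()), fs),
               class = "kicksyn_invalid_mvc")
})

test_that("cycle segmentation maps event times to half-open sample ranges", {
  ev <- tibble::tibble(
    event = c("cycle_start", "phase1_end", "phase2_end", "cycle_start"),
    time_s = c(1.0, 1.2, 1.4, 1.5))
  cyc <- segment_cycles(ev, fs = 2000, n_samples = 4000)
  expect_equal(cyc$start, 2000)
  expect_equal(cyc$end, 3000)
  expect_equal(cyc$phase1, 2400)
  expect_equal(cyc$phase2, 2800)
  expect_error(segment_cycles(ev[1:3, ], 2000, 4000),
               class = "kicksyn_event_stream")
  bad <- ev; bad$time_s[4] <- 0.5
  expect_error(segment_cycles(bad, 2000, 4000),
               class = "kicksyn_event_stream")
})

test_that("cycle normalisation divides by MVC and resamples to 100 points", {
  mvc <- tibble::tibble(muscle = c("m1", "m2"), mvc = c(2, 4))
  env <- rbind(m1 = rep(2, 150), m2 = rep(4, 150))
  ec <- normalize_cycle(env, mvc, c(60, 120))
  expect_equal(ec$activity, rbind(m1 = rep(1, 100), m2 = rep(1, 100)),
               ignore_attr = TRUE)
  expect_equal(ec$phase_idx, c(41, 81))
  # a row already of length 100 passes through unchanged
  x <- matrix(runif(100), 1, dimnames = list("m1", NULL))
  ec2 <- normalize_cycle(x, tibble::tibble(muscle = "m1", mvc = 1), c(40, 80))
  expect_equal(ec2$activity[1, ], x[1, ], tolerance = 1e-12)
  # linearity: a ramp resamples to a ramp with exact endpoints
  ramp <- matrix(seq(0, 1, length.out = 200), 1,
                 dimnames = list("m1", NULL))
  ec3 <- normalize_cycle(ramp, tibble::tibble(muscle = "m1", mvc = 1),
                         c(50, 150))
  expect_equal(ec3$activity[1, ], seq(0, 1, length.out = 100),
               tolerance = 1e-12)
  expect_error(normalize_cycle(ramp, tibble::tibble(muscle = "mX", mvc = 1),
                               c(50, 150)),
               class = "kicksyn_missing_mvc")
})

test_that("preprocessed cycles recover the generating envelopes", {
  study <- small_study()
  env <- preprocess_study(study)
  expect_s3_class(env, "kick_envelopes")
  tru <- study$truth$sessions
  cors <- sapply(seq_len(nrow(env)), function(i) {
    act <- env$envelope[[i]]$activity
    expect_true(all(act >= 0 & is.finite(act)))
    expect_equal(ncol(act), 100)
    key <- tru[tru$subject_id == env$subject_id[i] &
                 tru$timepoint == env$timepoint[i], ]
    clean <- key$scale * key$weights[[1]] %*% key$activations[[1]]
    sapply(rownames(act), function(m) cor(act[m, ], clean[m, ]))
  })
  expect_gt(min(rowMeans(cors)), 0.9) # every muscle, averaged over cycles
  expect_gt(mean(cors), 0.93)
})
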