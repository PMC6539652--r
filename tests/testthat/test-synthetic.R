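test_that("no-motion model yields a constant 1 g vertical signal", {
  m <- gait_model(2, 0, noise_sd = 0, stride_fraction = 0)
  rec <- gen_locomotion_signal(m, 10, 30, seed = 1)
  expect_true(all(rec$samples[, 1] == 1))
  expect_true(all(rec$samples[, 2:3] == 0))
})

test_that("a single-harmonic model peaks at its frequency in the periodogram", {
  rec <- tone_recording(2, 0.5, duration_s = 60)
  sp <- stats::spec.pgram(rec$samples[, 1] - mean(rec$samples[, 1]),
                          taper = 0, plot = FALSE)
  f <- sp$freq * 30
  peak <- f[which.max(sp$spec)]
  expect_lt(abs(peak - 2), 30 / length(rec$samples[, 1]) + 1e-9)  # one FFT bin
  # spectral fidelity: >= 95% of power within +/-0.25 Hz of the harmonic
  inband <- abs(f - 2) <= 0.25
  expect_gt(sum(sp$spec[inband]) / sum(sp$spec), 0.95)
})

test_that("generation is deterministic given the seed", {
  m <- gait_model(2, c(0.4, 0.2), noise_sd = 0.02)
  a <- gen_locomotion_signal(m, 20, 30, seed = 42)
  b <- gen_locomotion_signal(m, 20, 30, seed = 42)
  expect_identical(a$samples, b$samples)
  c_ <- gen_locomotion_signal(m, 20, 30, seed = 43)
  expect_false(identical(a$samples, c_$samples))
})

test_that("samples are clipped to the dynamic range", {
  m <- gait_model(1, 9, noise_sd = 0, stride_fraction = 0)
  rec <- gen_locomotion_signal(m, 10, 30, seed = 1, dynamic_range = 6)
  expect_lte(max(abs(rec$samples)), 6)
})

test_that("invalid locomotion requests are rejected", {
  expect_error(gen_locomotion_signal(gait_model(2, rep(0.1, 10)), 10, 30),
               "Nyquist")
  expect_error(gen_locomotion_signal(gait_model(2, 0.1), -5, 30), "positive")
  expect_error(gait_model(0, 0.1), "step_frequency")
  expect_error(gait_model(2, 0.1, axis_weights = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("rest signal is gravity plus calibrated noise", {
  r0 <- gen_rest_signal(10, 30, noise_sd = 0, seed = 1)
  expect_true(all(r0$samples[, 1] == 1))
  rn <- gen_rest_signal(60, 30, noise_sd = 0.005, seed = 2)
  expect_gt(stats::sd(rn$samples[, 1]), 0.004)
  expect_lt(stats::sd(rn$samples[, 1]), 0.006)
  expect_lt(abs(mean(rn$samples[, 1]) - 1), 3 * 0.005 / sqrt(1800))
  expect_error(gen_rest_signal(0, 30), "positive")
})

test_that("metabolic trace follows rmr times the MET demand", {
  prof <- subject_profile("adult", rmr = 0.3)
  proto <- data.frame(speed = c(3, 5), duration_s = 240)
  tr <- gen_metabolic_trace(prof, proto, noise_sd = 0, seed = 1)
  rest <- tr$time_s < 1100
  expect_equal(unique(tr$vo2[rest][-1]), 0.3)
  # steady state late in each stage equals the stage target
  late2 <- tr$time_s >= tr$stage_starts_s[2] + 180 &
    tr$time_s < tr$stage_starts_s[2] + 240
  expect_equal(mean(tr$vo2[late2]) / 0.3, met_at_speed(prof, 5), tolerance = 1e-3)
  expect_error(gen_metabolic_trace(prof, proto[0, ]), "empty")
})

test_that("child profiles have higher step frequency and lower METs than adults", {
  ad <- subject_profile("adult"); ch <- subject_profile("child")
  v <- c(2, 4, 6, 8, 10, 12)
  expect_true(all(step_freq_at_speed(ch, v) > step_freq_at_speed(ad, v)))
  expect_true(all(met_at_speed(ch, v) < met_at_speed(ad, v)))
  expect_true(all(diff(met_at_speed(ad, seq(0, 12, 0.5))) >= 0))
  # speed_at_met inverts met_at_speed
  expect_equal(speed_at_met(ad, met_at_speed(ad, 7)), 7, tolerance = 1e-10)
})

test_that("schedules reject overlap and disorder", {
  expect_error(day_schedule(c(0, 50), c(100, 100), c("rest", "rest")),
               "overlap")
  expect_error(day_schedule(c(100, 0), c(50, 50), c("rest", "rest")),
               "ordered")
  expect_error(day_schedule(0, 100, "locomotion"), "speed")
})

test_that("nonwear epoch fraction matches the schedule", {
  sched <- day_schedule(c(0, 3600, 7200), c(3600, 3600, 3600),
                        c("nonwear", "rest", "locomotion"),
                        c(NA, NA, 5))
  prof <- subject_profile("adult")
  lab <- truth_labels(sched, prof, 60)
  expect_equal(mean(lab == "nonwear"), 1 / 3)
  rec <- gen_freeliving_recording(sched, prof, seed = 1)
  expect_equal(mean(rec$idle), 1 / 3, tolerance = 1e-3)
  expect_equal(n_samples(rec), 3 * 3600 * 30)
})

test_that("free-living generation is reproducible and respects the range", {
  sched <- random_week_schedule(9, n_days = 1)
  prof <- subject_profile("adult")
  a <- gen_freeliving_recording(sched, prof, seed = 5)
  b <- gen_freeliving_recording(sched, prof, seed = 5)
  expect_identical(a$samples, b$samples)
  expect_lte(max(abs(a$samples)), 6)
  expect_identical(a$idle, b$idle)
})

test_that("random week schedules tile the period and alternate wear states", {
  sched <- random_week_schedule(3, n_days = 2)
  ends <- sched$start_s + sched$duration_s
  expect_equal(ends[nrow(sched)], 2 * 86400)
  expect_true(all(abs(sched$start_s[-1] - ends[-nrow(sched)]) < 1e-9))
  expect_setequal(unique(sched$activity),
                  c("nonwear", "rest", "locomotion"))
})
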