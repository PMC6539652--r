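test_that("wear mask follows the device idle flag", {
  rec <- gen_rest_signal(3600 * 4, 30, noise_sd = 0.005, seed = 1)
  expect_true(all(derive_wear_mask(rec, 60)$wear))
  # a scheduled 2 h idle block maps to 2 h of non-wear epochs (+/- boundary)
  rec$idle[(3600 * 30 + 1):(3600 * 3 * 30)] <- TRUE
  m <- derive_wear_mask(rec, 60)
  expect_equal(sum(!m$wear), 120, tolerance = 1)
  empty <- raw_recording(matrix(numeric(0), 0, 3), 30)
  expect_length(derive_wear_mask(empty, 60)$wear, 0L)
})

test_that("valid days need at least 12 h wear, inclusive at the boundary", {
  day_epochs <- 24 * 60
  mk <- function(wear_min) manual_mask(c(rep(TRUE, wear_min),
                                         rep(FALSE, day_epochs - wear_min)))
  expect_length(filter_valid_days(mk(13 * 60)), 1L)
  expect_length(filter_valid_days(mk(12 * 60)), 1L)      # exactly 12 h valid
  expect_length(filter_valid_days(mk(12 * 60 - 1)), 0L)  # 11 h 59 min invalid
})

test_that("daily window retains epoch starts in [06:00, 23:00)", {
  t0 <- as.POSIXct("2024-03-04 00:00:00", tz = "UTC")
  starts <- t0 + c(22 * 3600 + 59 * 60 + 57,  # 22:59:57 -> retained
                   23 * 3600,                 # 23:00:00 -> excluded
                   5 * 3600 + 3599,           # 05:59:59 -> excluded
                   6 * 3600)                  # 06:00:00 -> retained
  expect_equal(daily_window_mask(starts), c(TRUE, FALSE, FALSE, TRUE))
  es <- manual_series(1:4, epoch_length = 3, start_time = t0 + 23 * 3600 - 6)
  out <- apply_daily_window(es)
  expect_equal(out$series$values, 1:2)
})

test_that("classification uses half-open lower-inclusive intervals", {
  cp <- manual_cutpoints(c(20, 60, 170, 240))
  es <- manual_series(c(0, 19.99, 20, 59.99, 60, 170, 239.9, 240, 1000))
  lab <- classify_epochs(es, cp)
  expect_equal(as.character(lab$labels),
               c("SED", "SED", "LPA", "LPA", "MPA", "VPA", "VPA", "VVPA", "VVPA"))
})

test_that("counts cut-points scale linearly with epoch length", {
  cp <- manual_cutpoints(c(20, 60, 170, 240), unit = "counts_per_min")
  cpm <- cp$counts_per_min
  es <- manual_series(cpm[2] * 3 / 60 + c(-1e-9, 1e-9), unit = "counts")
  lab <- classify_epochs(es, cp)
  expect_equal(as.character(lab$labels), c("LPA", "MPA"))
})

test_that("unit mismatch between series and cut-points errors", {
  cp <- manual_cutpoints()  # mg cut-points
  es <- manual_series(c(1, 2), unit = "counts")
  expect_error(classify_epochs(es, cp), "unit")
})

test_that("an unattainable top cut-point collapses the classes above it", {
  cp <- manual_cutpoints(c(20, 60, 170, NA), attainable = c(TRUE, TRUE, TRUE, FALSE))
  lab <- classify_epochs(manual_series(c(10, 100, 5000)), cp)
  expect_equal(as.character(lab$labels), c("SED", "MPA", "VPA"))
})

test_that("a classification compared with itself is exactly diagonal", {
  cp <- manual_cutpoints()
  es <- manual_series(c(0, 30, 80, 200, 500, 10, 250))
  lab <- classify_epochs(es, cp)
  cm <- confusion_chart(lab, lab)
  expect_equal(unname(diag(cm)), rep(100, 5))
  expect_equal(unname(rowSums(cm)), rep(100, 5))
})

test_that("confusion rows are percentages over jointly included epochs", {
  cp <- manual_cutpoints()
  ref <- classify_epochs(manual_series(c(0, 0, 30, 30)), cp)
  cmp <- classify_epochs(manual_series(c(0, 30, 30, 80)), cp)
  cm <- confusion_chart(ref, cmp)
  expect_equal(cm["SED", "SED"], 50)
  expect_equal(cm["SED", "LPA"], 50)
  expect_equal(cm["LPA", "MPA"], 50)
  expect_true(all(is.na(cm["VPA", ])))
  expect_true("VPA" %in% attr(cm, "empty_rows"))
  occupied <- attr(cm, "row_n") > 0
  expect_equal(unname(rowSums(cm)[occupied]), rep(100, sum(occupied)),
               tolerance = 1e-3)
  # inclusion mask drops epochs from both series jointly
  cm2 <- confusion_chart(ref, cmp, include = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(sum(attr(cm2, "row_n")), 2)
})

test_that("intensity distributions sum to 100 and recover degenerate input", {
  cp <- manual_cutpoints()
  lab <- classify_epochs(manual_series(rep(0, 50)), cp)
  d <- intensity_distribution(lab)
  expect_equal(as.numeric(d["SED"]), 100)
  lab2 <- classify_epochs(manual_series(runif(200, 0, 400)), cp)
  expect_equal(sum(intensity_distribution(lab2)), 100, tolerance = 1e-3)
})

test_that("classification totals across labels equal the included epoch count", {
  cp <- manual_cutpoints()
  lab <- classify_epochs(manual_series(runif(300, 0, 500)), cp)
  inc <- rep(c(TRUE, FALSE), length.out = 300)
  expect_equal(sum(table(lab$labels[inc])), sum(inc))
})

test_that("total wear time is invariant to epoch length within boundaries", {
  sched <- day_schedule(c(0, 4 * 3600, 5 * 3600, 20 * 3600),
                        c(4 * 3600, 3600, 15 * 3600, 4 * 3600),
                        c("nonwear", "rest", "rest", "nonwear"))
  rec <- gen_freeliving_recording(sched, subject_profile("adult"), seed = 2)
  hours <- sapply(c(10, 60), function(e) {
    m <- derive_wear_mask(rec, e)
    sum(m$wear) * e / 3600
  })
  # two nonwear/wear boundaries, one epoch tolerance each
  expect_lt(abs(hours[1] - hours[2]), 2 * 60 / 3600 + 1e-9)
  expect_equal(hours[2], 16, tolerance = 0.05)
})

test_that("end-to-end: a clean 5-MET bout classifies as MPA", {
  prof <- subject_profile("adult")
  proto <- calibration_protocol("extended")
  pts <- do.call(rbind, lapply(1:3, function(s) simulate_calibration_subject(
    prof, proto, "bp10hz", seed = 300 + s, noise_sd_g = 0, vo2_noise_sd = 0)))
  cp <- derive_cutpoints(fit_calibration(pts, smoothing = 0.9,
                                         age_group = "adult", variant = "bp10hz"),
                         internal_rate_hz = 30)
  v5 <- speed_at_met(prof, 5)
  rec <- gen_locomotion_signal(gait_model_for_speed(prof, v5, noise_sd = 0),
                               120, 30, seed = 301)
  es <- vm_epochs(rec, filter_spec("bp10hz"), 3, unit = "mg")
  lab <- classify_epochs(es, cp)
  steady <- lab$labels[10:39]
  expect_gt(mean(steady == "MPA"), 0.9)
})
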