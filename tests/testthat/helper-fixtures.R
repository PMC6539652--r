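# Shared fixtures. Heavy objects are built lazily once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# single-axis pure tone recording (vertical axis only, no gravity removal
# concerns: gait_model adds the 1 g offset on the vertical axis)
tone_recording <- function(freq_hz, amp_g, duration_s = 60, rate_hz = 30,
                           seed = 5, noise_sd = 0) {
  gen_locomotion_signal(
    gait_model(freq_hz, amp_g, noise_sd = noise_sd,
               axis_weights = c(1, 0, 0), stride_fraction = 0),
    duration_s, rate_hz, seed = seed)
}

# small broadband gait recording for monotonicity-style checks
gait_recording <- function(speed = 8, duration_s = 120, seed = 7,
                           age_group = "adult", noise_sd = 0.01) {
  prof <- subject_profile(age_group)
  gen_locomotion_signal(gait_model_for_speed(prof, speed, noise_sd = noise_sd),
                        duration_s, 30, seed = seed, dynamic_range = 8)
}

# constructed cut-point set in mg with known thresholds
manual_cutpoints <- function(mg = c(20, 60, 170, 240), variant = "bp10hz",
                             attainable = rep(TRUE, 4), unit = "mg") {
  structure(
    data.frame(met_level = c(1.5, 3, 6, 9),
               label = c("LPA", "MPA", "VPA", "VVPA"),
               mg = mg, counts_per_min = mg * 256 * 30 * 60 / 4260,
               attainable = attainable),
    class = c("cutpoint_set", "data.frame"),
    age_group = "adult", variant = variant, unit = unit,
    labels = c("SED", "LPA", "MPA", "VPA", "VVPA"),
    internal_rate_hz = 30)
}

# epoch series on a given grid from raw values
manual_series <- function(values, epoch_length = 3, unit = "mg",
                          variant = "bp10hz",
                          start_time = as.POSIXct("2024-03-04 06:00:00", tz = "UTC")) {
  epoch_series(values, epoch_length, unit, "vector_magnitude", variant,
               internal_rate = 30, start_time = start_time)
}

# wear mask built directly from a logical vector
manual_mask <- function(wear, epoch_length = 60,
                        start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC")) {
  structure(list(wear = wear, epoch_length = epoch_length,
                 start_time = start_time, rule = "manual"),
            class = "wear_mask")
}
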