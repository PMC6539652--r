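#' Harmonic gait signal model
#'
#' Parametric model of hip-worn acceleration during steady locomotion: a
#' harmonic series at multiples of the step frequency (gait harmonics carry
#' energy up to roughly 10 Hz), a gravity offset on the vertical axis, an
#' optional stride-rate component at half the step frequency on the
#' horizontal axes (lateral sway and arm/trunk motion cycle once per stride,
#' i.e. every two steps), white sensor noise, and an optional high-frequency
#' contaminant (e.g. vehicle vibration above 10 Hz).
#'
#' @param step_frequency step rate in Hz (normal human ceiling is about 4 Hz).
#' @param harmonic_amplitudes per-harmonic peak accelerations in g; harmonic
#'   `k` sits at `k * step_frequency`.
#' @param vertical_gravity_offset static gravity on the vertical axis in g.
#' @param noise_sd white sensor noise SD in g (per axis).
#' @param axis_weights fraction of harmonic signal power per axis
#'   (vertical, ap, ml); must sum to 1.
#' @param stride_fraction amplitude of the stride-rate (step_frequency / 2)
#'   component as a fraction of the first harmonic, split over the ap and ml
#'   axes. Set to 0 for a pure step-harmonic model.
#' @param hf_amp,hf_freq amplitude (g) and frequency (Hz) of the optional
#'   high-frequency contaminant; default amplitude 0 (off).
#' @return An object of class `gait_model`.
#' @export
gait_model <- function(step_frequency, harmonic_amplitudes,
                       vertical_gravity_offset = 1, noise_sd = 0.01,
                       axis_weights = c(0.6, 0.25, 0.15),
                       stride_fraction = 0.35, hf_amp = 0, hf_freq = 12) {
  if (step_frequency <= 0) stop("step_frequency must be positive")
  if (any(harmonic_amplitudes < 0)) stop("harmonic amplitudes must be non-negative")
  if (abs(sum(axis_weights) - 1) > 1e-9) stop("axis_weights must sum to 1")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(
    list(step_frequency = step_frequency,
         harmonic_amplitudes = harmonic_amplitudes,
         vertical_gravity_offset = vertical_gravity_offset,
         noise_sd = noise_sd, axis_weights = axis_weights,
         stride_fraction = stride_fraction, hf_amp = hf_amp, hf_freq = hf_freq),
    class = "gait_model"
  )
}

#' Synthesize a steady locomotion recording
#'
#' Deterministic given the seed. Harmonic phases are drawn uniformly from the
#' seeded generator (avoids pathological constructive alignment); harmonic
#' power is distributed across axes by `sqrt(axis_weights)` amplitude scaling;
#' Gaussian sensor noise is added per axis; samples are clipped to the dynamic
#' range.
#'
#' @param model a [gait_model()].
#' @param duration_s signal duration in seconds (> 0).
#' @param sample_rate_hz sampling rate; must be at least twice the highest
#'   harmonic frequency.
#' @param seed integer seed.
#' @param dynamic_range symmetric clip in g.
#' @param start_time `POSIXct` start of the recording.
#' @return a [raw_recording()].
#' @export
gen_locomotion_signal <- function(model, duration_s, sample_rate_hz, seed = 1,
                                  dynamic_range = 6,
                                  start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC")) {
  if (duration_s <= 0) stop("duration must be positive")
  ka <- model$harmonic_amplitudes
  kmax_hz <- length(ka) * model$step_frequency
  if (kmax_hz > sample_rate_hz / 2 + 1e-9)
    stop("highest harmonic frequency exceeds Nyquist")
  if (model$hf_amp > 0 && model$hf_freq > sample_rate_hz / 2)
    stop("high-frequency contaminant exceeds Nyquist")
  n <- round(duration_s * sample_rate_hz)
  t <- (seq_len(n) - 1L) / sample_rate_hz
  rng <- local_rng(seed)
  phases <- rng$runif(length(ka), 0, 2 * pi)
  s <- numeric(n)
  for (k in seq_along(ka)) {
    if (ka[k] > 0)
      s <- s + ka[k] * sin(2 * pi * k * model$step_frequency * t + phases[k])
  }
  wa <- sqrt(model$axis_weights)
  samples <- cbind(model$vertical_gravity_offset + wa[1] * s,
                   wa[2] * s, wa[3] * s)
  if (model$stride_fraction > 0 && length(ka) && ka[1] > 0) {
    a_str <- model$stride_fraction * ka[1]
    ph <- rng$runif(1, 0, 2 * pi)
    arg <- pi * model$step_frequency * t + ph  # stride rate = step rate / 2
    samples[, 2] <- samples[, 2] + a_str * sin(arg)
    samples[, 3] <- samples[, 3] + a_str * cos(arg)
  }
  if (model$hf_amp > 0) {
    ph <- rng$runif(1, 0, 2 * pi)
    hf <- model$hf_amp * sin(2 * pi * model$hf_freq * t + ph)
    samples <- samples + hf %o% wa
  }
  if (model$noise_sd > 0)
    samples <- samples + matrix(rng$rnorm(3 * n, 0, model$noise_sd), n, 3)
  samples[samples > dynamic_range] <- dynamic_range
  samples[samples < -dynamic_range] <- -dynamic_range
  raw_recording(samples, sample_rate_hz, start_time = start_time,
                dynamic_range = dynamic_range)
}

#' Synthesize a resting (gravity-only) recording
#'
#' Vertical axis at 1 g plus white noise on all axes; emulates seated rest.
#'
#' @param duration_s duration in seconds (> 0).
#' @param sample_rate_hz sampling rate.
#' @param noise_sd sensor noise SD in g.
#' @param seed integer seed.
#' @param idle mark all samples idle (device-declared non-wear)?
#' @inheritParams gen_locomotion_signal
#' @return a [raw_recording()].
#' @export
gen_rest_signal <- function(duration_s, sample_rate_hz, noise_sd = 0.01, seed = 1,
                            dynamic_range = 6, idle = FALSE,
                            start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC")) {
  if (duration_s <= 0) stop("duration must be positive")
  n <- round(duration_s * sample_rate_hz)
  rng <- local_rng(seed)
  samples <- matrix(0, n, 3)
  samples[, 1] <- 1
  if (noise_sd > 0)
    samples <- samples + matrix(rng$rnorm(3 * n, 0, noise_sd), n, 3)
  samples[samples > dynamic_range] <- dynamic_range
  samples[samples < -dynamic_range] <- -dynamic_range
  raw_recording(samples, sample_rate_hz, start_time = start_time,
                dynamic_range = dynamic_range, idle = rep(idle, n))
}

# Seed-local RNG: draws do not disturb (or depend on) the global RNG state.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    s
  })
  draw <- function(fn) function(...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    out <- fn(...)
    env$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
    out
  }
  list(runif = draw(stats::runif), rnorm = draw(stats::rnorm),
       rlnorm = draw(stats::rlnorm), sample = draw(base::sample),
       rpois = draw(stats::rpois))
}

#' Treadmill calibration protocols
#'
#' The `standard` protocol is the conventional lab sequence: walking at 3,
#' 4, 5 and 6 km/h and running at 8 and 10 km/h, 4 minutes per stage, after
#' a 20-min seated rest. The `extended` protocol adds slow-walking and
#' fast-running stages (1-12 km/h in 1 km/h steps) so that the stage MET
#' demands straddle every intensity threshold (1.5-9 METs) for both age
#' groups; cut-point identifiability analyses use it, since a cut-point can
#' only be recovered where the calibration curve is pinned down by data on
#' both sides.
#'
#' @param type `"standard"` or `"extended"`.
#' @param stage_duration_s stage duration in seconds.
#' @return data frame with `speed` (km/h) and `duration_s`.
#' @export
calibration_protocol <- function(type = c("standard", "extended"),
                                 stage_duration_s = 240) {
  type <- match.arg(type)
  speeds <- switch(type, standard = c(3, 4, 5, 6, 8, 10), extended = 1:12)
  data.frame(speed = speeds, duration_s = stage_duration_s)
}

#' Subject profile for the synthetic study
#'
#' Encodes the physiological structure the calibration analysis relies on:
#' an individual resting metabolic rate (RMR, in consistent VO2 units such as
#' L/min), a monotone curvilinear speed-to-MET mapping
#' `MET(v) = 1 + met_scale * met_gain * v^met_exp`, and a speed-to-step-
#' frequency mapping `f(v) = min(4, step_base + step_slope * v) * step_factor`.
#' Children have higher RMR per unit size, hence lower METs at equal speed
#' (`met_scale` < 1), and a higher step frequency (`step_factor` > 1).
#'
#' @param age_group `"adult"` or `"child"`.
#' @param rmr resting VO2 (L/min); defaults 0.28 (adult) / 0.22 (child).
#' @param met_gain,met_exp,met_scale MET curve parameters; `met_scale`
#'   defaults to 1 (adult) / 0.88 (child).
#' @param step_base,step_slope,step_factor step-frequency curve parameters;
#'   `step_factor` defaults to 1 (adult) / 1.15 (child).
#' @param amp_per_kmh first-harmonic amplitude gain in g per km/h.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(age_group = c("adult", "child"), rmr = NULL,
                            met_gain = 0.25, met_exp = 1.55, met_scale = NULL,
                            step_base = 1.0, step_slope = 0.16,
                            step_factor = NULL, amp_per_kmh = 0.06) {
  age_group <- match.arg(age_group)
  if (is.null(rmr)) rmr <- if (age_group == "adult") 0.28 else 0.22
  if (is.null(met_scale)) met_scale <- if (age_group == "adult") 1 else 0.88
  if (is.null(step_factor)) step_factor <- if (age_group == "adult") 1 else 1.15
  if (rmr <= 0) stop("rmr must be positive")
  structure(
    list(age_group = age_group, rmr = rmr, met_gain = met_gain,
         met_exp = met_exp, met_scale = met_scale, step_base = step_base,
         step_slope = step_slope, step_factor = step_factor,
         amp_per_kmh = amp_per_kmh),
    class = "subject_profile"
  )
}

#' MET demand at a locomotion speed
#' @param profile a [subject_profile()].
#' @param speed_kmh speed in km/h (0 = rest).
#' @return METs (1 at rest; monotone nondecreasing in speed).
#' @export
met_at_speed <- function(profile, speed_kmh) {
  1 + profile$met_scale * profile$met_gain * pmax(0, speed_kmh)^profile$met_exp
}

#' Speed at which a MET demand is reached (inverse of [met_at_speed()])
#' @param profile a [subject_profile()].
#' @param met MET value (>= 1).
#' @return speed in km/h.
#' @export
speed_at_met <- function(profile, met) {
  ((met - 1) / (profile$met_scale * profile$met_gain))^(1 / profile$met_exp)
}

#' Step frequency at a locomotion speed
#' @param profile a [subject_profile()].
#' @param speed_kmh speed in km/h.
#' @return step frequency in Hz, capped at 4 Hz before the child factor.
#' @export
step_freq_at_speed <- function(profile, speed_kmh) {
  pmin(4, profile$step_base + profile$step_slope * speed_kmh) * profile$step_factor
}

#' Gait model implied by a profile at a given speed
#'
#' First-harmonic amplitude `amp_per_kmh * speed`, 1/k rolloff, harmonics up
#' to 10 Hz (at least one), stride component per the model default.
#'
#' @param profile a [subject_profile()].
#' @param speed_kmh speed in km/h (> 0).
#' @param noise_sd sensor noise SD in g.
#' @param freq_factor multiplier on the profile's step frequency (used for
#'   free-living bout-level jitter).
#' @param stride_sat_kmh walk-run transition speed. Lateral trunk sway grows
#'   with walking speed but only weakly beyond the transition to running
#'   (slope halved above it); because the stride component is the main
#'   in-band content of the narrow original filter at running speeds, this
#'   is what makes narrow-band output plateau (while staying weakly
#'   monotone) at running while wide-band output keeps growing.
#' @param harmonic_cap_hz highest harmonic frequency retained. Gait content
#'   concentrates below 10 Hz (the 1/k rolloff leaves ~95% of power there)
#'   but foot-strike transients carry a small tail above it, which is why a
#'   high-pass-only filter captures slightly more than the 10 Hz band.
#' @param ... passed through to [gait_model()].
#' @return a [gait_model()].
#' @export
gait_model_for_speed <- function(profile, speed_kmh, noise_sd = 0.01,
                                 freq_factor = 1, stride_sat_kmh = 6,
                                 harmonic_cap_hz = 14, ...) {
  if (speed_kmh <= 0) stop("speed must be positive for locomotion")
  f <- step_freq_at_speed(profile, speed_kmh) * freq_factor
  k <- max(1L, floor(harmonic_cap_hz / f))
  a1 <- profile$amp_per_kmh * speed_kmh
  v_eff <- min(speed_kmh, stride_sat_kmh) + 0.5 * max(0, speed_kmh - stride_sat_kmh)
  sf <- 0.35 * v_eff / speed_kmh
  gait_model(step_frequency = f, harmonic_amplitudes = a1 / seq_len(k),
             noise_sd = noise_sd, stride_fraction = sf, ...)
}

#' Synthesize a breath-by-breath VO2 trace for a lab protocol
#'
#' A 20-min seated-rest segment at speed 0 precedes the treadmill stages.
#' VO2 follows `rmr * MET(speed)` through first-order on/off kinetics with
#' time constant `tau_s` (steady state is reached well before the standard
#' selection window late in each stage), plus Gaussian breath noise.
#'
#' @param profile a [subject_profile()].
#' @param protocol data frame with columns `speed` (km/h) and `duration_s`.
#' @param breath_rate_hz breath sampling rate (breaths per second).
#' @param noise_sd breath-level VO2 noise SD (same units as `rmr`).
#' @param seed integer seed.
#' @param rest_duration_s initial rest duration (default 20 min).
#' @param tau_s VO2 kinetics time constant in seconds (0 = instantaneous).
#' @return An object of class `metabolic_trace`: `time_s`, `vo2`,
#'   `age_group`, `rest_duration_s`, `stage_starts_s` (named by speed).
#' @export
gen_metabolic_trace <- function(profile, protocol, breath_rate_hz = 0.3,
                                noise_sd = 0.03, seed = 1,
                                rest_duration_s = 1200, tau_s = 30) {
  protocol <- as.data.frame(protocol)
  if (nrow(protocol) == 0L) stop("empty protocol")
  if (any(protocol$speed < 0)) stop("speeds must be non-negative")
  total <- rest_duration_s + sum(protocol$duration_s)
  time_s <- seq(0, total, by = 1 / breath_rate_hz)
  bounds <- rest_duration_s + cumsum(c(0, protocol$duration_s))
  # intervals: [0, rest) = 1, then one per stage (last boundary = protocol end)
  stage_of <- findInterval(time_s, c(0, bounds[-length(bounds)]))
  met_target <- c(1, met_at_speed(profile, protocol$speed))[stage_of]
  if (tau_s > 0) {
    # first-order response to the piecewise-constant target
    met <- numeric(length(time_s))
    met[1] <- met_target[1]
    dt <- diff(time_s)
    for (i in seq_along(dt)) {
      a <- exp(-dt[i] / tau_s)
      met[i + 1] <- met_target[i + 1] + (met[i] - met_target[i + 1]) * a
    }
  } else met <- met_target
  vo2 <- profile$rmr * met
  if (noise_sd > 0) {
    rng <- local_rng(seed)
    vo2 <- vo2 + rng$rnorm(length(vo2), 0, noise_sd)
  }
  vo2 <- pmax(vo2, 1e-6)
  structure(
    list(time_s = time_s, vo2 = vo2, age_group = profile$age_group,
         rest_duration_s = rest_duration_s,
         stage_starts_s = stats::setNames(bounds[-length(bounds)],
                                          protocol$speed)),
    class = "metabolic_trace"
  )
}

#' Day schedule of free-living bouts
#'
#' Ordered, non-overlapping bouts of `nonwear`, `rest` or `locomotion`
#' (with a speed) tiling a recording period.
#'
#' @param start_s bout start offsets in seconds from the recording start.
#' @param duration_s bout durations in seconds (> 0).
#' @param activity character vector: `"nonwear"`, `"rest"` or `"locomotion"`.
#' @param speed_kmh locomotion speed per bout (`NA` for non-locomotion).
#' @return An object of class `day_schedule` (a data frame).
#' @export
day_schedule <- function(start_s, duration_s, activity, speed_kmh = NA_real_) {
  sched <- data.frame(start_s = start_s, duration_s = duration_s,
                      activity = activity,
                      speed_kmh = rep_len(speed_kmh, length(start_s)))
  if (any(sched$duration_s <= 0)) stop("bout durations must be positive")
  if (!all(sched$activity %in% c("nonwear", "rest", "locomotion")))
    stop("unknown activity type")
  if (is.unsorted(sched$start_s, strictly = TRUE)) stop("bouts must be chronologically ordered")
  ends <- sched$start_s + sched$duration_s
  if (any(sched$start_s[-1] < ends[-nrow(sched)] - 1e-9))
    stop("overlapping bouts")
  if (any(sched$activity == "locomotion" & !is.finite(sched$speed_kmh)))
    stop("locomotion bouts need a speed")
  class(sched) <- c("day_schedule", "data.frame")
  sched
}

#' Random multi-day free-living schedule
#'
#' Tiles `n_days` days: non-wear from 22:30 to 06:30, and a waking period
#' filled with seated/standing rest interleaved with walking bouts
#' (2.5-6.5 km/h) and running bouts (7-11.5 km/h). Bout counts and lengths
#' vary by day from the seeded generator; children get more, shorter bouts.
#'
#' @param seed integer seed.
#' @param n_days number of days.
#' @param age_group `"adult"` or `"child"` (affects bout structure).
#' @param wear_start_s,wear_end_s wear window within each day, seconds from
#'   midnight.
#' @return a [day_schedule()] spanning `n_days * 86400` seconds, starting at
#'   midnight.
#' @export
random_week_schedule <- function(seed = 1, n_days = 7,
                                 age_group = c("adult", "child"),
                                 wear_start_s = 6.5 * 3600,
                                 wear_end_s = 22.5 * 3600) {
  age_group <- match.arg(age_group)
  rng <- local_rng(seed + 7919L)
  rows <- list()
  add <- function(start, dur, act, speed = NA_real_) {
    rows[[length(rows) + 1L]] <<- data.frame(
      start_s = start, duration_s = dur, activity = act, speed_kmh = speed)
  }
  n_walk <- if (age_group == "adult") 8 else 12
  n_run <- if (age_group == "adult") 3 else 5
  bout_scale <- if (age_group == "adult") 1 else 0.6
  for (d in seq_len(n_days) - 1L) {
    day0 <- d * 86400
    add(day0, wear_start_s, "nonwear")
    # draw locomotion bouts for the waking period
    nw <- rng$rpois(1, n_walk); nr <- rng$rpois(1, n_run)
    nb <- nw + nr
    durs <- round(rng$runif(nb, 180, 1200) * bout_scale)
    speeds <- c(rng$runif(nw, 2.5, 6.5), rng$runif(nr, 7, 11.5))
    o <- rng$sample(nb)
    durs <- durs[o]; speeds <- speeds[o]
    wake_len <- wear_end_s - wear_start_s
    gap_total <- wake_len - sum(durs)
    stopifnot(gap_total > 0)
    g <- rng$runif(nb + 1L)
    gaps <- round(gap_total * g / sum(g))
    cursor <- day0 + wear_start_s
    for (i in seq_len(nb)) {
      if (gaps[i] > 0) { add(cursor, gaps[i], "rest"); cursor <- cursor + gaps[i] }
      add(cursor, durs[i], "locomotion", speeds[i])
      cursor <- cursor + durs[i]
    }
    if (day0 + wear_end_s - cursor > 0)
      add(cursor, day0 + wear_end_s - cursor, "rest")
    add(day0 + wear_end_s, 86400 - wear_end_s, "nonwear")
  }
  sched <- do.call(rbind, rows)
  day_schedule(sched$start_s, sched$duration_s, sched$activity, sched$speed_kmh)
}

#' Synthesize a free-living recording from a schedule
#'
#' Non-wear bouts are emitted as idle-flagged gravity samples (non-wear is a
#' device status, not a signal property). Rest bouts are gravity plus sensor
#' noise. Locomotion bouts are harmonic gait signals from
#' [gait_model_for_speed()], optionally with per-bout step-frequency jitter
#' (lognormal, `freq_sdlog`) and a slowly varying lognormal amplitude
#' envelope (AR(1) across 3-s blocks with coefficient `amp_ar`, marginal
#' sdlog `amp_sdlog`) emulating stride-to-stride and bout-level variability
#' of real gait. Set both sdlogs to 0 for a clean pipeline-recovery signal.
#'
#' @param schedule a [day_schedule()] tiling the recording period.
#' @param profile a [subject_profile()].
#' @param sample_rate_hz sampling rate (free-living devices here: 30 Hz).
#' @param seed integer seed.
#' @param noise_sd sensor noise SD in g.
#' @param amp_sdlog,amp_ar,freq_sdlog variability parameters (see above).
#' @param dynamic_range symmetric clip in g.
#' @param start_time `POSIXct` of schedule offset 0 (a local midnight).
#' @return a [raw_recording()] spanning the schedule.
#' @export
gen_freeliving_recording <- function(schedule, profile, sample_rate_hz = 30,
                                     seed = 1, noise_sd = 0.01,
                                     amp_sdlog = 0.25, amp_ar = 0.7,
                                     freq_sdlog = 0.08, dynamic_range = 6,
                                     start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC")) {
  stopifnot(inherits(schedule, "day_schedule"))
  rng <- local_rng(seed + 104729L)
  total_s <- schedule$start_s[nrow(schedule)] + schedule$duration_s[nrow(schedule)]
  n_total <- round(total_s * sample_rate_hz)
  samples <- matrix(0, n_total, 3)
  idle <- rep(FALSE, n_total)
  for (i in seq_len(nrow(schedule))) {
    i0 <- round(schedule$start_s[i] * sample_rate_hz) + 1L
    i1 <- round((schedule$start_s[i] + schedule$duration_s[i]) * sample_rate_hz)
    if (i1 < i0) next
    n <- i1 - i0 + 1L
    act <- schedule$activity[i]
    bout_seed <- (seed * 131071L + i * 613L) %% .Machine$integer.max
    if (act == "nonwear") {
      samples[i0:i1, 1] <- 1
      idle[i0:i1] <- TRUE
    } else if (act == "rest") {
      r <- gen_rest_signal(n / sample_rate_hz, sample_rate_hz, noise_sd,
                           seed = bout_seed, dynamic_range = dynamic_range)
      samples[i0:i1, ] <- r$samples[seq_len(n), ]
    } else {
      ff <- if (freq_sdlog > 0) rng$rlnorm(1, 0, freq_sdlog) else 1
      model <- gait_model_for_speed(profile, schedule$speed_kmh[i],
                                    noise_sd = noise_sd, freq_factor = ff)
      # keep all harmonics below Nyquist after jitter
      kmax <- floor((sample_rate_hz / 2 - 1e-9) / model$step_frequency)
      if (kmax < length(model$harmonic_amplitudes))
        model$harmonic_amplitudes <- model$harmonic_amplitudes[seq_len(max(1L, kmax))]
      r <- gen_locomotion_signal(model, n / sample_rate_hz, sample_rate_hz,
                                 seed = bout_seed, dynamic_range = dynamic_range)
      x <- r$samples[seq_len(n), , drop = FALSE]
      if (amp_sdlog > 0) {
        nb <- max(2L, ceiling(n / (3 * sample_rate_hz)))
        z <- numeric(nb)
        z[1] <- rng$rnorm(1)
        innov <- rng$rnorm(nb - 1L)
        for (b in 2:nb) z[b] <- amp_ar * z[b - 1] + sqrt(1 - amp_ar^2) * innov[b - 1L]
        env <- exp(amp_sdlog * z)
        env_t <- stats::approx(seq(0, 1, length.out = nb), env,
                               xout = seq(0, 1, length.out = n))$y
        x[, 1] <- 1 + (x[, 1] - 1) * env_t
        x[, 2] <- x[, 2] * env_t
        x[, 3] <- x[, 3] * env_t
      }
      x[x > dynamic_range] <- dynamic_range
      x[x < -dynamic_range] <- -dynamic_range
      samples[i0:i1, ] <- x
    }
  }
  raw_recording(samples, sample_rate_hz, start_time = start_time,
                dynamic_range = dynamic_range, idle = idle)
}

#' Ground-truth per-epoch labels from a schedule
#'
#' Labels each epoch (by its start time) from the scheduled activity: the
#' bout's MET demand via the profile's MET curve (rest = 1 MET) classified
#' against the MET thresholds of the intensity scheme, or `"nonwear"`.
#' This is the generator-side truth the recovery tests compare recovered
#' classifications against.
#'
#' @param schedule a [day_schedule()].
#' @param profile a [subject_profile()].
#' @param epoch_length_s epoch length in seconds.
#' @param scheme an [intensity_scheme()].
#' @return factor vector of labels (levels: intensity labels + `"nonwear"`),
#'   one per epoch over the schedule span.
#' @export
truth_labels <- function(schedule, profile, epoch_length_s,
                         scheme = intensity_scheme()) {
  total_s <- schedule$start_s[nrow(schedule)] + schedule$duration_s[nrow(schedule)]
  starts <- seq(0, total_s - epoch_length_s, by = epoch_length_s)
  bout <- findInterval(starts + 1e-9, schedule$start_s)
  act <- schedule$activity[bout]
  met <- ifelse(act == "rest", 1,
                ifelse(act == "locomotion",
                       met_at_speed(profile, schedule$speed_kmh[bout]), NA))
  lab <- ifelse(act == "nonwear", "nonwear",
                as.character(classify_met(met, scheme)))
  factor(lab, levels = c(scheme$labels, "nonwear"))
}
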