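#' Simulate one subject's lab calibration session
#'
#' Generates the treadmill protocol for one subject (stage gait signals at
#' the device rate, breath-by-breath VO2 with a 20-min rest segment),
#' processes the acceleration through the requested filter variants (1-s mg
#' and counts vector-magnitude epochs), and extracts one calibration point
#' per stage and variant. Stage signals share the subject's seed, so the
#' harmonic phases are common across speeds.
#'
#' @param profile a [subject_profile()].
#' @param protocol data frame with `speed` (km/h) and `duration_s` columns.
#' @param variants character vector of filter variants.
#' @param seed integer seed for this subject.
#' @param noise_sd_g accelerometer noise SD in g.
#' @param vo2_noise_sd breath-level VO2 noise SD.
#' @param sample_rate_hz accelerometer rate the stages are generated at; if
#'   above 30 Hz the recording is down-sampled to 30 Hz first (device
#'   emulation).
#' @param truncation_g clip applied with modified variants on calibration
#'   data (the wider-range lab device is truncated to the field device's
#'   +/-6 g range).
#' @param subject_id carried through for bookkeeping.
#' @return data frame of calibration points: one row per stage x variant
#'   with `subject`, `age_group`, `variant`, `speed_kmh`, `mets`, `mg`,
#'   `counts_per_min`, `internal_rate_hz`.
#' @export
simulate_calibration_subject <- function(profile, protocol, variants, seed,
                                         noise_sd_g = 0.01, vo2_noise_sd = 0.03,
                                         sample_rate_hz = 30, truncation_g = 6,
                                         subject_id = NA_integer_) {
  protocol <- as.data.frame(protocol)
  trace <- gen_metabolic_trace(profile, protocol, noise_sd = vo2_noise_sd,
                               seed = seed)
  rmr <- compute_rmr(trace)
  stages <- lapply(seq_len(nrow(protocol)), function(i) {
    gen_locomotion_signal(
      gait_model_for_speed(profile, protocol$speed[i], noise_sd = noise_sd_g),
      protocol$duration_s[i], sample_rate_hz, seed = seed,
      dynamic_range = 8)
  })
  rec <- concat_recordings(stages)
  rec <- ensure_30hz(rec)
  rest_s <- trace$rest_duration_s
  out <- list()
  for (v in variants) {
    spec <- filter_spec(v)
    mg <- vm_epochs(rec, spec, 1, unit = "mg", truncation_g = truncation_g)
    ct <- vm_epochs(rec, spec, 1, unit = "counts", truncation_g = truncation_g)
    for (i in seq_len(nrow(protocol))) {
      pt <- extract_stage(trace, mg, ct,
                          stage_start_s = trace$stage_starts_s[i], rmr = rmr,
                          stage_duration_s = protocol$duration_s[i],
                          speed_kmh = protocol$speed[i], accel_t0_s = rest_s)
      pt$subject <- subject_id
      pt$age_group <- profile$age_group
      pt$variant <- v
      pt$internal_rate_hz <- mg$internal_rate
      out[[length(out) + 1L]] <- pt
    }
  }
  do.call(rbind, out)
}

# profile with seeded between-subject variability around the group defaults
sample_subject_profile <- function(age_group, seed, sd = 0.08) {
  rng <- local_rng(seed + 52711L)
  base <- subject_profile(age_group)
  f <- function(x, s) x * rng$rlnorm(1, 0, s)
  subject_profile(age_group,
                  rmr = f(base$rmr, sd),
                  met_scale = f(base$met_scale, sd * 0.6),
                  step_factor = f(base$step_factor, sd * 0.4),
                  amp_per_kmh = f(base$amp_per_kmh, sd * 1.2))
}

#' Run the lab calibration workflow
#'
#' Simulates (or accepts) stage-level calibration points for each age group,
#' fits the anchored smoothing-spline calibration per age group and filter
#' variant, and evaluates the MET thresholds into a cut-point table.
#'
#' @param config named list validated by [validate_config()]
#'   (`kind = "calibration"`): seed, subject count, age groups, variants,
#'   protocol speeds / stage duration, smoothing, noise levels.
#' @param points optional pre-computed calibration points (as produced by
#'   [simulate_calibration_subject()]); when supplied, simulation is skipped.
#' @return list with `points`, `curves` (nested list by age group then
#'   variant), `cutpoints` (data frame: `age_group`, `variant`, `met_level`,
#'   `label`, `mg`, `counts_per_min`, `attainable`) and `config`.
#' @export
run_calibration_workflow <- function(config = list(), points = NULL) {
  config <- validate_config(config, "calibration")
  if (is.null(points)) {
    protocol <- data.frame(speed = config$protocol_speeds,
                           duration_s = config$stage_duration_s)
    acc <- list()
    for (g in config$age_groups) {
      for (s in seq_len(config$n_subjects)) {
        subj_seed <- (config$seed * 1000L + s * 17L +
                        ifelse(g == "child", 501L, 0L)) %% .Machine$integer.max
        prof <- sample_subject_profile(g, subj_seed, config$subject_sd)
        acc[[length(acc) + 1L]] <- simulate_calibration_subject(
          prof, protocol, config$variants, subj_seed,
          noise_sd_g = config$noise_sd_g, vo2_noise_sd = config$vo2_noise_sd,
          sample_rate_hz = config$sample_rate_hz,
          truncation_g = config$truncation_g, subject_id = s)
      }
    }
    points <- do.call(rbind, acc)
  }
  curves <- list()
  cps <- list()
  for (g in unique(points$age_group)) {
    curves[[g]] <- list()
    for (v in unique(points$variant)) {
      sub <- points[points$age_group == g & points$variant == v, ]
      curve <- fit_calibration(sub, smoothing = config$smoothing,
                               age_group = g, variant = v)
      rate <- sub$internal_rate_hz[1]
      cp <- derive_cutpoints(curve, internal_rate_hz = rate)
      curves[[g]][[v]] <- curve
      cps[[length(cps) + 1L]] <- cbind(age_group = g, variant = v,
                                       as.data.frame(cp))
    }
  }
  list(points = points, curves = curves,
       cutpoints = do.call(rbind, cps), config = config)
}

#' Run the free-living comparison workflow
#'
#' Simulates (or accepts) a multi-day free-living recording, processes it
#' with every filter variant at the configured epoch length, applies the
#' wear-time / valid-day / daily-window rules, classifies epochs with the
#' supplied cut-points, and produces the epoch-by-epoch confusion charts of
#' every modified variant against the original filter, the intensity
#' distribution per variant, and (optionally) the sub-band histograms
#' conditioned on reference intensity.
#'
#' @param config named list validated by [validate_config()]
#'   (`kind = "freeliving"`).
#' @param cutpoints cut-point table from [run_calibration_workflow()]
#'   (`$cutpoints`), covering the configured age group and variants, in mg.
#' @param recording optional pre-built [raw_recording()]; when missing a
#'   recording is simulated from [random_week_schedule()].
#' @param profile optional [subject_profile()] used for simulation.
#' @return list with `labels` (list by variant), `included` (logical mask),
#'   `confusion` (list by modified variant), `distribution` (matrix:
#'   variants x classes, percent), `subband_hist`, `relative`, `mask`,
#'   `config`.
#' @export
run_freeliving_workflow <- function(config = list(), cutpoints,
                                    recording = NULL, profile = NULL) {
  config <- validate_config(config, "freeliving")
  if (is.null(profile)) profile <- subject_profile(config$age_group)
  if (is.null(recording)) {
    sched <- random_week_schedule(config$seed, config$n_days, config$age_group)
    recording <- gen_freeliving_recording(
      sched, profile, seed = config$seed, noise_sd = config$noise_sd_g,
      amp_sdlog = config$amp_sdlog, freq_sdlog = config$freq_sdlog)
  }
  e <- config$epoch_length_s
  mask <- derive_wear_mask(recording, e)
  included <- inclusion_mask(mask, config$min_wear_h,
                             config$window_start, config$window_end)
  series <- list()
  labels <- list()
  for (v in config$variants) {
    series[[v]] <- vm_epochs(recording, filter_spec(v), e, unit = "mg")
    cp_rows <- cutpoints[cutpoints$age_group == config$age_group &
                           cutpoints$variant == v, ]
    if (nrow(cp_rows) == 0L) stop("no cut-points for variant ", v)
    cp <- structure(cp_rows[, c("met_level", "label", "mg", "counts_per_min",
                                "attainable")],
                    class = c("cutpoint_set", "data.frame"),
                    age_group = config$age_group, variant = v, unit = "mg",
                    labels = intensity_scheme()$labels)
    labels[[v]] <- classify_epochs(series[[v]], cp)
  }
  n_ep <- length(labels[[1]]$labels)
  included <- included[seq_len(n_ep)]
  confusion <- list()
  for (v in setdiff(config$variants, "ag_original"))
    confusion[[v]] <- confusion_chart(labels[["ag_original"]], labels[[v]],
                                      included)
  distribution <- t(vapply(config$variants, function(v)
    as.numeric(intensity_distribution(labels[[v]], included)),
    numeric(5)))
  colnames(distribution) <- intensity_scheme()$labels
  out <- list(labels = labels, included = included, confusion = confusion,
              distribution = distribution, mask = mask, config = config,
              series = series)
  if (isTRUE(config$subbands)) {
    specs <- all_subband_specs()
    ref <- if (e == 3) series[["ag_original"]]
    else vm_epochs(recording, filter_spec("ag_original"), 3, unit = "mg")
    bands <- lapply(specs[c("mid", "high", "vhigh")], function(sp)
      subband_series(recording, sp, 3))
    inc3 <- inclusion_mask(derive_wear_mask(recording, 3), config$min_wear_h,
                           config$window_start, config$window_end)
    inc3 <- inc3[seq_along(ref$values)]
    out$subband_hist <- subband_histogram(ref, bands, inc3)
    out$relative <- relative_contribution(out$subband_hist)
  }
  out
}
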