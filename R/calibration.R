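#' Intensity scheme: MET thresholds and class labels
#'
#' Five intensity classes separated by four MET thresholds, with half-open
#' lower-inclusive intervals: SED `< 1.5`, LPA `>= 1.5 - < 3`, MPA
#' `>= 3 - < 6`, VPA `>= 6 - < 9`, VVPA `>= 9`.
#'
#' @param thresholds increasing MET thresholds.
#' @param labels class labels; one more label than thresholds.
#' @return An object of class `intensity_scheme`.
#' @export
intensity_scheme <- function(thresholds = c(1.5, 3, 6, 9),
                             labels = c("SED", "LPA", "MPA", "VPA", "VVPA")) {
  if (is.unsorted(thresholds, strictly = TRUE)) stop("thresholds must be increasing")
  if (length(labels) != length(thresholds) + 1L)
    stop("need one more label than thresholds")
  structure(list(thresholds = thresholds, labels = labels),
            class = "intensity_scheme")
}

# classify MET values against scheme thresholds (lower-inclusive)
classify_met <- function(met, scheme = intensity_scheme()) {
  idx <- findInterval(met, scheme$thresholds) + 1L
  factor(scheme$labels[idx], levels = scheme$labels)
}

#' Resting metabolic rate from a seated-rest VO2 segment
#'
#' The resting VO2 trace is smoothed with a centered moving-average filter of
#' `window_s` seconds (time-based window over the breath series) and the
#' minimum smoothed value is the individual RMR.
#'
#' @param trace a `metabolic_trace` (see [gen_metabolic_trace()]) or a list
#'   with `time_s`, `vo2` and `rest_duration_s`.
#' @param window_s moving-average window in seconds (default 2 min).
#' @return RMR in the trace's VO2 units.
#' @export
compute_rmr <- function(trace, window_s = 120) {
  rest <- trace$time_s < trace$rest_duration_s
  t <- trace$time_s[rest]
  v <- trace$vo2[rest]
  if (length(t) < 2L || (max(t) - min(t)) < window_s)
    stop("resting segment shorter than the smoothing window")
  half <- window_s / 2
  cs <- cumsum(c(0, v))
  lo <- findInterval(t - half, t, left.open = TRUE) + 1L
  hi <- findInterval(t + half, t)
  sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  min(sm)
}

#' Extract one stage-level calibration point
#'
#' Takes the one-minute selection window starting `sel_start_s` into the
#' stage (default 2 min 45 s, i.e. the interval `[165, 225)` s of a 4-min
#' stage): VO2 is averaged over the window and divided by the RMR to give
#' METs; acceleration is the mean of the mg epochs whose start falls in the
#' window, and counts are aggregated over the window to a one-minute epoch.
#'
#' @param trace a `metabolic_trace`.
#' @param mg_epochs [epoch_series()] in mg (epoch length dividing the window).
#' @param counts_epochs [epoch_series()] in counts on the same recording.
#' @param stage_start_s stage start in seconds from the trace start.
#' @param rmr resting metabolic rate (from [compute_rmr()]).
#' @param sel_start_s,sel_len_s selection window offset and length in seconds.
#' @param stage_duration_s stage duration; the window must fit inside it.
#' @param speed_kmh stage speed, carried through for bookkeeping.
#' @param accel_t0_s time on the trace clock (s) of the first epoch of the
#'   acceleration series (e.g. the rest duration when the accelerometer
#'   series starts at the first treadmill stage).
#' @return one-row data frame: `speed_kmh`, `mets`, `mg`, `counts_per_min`.
#' @export
extract_stage <- function(trace, mg_epochs, counts_epochs, stage_start_s, rmr,
                          sel_start_s = 165, sel_len_s = 60,
                          stage_duration_s = 240, speed_kmh = NA_real_,
                          accel_t0_s = 0) {
  if (stage_duration_s < sel_start_s + sel_len_s)
    stop("stage shorter than the selection window")
  w0 <- stage_start_s + sel_start_s
  w1 <- w0 + sel_len_s
  inw <- trace$time_s >= w0 & trace$time_s < w1
  if (!any(inw)) stop("no VO2 breaths inside the selection window")
  mets <- mean(trace$vo2[inw]) / rmr
  sel_epochs <- function(es) {
    starts <- accel_t0_s + (seq_along(es$values) - 1) * es$epoch_length
    starts >= w0 - 1e-9 & starts < w1 - 1e-9
  }
  mg_in <- sel_epochs(mg_epochs)
  ct_in <- sel_epochs(counts_epochs)
  if (!any(mg_in) || !any(ct_in)) stop("no acceleration epochs inside the selection window")
  counts_min <- sum(counts_epochs$values[ct_in]) * 60 /
    (sum(ct_in) * counts_epochs$epoch_length)
  data.frame(speed_kmh = speed_kmh, mets = mets,
             mg = mean(mg_epochs$values[mg_in]), counts_per_min = counts_min)
}

#' Fit an anchored acceleration-vs-METs calibration curve
#'
#' Fits a cubic smoothing spline of acceleration output on METs (pooled
#' stage points from all subjects of one age group, one filter variant)
#' with smoothing parameter `smoothing` in the p-parameterization of
#' [fit_smoothing_spline()] (p = 0 least-squares line, p = 1 interpolant,
#' penalty in native MET units). The spline is taken over the MET axis
#' because the cut-points are produced by evaluating the fitted curve at
#' the MET thresholds; on the MET scale (range roughly 1-12) the smoothing
#' factor 0.1 yields the smooth curvilinear fits the calibration needs,
#' whereas over the acceleration axis (hundreds of mg) the same factor
#' would nearly interpolate the between-subject scatter and the evaluated
#' cut-points would inherit its wiggles. The forced starting point of zero
#' acceleration and one MET is a pseudo-observation at (1 MET, 0 mg) with
#' weight `anchor_weight` times the data weight.
#'
#' The returned curve exposes both directions: `met_to_accel` is the fitted
#' spline, and `fun` (acceleration to METs) is its first-attainment inverse
#' (smallest MET at which the fitted curve reaches the given acceleration),
#' which pins `fun(0) = 1` and is well defined even where the smoothed fit
#' is locally non-monotone.
#'
#' @param points data frame with columns `mets` and the acceleration column
#'   named by `unit` (`mg` or `counts_per_min`); at least 6 distinct MET
#'   values.
#' @param smoothing smoothing parameter p (default 0.1).
#' @param anchor numeric length-2, acceleration and MET of the forced start
#'   (default 0 acceleration, 1 MET).
#' @param anchor_weight weight multiplier of the anchor pseudo-point.
#' @param unit which acceleration column to calibrate on.
#' @param age_group,variant provenance carried onto the curve.
#' @return An object of class `calibration_curve` with fields `fun`
#'   (vectorized acceleration -> METs), `met_to_accel` (METs ->
#'   acceleration, the fitted spline), `met_range`, `x_range` (acceleration
#'   span), `points`, `unit`, `age_group`, `variant`, `smoothing`.
#' @export
fit_calibration <- function(points, smoothing = 0.1, anchor = c(0, 1),
                            anchor_weight = 1e8,
                            unit = c("mg", "counts_per_min"),
                            age_group = NA_character_, variant = NA_character_) {
  unit <- match.arg(unit)
  acc <- points[[unit]]
  met <- points$mets
  if (length(unique(met)) < 6L)
    stop("need at least 6 distinct MET values")
  if (length(unique(acc)) < 2L)
    stop("acceleration values are all identical")
  fit <- fit_smoothing_spline(c(anchor[2], met), c(anchor[1], acc),
                              w = c(anchor_weight, rep(1, length(met))),
                              p = smoothing)
  met_range <- c(anchor[2], max(met))
  mgrid <- seq(met_range[1], met_range[2], length.out = 4000L)
  agrid <- cummax(fit$fun(mgrid))  # first-attainment envelope
  inverse <- function(a) {
    vapply(a, function(ai) {
      if (ai <= agrid[1]) return(mgrid[1])
      i <- findInterval(ai, agrid)
      if (i >= length(mgrid)) return(NA_real_)
      lo <- mgrid[i]; hi <- mgrid[i + 1L]
      if (fit$fun(hi) >= ai && fit$fun(lo) <= ai)
        stats::uniroot(function(m) fit$fun(m) - ai, lower = lo, upper = hi,
                       tol = 1e-10)$root
      else  # attainment point sits on the envelope, interpolate the grid
        lo + (hi - lo) * (ai - agrid[i]) / max(agrid[i + 1L] - agrid[i], 1e-12)
    }, numeric(1))
  }
  if (abs(inverse(anchor[1]) - anchor[2]) > 1e-6)
    stop("anchor constraint not met: curve(0) != 1")
  # attainment envelope: smallest acceleration at which each MET is reached
  envelope <- stats::approxfun(mgrid, agrid, rule = 2)
  structure(
    list(fun = inverse, met_to_accel = fit$fun, envelope = envelope,
         met_range = met_range,
         x_range = c(min(anchor[1], min(acc)), max(acc)),
         points = points, unit = unit, smoothing = smoothing, anchor = anchor,
         age_group = age_group, variant = variant, spline = fit),
    class = "calibration_curve"
  )
}

#' @export
predict.calibration_curve <- function(object, newx, ...) object$fun(newx)

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("<calibration_curve> %s / %s, %d points on [%g, %g] %s, p = %g\n",
              x$age_group, x$variant, nrow(x$points), x$x_range[1],
              x$x_range[2], x$unit, x$smoothing))
  invisible(x)
}

#' Derive intensity cut-points from a calibration curve
#'
#' The fitted curve is evaluated at each MET threshold: the cut-point is
#' the acceleration the curve assigns to that MET demand (equivalently, the
#' smallest acceleration whose first-attainment MET equals the threshold).
#' A threshold beyond the fitted MET range (the calibration splines flatten
#' past the highest stage demands, so higher thresholds are not credible)
#' is reported as unattainable (`NA`). Cut-points are emitted in both mg
#' and counts/min using the variant's internal-rate conversion.
#'
#' @param curve a [fit_calibration()] curve.
#' @param scheme an [intensity_scheme()].
#' @param internal_rate_hz aggregation rate used in the counts conversion
#'   (10 Hz for the original chain, the device rate for modified variants).
#' @return An object of class `cutpoint_set`: a data frame with columns
#'   `met_level`, `label` (class entered at the threshold), `mg`,
#'   `counts_per_min`, `attainable`; attributes `age_group`, `variant`,
#'   `unit`, `labels` (all 5 class labels).
#' @export
derive_cutpoints <- function(curve, scheme = intensity_scheme(),
                             internal_rate_hz = 30) {
  cp <- vapply(scheme$thresholds, function(m) {
    if (m < curve$met_range[1] || m > curve$met_range[2]) return(NA_real_)
    max(0, curve$envelope(m))
  }, numeric(1))
  k <- count_constants()
  if (curve$unit == "mg") {
    mg <- cp
    cpm <- cp * k$b * internal_rate_hz * 60 / k$r
  } else {
    cpm <- cp
    mg <- counts_to_mg(cp, internal_rate_hz, 60)
  }
  ok <- !is.na(cp)
  if (sum(ok) >= 2 && is.unsorted(cp[ok], strictly = TRUE))
    warning("cut-points are not strictly increasing")
  out <- data.frame(met_level = scheme$thresholds,
                    label = scheme$labels[-1L],
                    mg = mg, counts_per_min = cpm, attainable = ok)
  structure(out, class = c("cutpoint_set", "data.frame"),
            age_group = curve$age_group, variant = curve$variant,
            unit = curve$unit, labels = scheme$labels,
            internal_rate_hz = internal_rate_hz)
}
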