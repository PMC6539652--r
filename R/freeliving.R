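#' Derive a per-epoch wear mask from device idle status
#'
#' An epoch is non-wear when more than `idle_threshold` of its samples carry
#' the idle status flag (idle-sleep-mode style detection: wear is decided by
#' device status, not by signal content).
#'
#' @param recording a [raw_recording()].
#' @param epoch_length_s epoch length in seconds.
#' @param idle_threshold fraction of idle samples above which an epoch is
#'   non-wear (default 0.5).
#' @return An object of class `wear_mask`: `wear` (logical per epoch),
#'   `epoch_length`, `start_time`.
#' @export
derive_wear_mask <- function(recording, epoch_length_s, idle_threshold = 0.5) {
  frac_idle <- aggregate_epochs(as.numeric(recording$idle),
                                recording$sample_rate, epoch_length_s,
                                stat = "mean")
  structure(
    list(wear = frac_idle <= idle_threshold, epoch_length = epoch_length_s,
         start_time = recording$start_time, rule = "idle_status"),
    class = "wear_mask"
  )
}

#' Find valid days (enough wear time)
#'
#' A calendar day is valid when its total wear time is at least `min_wear_h`
#' hours (inclusive boundary: exactly 12 h is valid). Wear time is counted
#' over the whole day; the daily analysis window is applied separately.
#'
#' @param mask a [derive_wear_mask()] mask.
#' @param min_wear_h minimum wear hours per day.
#' @return `Date` vector of valid days.
#' @export
filter_valid_days <- function(mask, min_wear_h = 12) {
  starts <- epoch_starts(mask)
  day <- as.Date(format(starts, "%Y-%m-%d"))
  wear_h <- tapply(mask$wear * mask$epoch_length / 3600, day, sum)
  as.Date(names(wear_h)[wear_h >= min_wear_h])
}

#' Daily analysis-window inclusion
#'
#' Epochs are included when their start time falls in `[start, end)` local
#' clock time (half-open: an epoch starting exactly at the window end is
#' excluded). The default window 06:00-23:00 removes overnight wear.
#'
#' @param x an `epoch_series`, `wear_mask`, or `POSIXct` vector of epoch
#'   starts.
#' @param start,end window bounds as `"HH:MM"` strings.
#' @return logical inclusion vector, one element per epoch.
#' @export
daily_window_mask <- function(x, start = "06:00", end = "23:00") {
  starts <- if (inherits(x, "POSIXct")) x else epoch_starts(x)
  secs <- as.numeric(format(starts, "%H")) * 3600 +
    as.numeric(format(starts, "%M")) * 60 +
    as.numeric(format(starts, "%S"))
  parse_hm <- function(s) {
    p <- as.numeric(strsplit(s, ":", fixed = TRUE)[[1]])
    p[1] * 3600 + p[2] * 60
  }
  secs >= parse_hm(start) & secs < parse_hm(end)
}

#' Apply the daily analysis window to an epoch series
#'
#' Convenience wrapper around [daily_window_mask()] returning the series
#' restricted to included epochs (values outside the window dropped).
#'
#' @inheritParams daily_window_mask
#' @param series an [epoch_series()].
#' @return list with `series` (values inside the window) and `included`
#'   (the logical mask on the original grid).
#' @export
apply_daily_window <- function(series, start = "06:00", end = "23:00") {
  inc <- daily_window_mask(series, start, end)
  out <- series
  out$values <- series$values[inc]
  list(series = out, included = inc)
}

#' Classify epochs by intensity cut-points
#'
#' Half-open lower-inclusive intervals: `[0, c1.5)` SED, `[c1.5, c3)` LPA,
#' `[c3, c6)` MPA, `[c6, c9)` VPA, `[c9, Inf)` VVPA (a value exactly at a
#' cut-point enters the class above it). Cut-points calibrated in counts/min
#' are scaled linearly to the series' epoch length before comparison; mg
#' cut-points (mean acceleration) are epoch-length invariant. An
#' unattainable upper cut-point collapses its boundary upward (the classes
#' above it are never assigned).
#'
#' @param series an [epoch_series()].
#' @param cutpoints a [derive_cutpoints()] set whose unit matches the series.
#' @return An object of class `label_series`: `labels` (factor, levels =
#'   intensity classes), `epoch_length`, `start_time`, `variant`.
#' @export
classify_epochs <- function(series, cutpoints) {
  unit <- attr(cutpoints, "unit")
  if (!identical(series$unit, if (unit == "counts_per_min") "counts" else unit))
    stop("unit mismatch between series and cut-points")
  thr <- if (unit == "mg") cutpoints$mg
  else cutpoints$counts_per_min * series$epoch_length / 60
  labels <- attr(cutpoints, "labels")
  thr_ok <- thr[cutpoints$attainable]
  idx <- findInterval(series$values, thr_ok) + 1L
  structure(
    list(labels = factor(labels[idx], levels = labels),
         epoch_length = series$epoch_length, start_time = series$start_time,
         variant = series$variant,
         cutpoint_provenance = c(age_group = attr(cutpoints, "age_group"),
                                 variant = attr(cutpoints, "variant"))),
    class = "label_series"
  )
}

#' Row-normalized confusion chart between two classifications
#'
#' Cross-tabulates two label series epoch by epoch over the jointly included
#' epochs, with the reference classification on rows, normalized so each
#' occupied row sums to 100%. Rows with zero reference epochs are flagged in
#' the `empty_rows` attribute and left as `NA`.
#'
#' @param ref,cmp [classify_epochs()] label series on identical grids
#'   (reference = original-filter labels by convention).
#' @param include logical inclusion mask (wear, valid day and daily window
#'   combined); default all.
#' @return matrix (rows = reference classes, columns = comparison classes)
#'   of row percentages, with attributes `row_n` (reference epoch counts)
#'   and `empty_rows`.
#' @export
confusion_chart <- function(ref, cmp, include = NULL) {
  if (length(ref$labels) != length(cmp$labels) ||
      ref$epoch_length != cmp$epoch_length)
    stop("label series grids do not match")
  if (is.null(include)) include <- rep(TRUE, length(ref$labels))
  r <- ref$labels[include]
  c_ <- cmp$labels[include]
  tab <- table(reference = r, comparison = c_)
  n <- rowSums(tab)
  pct <- sweep(tab, 1, n, "/") * 100
  pct[n == 0, ] <- NA_real_
  out <- unclass(as.matrix(pct))
  attr(out, "row_n") <- as.numeric(n)
  attr(out, "empty_rows") <- rownames(tab)[n == 0]
  out
}

#' Time distribution across intensity classes
#'
#' Fraction of included epochs at each intensity level, in percent.
#'
#' @param labels a [classify_epochs()] label series.
#' @param include logical inclusion mask; default all.
#' @return named numeric vector of percentages summing to 100.
#' @export
intensity_distribution <- function(labels, include = NULL) {
  if (is.null(include)) include <- rep(TRUE, length(labels$labels))
  l <- labels$labels[include]
  l <- l[!is.na(l)]
  100 * table(l) / length(l)
}

#' Combined inclusion mask: wear, valid day and daily window
#'
#' @param mask a [derive_wear_mask()] mask.
#' @param min_wear_h valid-day wear threshold in hours.
#' @param window_start,window_end daily window bounds (`"HH:MM"`).
#' @return logical vector, one element per epoch.
#' @export
inclusion_mask <- function(mask, min_wear_h = 12,
                           window_start = "06:00", window_end = "23:00") {
  starts <- epoch_starts(mask)
  valid <- filter_valid_days(mask, min_wear_h)
  day <- as.Date(format(starts, "%Y-%m-%d"))
  mask$wear & (day %in% valid) &
    daily_window_mask(starts, window_start, window_end)
}
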