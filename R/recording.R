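#' Raw triaxial acceleration recording
#'
#' Container for an equally spaced triaxial acceleration time series in g,
#' with the device metadata the processing chain needs (sample rate, symmetric
#' dynamic range) and a per-sample idle flag used for non-wear detection
#' (idle-sleep-mode style: the device, not the signal, says when it was idle).
#'
#' @param samples numeric matrix with `n` rows and 3 columns
#'   (vertical, anteroposterior, mediolateral), in g.
#' @param sample_rate sampling rate in Hz.
#' @param start_time `POSIXct` timestamp of the first sample. Timestamps are
#'   treated as naive local clock time.
#' @param dynamic_range symmetric full-scale range in g; samples must satisfy
#'   `|x| <= dynamic_range`.
#' @param idle logical vector of length `n`; `TRUE` marks samples recorded in
#'   idle (non-wear) state. Defaults to all-active.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sample_rate,
                          start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC"),
                          dynamic_range = 6, idle = NULL) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 3)
  samples <- as.matrix(samples)
  if (ncol(samples) != 3L) stop("samples must have 3 columns (vertical, ap, ml)")
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0)
    stop("sample_rate must be a positive scalar")
  if (dynamic_range <= 0) stop("dynamic_range must be positive")
  if (is.null(idle)) idle <- rep(FALSE, nrow(samples))
  idle <- as.logical(idle)
  if (length(idle) != nrow(samples)) stop("idle flag length must match sample count")
  if (nrow(samples) > 0 && max(abs(samples)) > dynamic_range + 1e-9)
    stop("samples exceed the declared dynamic range")
  colnames(samples) <- c("vertical", "ap", "ml")
  structure(
    list(samples = samples, sample_rate = sample_rate, start_time = start_time,
         dynamic_range = dynamic_range, idle = idle),
    class = "raw_recording"
  )
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf(
    "<raw_recording> %d samples @ %g Hz (%.1f s), range +/-%g g, %.1f%% idle\n",
    n_samples(x), x$sample_rate, duration_s(x), x$dynamic_range,
    100 * mean(x$idle)))
  invisible(x)
}

#' Number of samples in a recording
#' @param recording a `raw_recording`.
#' @return integer sample count.
#' @export
n_samples <- function(recording) nrow(recording$samples)

#' Duration of a recording in seconds
#' @param recording a `raw_recording`.
#' @return duration in seconds (`n / sample_rate`).
#' @export
duration_s <- function(recording) n_samples(recording) / recording$sample_rate

#' Concatenate recordings end to end
#'
#' All parts must share sample rate and dynamic range; the start time of the
#' first part is kept and the rest are assumed contiguous.
#'
#' @param ... `raw_recording` objects.
#' @return a single `raw_recording`.
#' @export
concat_recordings <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) && !inherits(parts[[1]], "raw_recording"))
    parts <- parts[[1]]
  stopifnot(length(parts) >= 1L)
  rate <- parts[[1]]$sample_rate
  rng <- parts[[1]]$dynamic_range
  for (p in parts) {
    if (!inherits(p, "raw_recording")) stop("all parts must be raw_recording objects")
    if (p$sample_rate != rate || p$dynamic_range != rng)
      stop("recordings differ in sample rate or dynamic range")
  }
  raw_recording(
    do.call(rbind, lapply(parts, function(p) p$samples)),
    sample_rate = rate, start_time = parts[[1]]$start_time,
    dynamic_range = rng, idle = unlist(lapply(parts, function(p) p$idle))
  )
}

#' Per-epoch output series
#'
#' Scalar output (activity counts or mean filtered acceleration in mg) on a
#' fixed epoch grid, with the provenance the downstream analyses need: filter
#' variant, axis, and the internal rate at which rectified samples were
#' aggregated (this rate enters the counts-to-mg conversion).
#'
#' @param values numeric vector of per-epoch values (must be non-negative).
#' @param epoch_length epoch length in seconds.
#' @param unit `"counts"` or `"mg"`.
#' @param axis `"vertical"`, `"ap"`, `"ml"` or `"vector_magnitude"`.
#' @param variant filter variant identifier (see [filter_spec()]).
#' @param internal_rate rate in Hz at which rectified samples were aggregated.
#' @param start_time `POSIXct` start of the first epoch.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values, epoch_length, unit, axis, variant,
                         internal_rate,
                         start_time = as.POSIXct("2024-03-04 00:00:00", tz = "UTC")) {
  values <- as.numeric(values)
  if (length(values) && min(values) < 0) stop("epoch values must be non-negative")
  unit <- match.arg(unit, c("counts", "mg"))
  structure(
    list(values = values, epoch_length = epoch_length, unit = unit, axis = axis,
         variant = variant, internal_rate = internal_rate, start_time = start_time),
    class = "epoch_series"
  )
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("<epoch_series> %d x %gs epochs, %s, axis=%s, variant=%s\n",
              length(x$values), x$epoch_length, x$unit, x$axis, x$variant))
  invisible(x)
}

#' Epoch start times of an epoch series or wear mask
#' @param x an `epoch_series` or `wear_mask`.
#' @return `POSIXct` vector of epoch start times.
#' @export
epoch_starts <- function(x) {
  n <- if (!is.null(x$values)) length(x$values) else length(x$wear)
  x$start_time + (seq_len(n) - 1L) * x$epoch_length
}

same_epoch_grid <- function(a, b) {
  length(a$values) == length(b$values) &&
    a$epoch_length == b$epoch_length &&
    abs(as.numeric(difftime(a$start_time, b$start_time, units = "secs"))) < 1e-6
}
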