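#' Count-scale constants
#'
#' The activity-count quantum comes from mapping the original +/-2.13 g device
#' range (2 x 2.13 g x 10^3 = 4260 mg full span, `r`) onto 8-bit resolution
#' (2^8 = 256 levels, `b`): one count corresponds to r/b = 16.640625 mg
#' (conventionally printed as 16.64 mg).
#'
#' @return list with `r` (full span, mg), `b` (quantization levels),
#'   `mg_per_count` (r/b) and `truncation_g` (2.13 g count-scale clip).
#' @export
count_constants <- function() {
  r <- 2 * 2.13 * 1e3
  b <- 2^8
  list(r = r, b = b, mg_per_count = r / b, truncation_g = 2.13)
}

#' Convert aggregated counts to mean acceleration in mg
#'
#' Aggregated counts divided by the internal aggregation rate `f` and epoch
#' length `e`, scaled back to mg: `mg = counts * r / (b * f * e)`. With the
#' original chain (f = 10 Hz, e = 60 s) the factor is 4260/(256*10*60) =
#' 0.0277 mg per count.
#'
#' @param counts non-negative aggregated counts.
#' @param internal_rate_hz rate at which rectified samples were aggregated.
#' @param epoch_length_s epoch length in seconds.
#' @return mean acceleration in mg.
#' @export
counts_to_mg <- function(counts, internal_rate_hz, epoch_length_s) {
  if (any(counts < 0)) stop("counts must be non-negative")
  if (internal_rate_hz <= 0 || epoch_length_s <= 0)
    stop("internal rate and epoch length must be positive")
  k <- count_constants()
  counts * k$r / (k$b * internal_rate_hz * epoch_length_s)
}

#' Down-sample a recording
#'
#' Applies an anti-aliasing low-pass (8th-order Butterworth with cutoff at
#' 0.8 x target Nyquist) before interpolating onto the target grid, so that
#' content above the target Nyquist cannot alias. Duration is preserved
#' within one sample period; upsampling is not supported. Idle flags are
#' carried over by nearest neighbour.
#'
#' @param recording a [raw_recording()].
#' @param target_rate_hz target sampling rate (must not exceed the source rate).
#' @return a [raw_recording()] at the target rate.
#' @export
resample_recording <- function(recording, target_rate_hz) {
  src <- recording$sample_rate
  if (target_rate_hz > src) stop("upsampling is not supported")
  if (target_rate_hz == src) return(recording)
  n <- n_samples(recording)
  aa <- signal::butter(8, (0.8 * target_rate_hz / 2) / (src / 2), type = "low")
  t_src <- (seq_len(n) - 1L) / src
  n_new <- floor(n * target_rate_hz / src)
  t_new <- (seq_len(n_new) - 1L) / target_rate_hz
  out <- matrix(0, n_new, 3)
  for (j in 1:3) {
    xf <- as.numeric(signal::filter(aa, recording$samples[, j]))
    out[, j] <- stats::spline(t_src, xf, xout = t_new, method = "fmm")$y
  }
  # interpolation can overshoot marginally at sharp clipped edges
  out[out > recording$dynamic_range] <- recording$dynamic_range
  out[out < -recording$dynamic_range] <- -recording$dynamic_range
  idle_new <- recording$idle[pmin(n, round(t_new * src) + 1L)]
  raw_recording(out, target_rate_hz, start_time = recording$start_time,
                dynamic_range = recording$dynamic_range, idle = idle_new)
}

# Shared per-axis processing chain. Returns rectified per-sample values in g
# at the internal aggregation rate, plus that rate and the idle flags on the
# same grid. The original chain anti-alias filters, band-passes, decimates to
# 10 Hz and clips to +/-2.13 g; modified chains band-pass at the device rate
# with no decimation. Idle samples contribute zero.
process_axis <- function(x, idle, spec, sample_rate, truncation_g = NULL,
                         dead_band_g = NULL) {
  variant <- spec$variant
  if (identical(variant, "ag_original")) {
    aa <- signal::butter(8, 5 / (sample_rate / 2), type = "low")
    x <- as.numeric(signal::filter(aa, x))
    resp <- design_filter(spec, sample_rate)
    x <- apply_filter(resp, x)
    dec <- as.integer(round(sample_rate / 10))
    keep <- seq(1L, length(x), by = dec)
    x <- x[keep]
    idle <- idle[keep]
    internal_rate <- sample_rate / dec
    clip <- count_constants()$truncation_g
    x[x > clip] <- clip
    x[x < -clip] <- -clip
    if (is.null(dead_band_g)) dead_band_g <- 0.068
  } else {
    resp <- design_filter(spec, sample_rate)
    x <- apply_filter(resp, x)
    if (!is.null(truncation_g)) {
      x[x > truncation_g] <- truncation_g
      x[x < -truncation_g] <- -truncation_g
    }
    internal_rate <- sample_rate
    if (is.null(dead_band_g)) dead_band_g <- 0
  }
  x <- abs(x)
  if (dead_band_g > 0) x[x < dead_band_g] <- 0
  x[idle] <- 0
  list(rectified = x, internal_rate = internal_rate, idle = idle)
}

aggregate_epochs <- function(x, internal_rate, epoch_length_s, stat = c("sum", "mean")) {
  stat <- match.arg(stat)
  spe <- internal_rate * epoch_length_s
  if (abs(spe - round(spe)) > 1e-9)
    stop("epoch length is not an integer number of samples at the internal rate")
  spe <- as.integer(round(spe))
  n_ep <- length(x) %/% spe
  if (n_ep * spe < length(x))
    message(sprintf("dropping trailing partial epoch (%d samples)",
                    length(x) - n_ep * spe))
  if (n_ep == 0L) return(numeric(0))
  m <- matrix(x[seq_len(n_ep * spe)], nrow = spe)
  if (stat == "sum") colSums(m) else colMeans(m)
}

ensure_30hz <- function(recording) {
  if (abs(recording$sample_rate - 30) < 1e-9) return(recording)
  message(sprintf("resampling recording from %g Hz to 30 Hz before count generation",
                  recording$sample_rate))
  resample_recording(recording, 30)
}

#' Generate per-axis activity counts
#'
#' Realizes the count-generation chain for one recording and filter variant.
#' The original variant applies an anti-aliasing low-pass, the 0.29-1.63 Hz
#' band-pass, decimation to a 10 Hz internal rate, truncation to +/-2.13 g,
#' rectification, a dead-band, and per-sample quantization to integer counts
#' (floor of |x| / 16.640625 mg) which are summed per epoch. The modified
#' variants band-pass at the device rate (no anti-aliasing stage, no
#' decimation), optionally truncate, rectify and quantize identically.
#' Idle-status samples contribute zero. Trailing partial epochs are dropped.
#'
#' @param recording a [raw_recording()]; resampled to 30 Hz if not already.
#' @param spec a [filter_spec()].
#' @param epoch_length_s epoch length in seconds (1, 3, 10 or 60).
#' @param truncation_g optional clip in g applied with modified variants
#'   (use 6 for calibration-protocol data recorded on wider-range devices;
#'   `NULL` for data already range-limited). The original variant always
#'   clips at +/-2.13 g.
#' @param dead_band_g dead-band threshold in g; values below it are zeroed
#'   before quantization. Defaults to 0.068 g for the original variant and 0
#'   for modified variants.
#' @return named list of three [epoch_series()] (vertical, ap, ml) in counts.
#' @export
compute_counts <- function(recording, spec, epoch_length_s, truncation_g = NULL,
                           dead_band_g = NULL) {
  recording <- ensure_30hz(recording)
  q_g <- count_constants()$mg_per_count / 1000
  out <- list()
  for (j in 1:3) {
    p <- process_axis(recording$samples[, j], recording$idle, spec,
                      recording$sample_rate, truncation_g, dead_band_g)
    counts <- floor(p$rectified / q_g)
    out[[colnames(recording$samples)[j]]] <- epoch_series(
      aggregate_epochs(counts, p$internal_rate, epoch_length_s),
      epoch_length = epoch_length_s, unit = "counts",
      axis = colnames(recording$samples)[j], variant = spec$variant,
      internal_rate = p$internal_rate, start_time = recording$start_time)
  }
  out
}

#' Mean filtered acceleration per epoch in mg
#'
#' Same chain as [compute_counts()] but without the 8-bit quantization: the
#' epoch value is the mean of the rectified filtered samples, scaled to mg.
#' Decimals are retained, so counts and mg outputs agree only up to the
#' per-sample quantization bound.
#'
#' @inheritParams compute_counts
#' @return named list of three [epoch_series()] (vertical, ap, ml) in mg.
#' @export
mean_filtered_mg <- function(recording, spec, epoch_length_s, truncation_g = NULL,
                             dead_band_g = NULL) {
  recording <- ensure_30hz(recording)
  out <- list()
  for (j in 1:3) {
    p <- process_axis(recording$samples[, j], recording$idle, spec,
                      recording$sample_rate, truncation_g, dead_band_g)
    out[[colnames(recording$samples)[j]]] <- epoch_series(
      aggregate_epochs(p$rectified * 1e3, p$internal_rate, epoch_length_s, stat = "mean"),
      epoch_length = epoch_length_s, unit = "mg",
      axis = colnames(recording$samples)[j], variant = spec$variant,
      internal_rate = p$internal_rate, start_time = recording$start_time)
  }
  out
}

#' Combine per-axis epoch series into a vector magnitude
#'
#' Per-epoch Euclidean norm of the three axis outputs (the standard
#' per-epoch vector-magnitude convention).
#'
#' @param x,y,z [epoch_series()] on identical grids with identical units,
#'   variants and epoch lengths.
#' @return an [epoch_series()] with `axis = "vector_magnitude"`.
#' @export
vector_magnitude <- function(x, y, z) {
  for (other in list(y, z)) {
    if (!same_epoch_grid(x, other)) stop("epoch grids do not match")
    if (x$unit != other$unit || x$variant != other$variant)
      stop("units or filter variants do not match")
  }
  epoch_series(sqrt(x$values^2 + y$values^2 + z$values^2),
               epoch_length = x$epoch_length, unit = x$unit,
               axis = "vector_magnitude", variant = x$variant,
               internal_rate = x$internal_rate, start_time = x$start_time)
}

#' Vector-magnitude epoch output for one variant
#'
#' Convenience wrapper: per-axis processing via [compute_counts()] or
#' [mean_filtered_mg()], combined with [vector_magnitude()].
#'
#' @inheritParams compute_counts
#' @param unit `"mg"` or `"counts"`.
#' @return an [epoch_series()] with `axis = "vector_magnitude"`.
#' @export
vm_epochs <- function(recording, spec, epoch_length_s, unit = c("mg", "counts"),
                      truncation_g = NULL, dead_band_g = NULL) {
  unit <- match.arg(unit)
  per_axis <- if (unit == "mg")
    mean_filtered_mg(recording, spec, epoch_length_s, truncation_g, dead_band_g)
  else
    compute_counts(recording, spec, epoch_length_s, truncation_g, dead_band_g)
  vector_magnitude(per_axis[[1]], per_axis[[2]], per_axis[[3]])
}
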