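#' Frequency filter specification
#'
#' Declarative definition of the band-pass filter applied before rectification
#' and aggregation. Four variants are supported: the original ActiGraph-style
#' narrow band (half-power edges 0.29 and 1.63 Hz), two widened fourth-order
#' Butterworth band-passes sharing the 0.29 Hz high-pass edge but with the
#' low-pass edge moved to 4 or 10 Hz, and a high-pass-only variant where the
#' low-pass component is removed entirely.
#'
#' @param variant one of `"ag_original"`, `"bp4hz"`, `"bp10hz"`, `"hp_only"`.
#' @return An object of class `filter_spec` with fields `variant`, `order`,
#'   `high_pass_cutoff` (Hz) and `low_pass_cutoff` (Hz, `NA` for `hp_only`).
#' @export
filter_spec <- function(variant = c("ag_original", "bp4hz", "bp10hz", "hp_only")) {
  variant <- match.arg(variant)
  low <- switch(variant, ag_original = 1.63, bp4hz = 4, bp10hz = 10, hp_only = NA_real_)
  structure(
    list(variant = variant, order = 4L, high_pass_cutoff = 0.29, low_pass_cutoff = low),
    class = "filter_spec"
  )
}

#' All four filter variants
#' @return named list of [filter_spec()] objects.
#' @export
all_filter_specs <- function() {
  v <- c("ag_original", "bp4hz", "bp10hz", "hp_only")
  stats::setNames(lapply(v, filter_spec), v)
}

#' Design a digital filter from a specification
#'
#' Realizes the spec as a causal digital Butterworth filter at the given
#' sample rate (band-pass designs of total order 4; the high-pass-only
#' variant as a fourth-order high-pass). The realized half-power frequencies
#' are measured from the magnitude response and checked against the spec
#' within 2% relative error; an unstable realization or a cutoff at or above
#' Nyquist is an error.
#'
#' @param spec a [filter_spec()] or a list with fields `order` (total order,
#'   even for band-pass), `high_pass_cutoff` and `low_pass_cutoff` (Hz,
#'   `NA` for high-pass only).
#' @param sample_rate_hz sampling rate of the data the filter will run on.
#' @return An object of class `filter_response`: transfer-function
#'   coefficients `b`, `a`, the `sample_rate`, the originating `spec` and the
#'   measured `half_power_hz` (named `low`, `high`; `high` is `NA` for
#'   high-pass designs).
#' @export
design_filter <- function(spec, sample_rate_hz) {
  nyq <- sample_rate_hz / 2
  hp <- spec$high_pass_cutoff
  lp <- spec$low_pass_cutoff
  ord <- if (is.null(spec$order)) 4L else as.integer(spec$order)
  if (hp >= nyq || (!is.na(lp) && lp >= nyq))
    stop("filter cutoff at or above Nyquist frequency")
  if (is.na(lp)) {
    ba <- signal::butter(ord, hp / nyq, type = "high")
  } else {
    if (ord %% 2L != 0L) stop("band-pass order must be even")
    ba <- signal::butter(ord / 2L, c(hp, lp) / nyq, type = "pass")
  }
  if (max(Mod(polyroot(rev(ba$a)))) >= 1)
    stop("unstable filter realization")
  resp <- structure(
    list(b = ba$b, a = ba$a, sample_rate = sample_rate_hz, spec = spec,
         half_power_hz = c(low = NA_real_, high = NA_real_)),
    class = "filter_response"
  )
  resp$half_power_hz <- half_power_edges(resp)
  tol <- 0.02
  if (abs(resp$half_power_hz[["low"]] - hp) / hp > tol)
    stop("realized high-pass edge off spec by more than 2%")
  if (!is.na(lp) && abs(resp$half_power_hz[["high"]] - lp) / lp > tol)
    stop("realized low-pass edge off spec by more than 2%")
  resp
}

#' Evaluate a filter's complex frequency response
#' @param resp a `filter_response`.
#' @param f frequencies in Hz.
#' @return complex vector `H(f)`.
#' @export
filter_response_at <- function(resp, f) {
  w <- 2 * pi * f / resp$sample_rate
  z <- exp(-1i * w)
  num <- outer(z, seq_along(resp$b) - 1, `^`) %*% resp$b
  den <- outer(z, seq_along(resp$a) - 1, `^`) %*% resp$a
  as.vector(num / den)
}

#' Measure realized half-power (-3 dB) edge frequencies
#'
#' Locates the frequencies where the squared magnitude response crosses one
#' half, by bisection on a fine grid between DC and Nyquist. For band-pass
#' designs both edges are returned; for high-pass designs only the low edge.
#'
#' @param resp a `filter_response`.
#' @param n grid size used to bracket the crossings.
#' @return named numeric vector `c(low=, high=)` in Hz (`high` is `NA` for
#'   high-pass designs).
#' @export
half_power_edges <- function(resp, n = 16384L) {
  f <- seq(0, resp$sample_rate / 2, length.out = n)
  m2 <- Mod(filter_response_at(resp, f))^2
  g <- function(freq) Mod(filter_response_at(resp, freq))^2 - 0.5
  peak <- which.max(m2)
  cross_root <- function(i) {
    stats::uniroot(g, lower = f[i], upper = f[i + 1], tol = 1e-10)$root
  }
  # low edge: last upward crossing below the response peak
  below <- which(m2[seq_len(peak - 1)] < 0.5)
  low <- if (length(below)) cross_root(max(below)) else NA_real_
  # high edge: first downward crossing above the peak
  above <- which(m2 < 0.5)
  above <- above[above > peak]
  high <- if (length(above)) cross_root(min(above) - 1L) else NA_real_
  c(low = low, high = high)
}

#' Apply a designed filter to a signal (causal, zero initial conditions)
#' @param resp a `filter_response`.
#' @param x numeric signal vector.
#' @return filtered signal of the same length.
#' @export
apply_filter <- function(resp, x) {
  as.numeric(signal::filter(signal::Arma(b = resp$b, a = resp$a), x))
}
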