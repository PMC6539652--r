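---
title: "Frequency filtering, MET calibration and intensity classification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency filtering, MET calibration and intensity classification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(accelband)
```

## The problem

Hip-worn accelerometer studies conventionally reduce raw acceleration to
*activity counts*: the signal is band-pass filtered, rectified, quantized and
summed over epochs. The de-facto standard narrow band (half-power edges 0.29
and 1.63 Hz) was designed around slow walking, but human gait places harmonic
energy up to roughly 10 Hz, and step frequency rises with speed and is higher
in children. A narrow filter therefore discards an intensity-dependent share
of the movement signal: counts plateau at running speeds, and the resulting
intensity classification degrades exactly where physical-activity guidelines
care most. Widening the band captures more of the signal but potentially also
more non-movement noise (e.g. vehicle vibration above 10 Hz).

`accelband` implements the full comparison pipeline: the original count chain
and three widened fourth-order Butterworth variants (low-pass edge at 4 Hz,
10 Hz, or removed), calibration of each variant's output against energy
expenditure to obtain filter-specific intensity cut-points, free-living
classification agreement between filters, and a frequency sub-band
decomposition of free-living acceleration conditioned on reference intensity.
Because the underlying cohort data are not public, a synthetic-data module
generates lab and free-living recordings with the statistical structure the
analysis assumes, with known ground truth.

## The count chain

All variants share the same skeleton per axis:

1. *Filter.* The original chain applies an 8th-order anti-aliasing low-pass
   at 5 Hz, the 0.29–1.63 Hz band-pass, and decimates to a 10 Hz internal
   rate. (The canonical replication of the proprietary chain distributes
   fixed filter coefficients; this package instead designs a Butterworth
   band-pass from the published half-power points, which keeps it
   self-contained; realized edges are checked to land within 2% of nominal.)
   The modified variants apply their fourth-order Butterworth band-pass at
   the device rate (30 Hz) with no anti-aliasing stage and no decimation.
   All filtering is causal single-pass (the device processes a live stream);
   startup transients are not trimmed.
2. *Truncate.* The original chain clips at ±2.13 g (its count scale's full
   range). Modified variants clip calibration-protocol data at ±6 g to
   emulate the narrower range of the field device; free-living 30 Hz ±6 g
   data are already range-limited.
3. *Rectify* (absolute value); samples flagged idle contribute zero.
4. *Dead-band.* The original chain zeroes rectified samples below 0.068 g
   (the replication literature's threshold); modified variants apply none.
5. *Quantize and aggregate.* For counts, each sample is floored to integer
   multiples of the count quantum and summed per epoch; the quantum comes
   from mapping the ±2.13 g range onto 8 bits:
   2 × 2.13 g × 10³ / 2⁸ = 4260 / 256 = 16.64 mg per count.
   For mean-mg output the quantization is skipped and the epoch value is the
   mean rectified sample in mg. Counts convert back to mean mg as
   `counts × r/(b·f·e)`; with the original chain's 10 Hz internal rate and
   60 s epochs the factor is 0.0277. Because quantization floors per sample,
   counts-times-factor always under-reports mean mg by less than one quantum
   — an exact invariant the tests assert.
6. *Vector magnitude.* Per-epoch Euclidean norm across the three axes
   (per-sample vector magnitude is not used; per-epoch VM of per-axis
   aggregates is the standard device convention).

Trailing partial epochs are dropped, never padded. Epoch lengths 1, 3, 10
and 60 s are supported; 3 s is the headline choice (long enough for the
0.29 Hz high-pass's ~3 s cycle, short enough for intermittent activity).

## Calibration model

Each simulated subject rests 20 min and completes treadmill stages; VO₂ is
generated breath by breath. The analysis chain:

- *RMR*: minimum of a 2-min centered moving average over the resting VO₂.
- *Stage points*: the minute beginning 2:45 into each stage (half-open
  window `[165, 225)` s) gives mean VO₂ → METs (divide by RMR), mean mg,
  and counts aggregated to one minute.
- *Curve*: a cubic smoothing spline of acceleration output on METs, fitted
  per age group and filter variant, with a forced starting point of zero
  acceleration at one MET, and evaluated at 1.5/3/6/9 METs to yield the
  cut-points (classes SED / LPA / MPA / VPA / VVPA, lower-inclusive
  intervals per the `≥1.5–<3` convention).

Two numerical choices deserve explanation.

**Smoothing parameterization.** The spline minimizes
`p·Σw(y−f)² + (1−p)·∫f″²` with `p = 0.1`, in native x units — the MATLAB
`fit`/`csaps` convention, where a given `p`'s effect depends on the x scale.
The package implements this criterion directly (a weighted natural cubic
smoothing spline in Reinsch form) rather than through `stats::smooth.spline`,
which rescales x to [0, 1] and renormalizes weights internally and would
silently change both the meaning of `p = 0.1` and the anchor weighting. The
fit is taken over the MET axis (range ≈ 1–12), where `p = 0.1` yields
genuinely smooth curvilinear fits; over the acceleration axis (hundreds of
mg) the same `p` would essentially interpolate the between-subject scatter,
and cut-points read off such a fit inherit its wiggles. Evaluating the
fitted curve at the MET thresholds is also what produces cut-point tables
that are orderly across filters and MET levels.

**Anchor.** The forced starting point is a pseudo-observation at (1 MET,
0 acceleration) with weight 10⁸ — large enough that the curve passes the
anchor to ≈10⁻⁸ in MET units (the package asserts 10⁻⁶). The
acceleration→MET direction required by the classification interface is the
*first-attainment inverse*: the smallest MET at which the fitted curve
reaches a given acceleration. Cut-points likewise use the first-attainment
envelope, which keeps them monotone across MET levels even where the
smoothed curve flattens (the narrow band's output plateaus at running, so
its fitted curve can crest; the physiologically meaningful cut-point is the
first attainment).

A threshold above the fitted MET range is reported as unattainable rather
than extrapolated: the calibration splines flatten past the highest stage
demand and are not credible beyond it.

## The synthetic study conditions

The generator encodes the structure the analysis depends on; its defaults
are fixed study conditions, not tuning knobs.

- *Gait*: harmonics of the step frequency with 1/k amplitude rolloff,
  capped at 14 Hz — ~95% of power below 10 Hz, plus the small foot-strike
  tail above it (which is why the high-pass variant captures slightly more
  than the 10 Hz band). First-harmonic amplitude 0.06 g per km/h; axis
  power split 0.6/0.25/0.15 (vertical/AP/ML); white sensor noise 0.01 g.
- *Stride sway*: a component at half the step frequency (lateral sway and
  trunk rotation cycle once per two steps) at 0.35 of the first harmonic,
  on the horizontal axes, whose amplitude grows at half slope beyond the
  6 km/h walk-run transition. This component is the dominant in-band
  content of the narrow filter at running speeds, and its saturation is
  what makes narrow-band output plateau (while remaining weakly monotone)
  as speed rises — the mechanism behind the compressed vigorous-intensity
  cut-points of the original chain.
- *Step frequency*: adults 1.0 + 0.16·v Hz (≈108 steps/min at 5 km/h,
  ≈175 at 12 km/h), capped at 4 Hz; children 15% higher.
- *Energy expenditure*: MET(v) = 1 + s·0.25·v^1.55 with s = 1 for adults
  (≈9.9 METs at 10 km/h) and s = 0.88 for children — children's higher RMR
  makes their MET value at a given speed lower. Adult resting VO₂ 0.28
  L/min, children 0.22. VO₂ follows stage demands through first-order
  kinetics (τ = 30 s) with 0.03 L/min breath noise.
- *Free-living wear*: days tile non-wear nights (idle device flag — non-wear
  is a device status, never inferred from signal content), rest, and walking
  (2.5–6.5 km/h) and running (7–11.5 km/h) bouts. Locomotion carries
  per-bout step-frequency jitter (lognormal, sdlog 0.08) and a slow AR(1)
  lognormal amplitude envelope (sdlog 0.25) emulating stride-to-stride and
  bout-level variability. An optional high-frequency contaminant (vehicle
  vibration above 10 Hz) is available but defaults to zero amplitude, since
  no quantitative noise model is established.

What the generator does *not* emulate: biomechanically realistic gait
(impacts, soft-tissue artifact, posture transitions), non-locomotor
activities (cycling, load carrying), device calibration error, or
autocorrelated sensor noise. Passing tests therefore demonstrate that the
*processing chain* behaves as specified on signals with gait-like spectral
structure — not that the synthetic cut-point values transfer to real
cohorts.

## Protocols and identifiability

The default protocol is the conventional one (3, 4, 5, 6, 8, 10 km/h; 4-min
stages). Under the synthetic MET curves, children do not reach 9 METs within
it — mirroring the real difficulty that few subjects reach the highest
demands, where fitted splines plateau. Analyses that require every threshold
to be identifiable (cut-point recovery, the cut-point ordering audit)
therefore use the package's *extended* protocol (1–12 km/h), which straddles
all thresholds for both age groups. A cut-point can only be recovered where
stage data pin the curve down on both sides of it.

Two further recovery caveats are structural, and documented rather than
papered over:

- At 1.5 METs the curve sits in the anchored boundary region, where the
  spline's boundary conditions and the anchor dominate; for the original
  chain the dead-band additionally zeroes most of the signal at the
  corresponding very slow speeds, putting a kink in the acceleration–MET
  relation that stage-spaced data cannot resolve. The 1.5-MET cut-point is
  therefore excluded from the strict recovery check.
- The production smoothing (`p = 0.1`) deliberately trades bias for
  smoothness; its bias shrinks as calibration points accumulate but does
  not vanish. The recovery test isolates pipeline correctness by using a
  near-interpolating spline (`p = 0.9`) on noiseless phase-replicate
  subjects, and compares against generator truth measured through the same
  first-attainment envelope. The sensitivity of the 3-MET cut-point to
  doubling `p` is computed and bounded in a regression test, not asserted
  against any external value.

## Free-living rules

- Non-wear: an epoch is non-wear when more than half its samples carry the
  idle flag.
- Valid day: at least 12 h of wear, counted over the whole day (the daily
  window is applied afterwards); the boundary is inclusive.
- Daily window: epochs whose start falls in `[06:00, 23:00)` local time;
  epochs straddling the boundary belong to their start time. Days begin at
  local midnight; timestamps are naive local time.
- Classification: lower-inclusive half-open intervals. Cut-points
  calibrated in counts/min scale linearly to shorter epochs (divide by
  60/epoch); mean-mg cut-points are epoch-length invariant. This linear
  scaling is an assumption, flagged as such — no alternative rule is
  established for sub-minute epochs.
- Agreement: 5×5 row-normalized confusion charts over jointly included
  epochs, original-filter labels as reference rows; empty rows are flagged,
  not fabricated.

## Sub-band decomposition

Four bands: the original 0.29–1.63 Hz chain (reused as-is, so the reference
axis is exactly the original processing output, dead-band included) and
tenth-order Butterworth designs at 1.7–4 Hz, 4–10 Hz, and a high-pass at
10 Hz (at a 30 Hz device rate this spans 10 Hz to Nyquist). The 1.63→1.7 Hz
gap is intentional. Three-second vector-magnitude means per band are
aggregated into 41 bins of the reference output — forty 10-mg bins spanning
0–400 mg plus an open overflow bin — and each band is expressed relative to
the reference per bin. Empty bins are emitted as absent, not zero. Near the
zero bins the reference chain's dead-band drives its own output to ~0 while
the wider bands still see the sensor noise floor, so relative contributions
there are noise-dominated by construction; content comparisons are
meaningful from the light-activity bins upward.

## Problem sizes

The shipped analyses and tests use sizes chosen to exercise every rule at
full fidelity while remaining desk-scale: 10 subjects per age group for
calibration (8 phase-replicates for recovery checks), one simulated week of
free-living wear at 30 Hz for the agreement and sub-band analyses, and
shorter fixtures for unit-level properties. All randomness flows through
explicit integer seeds; identical seeds reproduce outputs bit-identically.

## Known limitations

- The original-chain coefficients are a Butterworth approximation from the
  published half-power points, not the proprietary firmware's exact
  coefficients; bit-exact count replication is out of scope.
- Cut-point values produced from synthetic data are internally consistent
  but are not estimates of any real cohort's cut-points.
- Linear epoch scaling of counts/min cut-points below one minute is a
  convention, not a validated rule.
- The free-living "12 h wear" rule is evaluated against the full day; if a
  study intends wear within the daily window only, the threshold must be
  reinterpreted.
- Binary device formats (gt3x, CWA) are not parsed; the CSV reader defines
  the adapter surface a format-specific reader must satisfy.
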