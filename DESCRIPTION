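Package: accelband
Title: Frequency-Filtered Activity Counts, MET Calibration and Intensity
    Classification for Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how the width of the band-pass frequency
    filter used in accelerometer processing affects physical-activity
    intensity measurement. Implements the ActiGraph-style count chain
    (band-pass filtering, rectification, dead-band, 8-bit quantization,
    epoch aggregation) alongside widened fourth-order Butterworth variants
    (0.29-4 Hz, 0.29-10 Hz, high-pass only), anchored smoothing-spline
    calibration of acceleration output against energy expenditure (METs)
    to derive intensity cut-points, free-living wear-time and valid-day
    screening, epoch-by-epoch classification agreement between filters,
    and decomposition of free-living acceleration into frequency sub-bands
    conditioned on reference intensity. A synthetic-data module emulates
    treadmill calibration protocols and free-living wear so every stage is
    testable without proprietary device data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
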