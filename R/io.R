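#' Write a raw recording to columnar CSV with a YAML sidecar
#'
#' Columns: `timestamp_iso8601` (fractional seconds), `ax_g`, `ay_g`,
#' `az_g`, `status` (`active`/`idle`). A sidecar `<path>.yaml` carries
#' `sample_rate`, `dynamic_range` and `start_time`.
#'
#' @param recording a [raw_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(recording, path) {
  n <- n_samples(recording)
  t <- recording$start_time + (seq_len(n) - 1) / recording$sample_rate
  df <- data.frame(
    timestamp_iso8601 = format(t, "%Y-%m-%dT%H:%M:%OS4"),
    ax_g = recording$samples[, 1], ay_g = recording$samples[, 2],
    az_g = recording$samples[, 3],
    status = ifelse(recording$idle, "idle", "active"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  yaml::write_yaml(
    list(sample_rate = recording$sample_rate,
         dynamic_range = recording$dynamic_range,
         start_time = format(recording$start_time, "%Y-%m-%dT%H:%M:%OS4")),
    paste0(path, ".yaml"))
  invisible(path)
}

#' Read a raw recording from columnar CSV
#'
#' Validates that timestamps are strictly increasing and equally spaced, and
#' that the realized sample rate matches the declared one within 1%; a
#' timestamp gap or reversal is reported with its line number.
#'
#' @param path CSV path written by [write_raw_csv()] (sidecar
#'   `<path>.yaml` read when present; otherwise the rate is inferred from
#'   the timestamps).
#' @return a [raw_recording()].
#' @export
read_raw_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty recording file: ", path)
  need <- c("timestamp_iso8601", "ax_g", "ay_g", "az_g", "status")
  if (!all(need %in% names(df)))
    stop("malformed raw CSV (missing columns): ", path)
  op <- options(digits.secs = 6); on.exit(options(op))
  t <- as.POSIXct(df$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%OS", tz = "UTC")
  if (anyNA(t)) stop("unparseable timestamp at line ", which(is.na(t))[1] + 1L)
  dt <- diff(as.numeric(t))
  if (length(dt)) {
    med <- stats::median(dt)
    bad <- which(dt <= 0 | abs(dt - med) > 0.25 * med)
    if (length(bad))
      stop("timestamp gap or reversal at line ", bad[1] + 2L)
  }
  side <- paste0(path, ".yaml")
  declared <- NULL
  rng <- 6
  if (file.exists(side)) {
    meta <- yaml::read_yaml(side)
    declared <- meta$sample_rate
    if (!is.null(meta$dynamic_range)) rng <- meta$dynamic_range
  }
  realized <- if (length(dt)) 1 / stats::median(dt) else declared
  if (is.null(realized)) stop("cannot determine sample rate of ", path)
  if (!is.null(declared) && abs(realized - declared) / declared > 0.01)
    stop(sprintf("realized sample rate %.3f Hz differs from declared %.3f Hz by more than 1%%",
                 realized, declared))
  rate <- if (!is.null(declared)) declared else realized
  raw_recording(cbind(df$ax_g, df$ay_g, df$az_g), rate, start_time = t[1],
                dynamic_range = rng, idle = df$status == "idle")
}

# 32-bit polynomial rolling hash of a character scalar, as 8 hex digits,
# for provenance headers (stability matters, cryptography does not)
config_hash <- function(s) {
  h <- 17
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2^32
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

provenance_header <- function(seed = NA, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("accelband")),
                  error = function(e) "dev")
  hash <- if (is.null(config)) "none"
  else config_hash(paste(deparse(config), collapse = ""))
  c(sprintf("# accelband %s", ver),
    sprintf("# seed: %s", seed),
    sprintf("# config_hash: %s", hash))
}

#' Write a table as CSV with a provenance comment header
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed seed recorded in the header.
#' @param config configuration object hashed into the header.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path, seed = NA, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_table_csv()]
#' @param path CSV path.
#' @return data frame (provenance comments skipped).
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Validate a pipeline configuration list
#'
#' Checks a configuration (e.g. from [yaml::read_yaml()]) against the known
#' key set; unknown keys are rejected so typos cannot silently disable a
#' rule. Missing keys fall back to package defaults.
#'
#' @param config named list.
#' @param kind `"calibration"` or `"freeliving"`.
#' @return the completed configuration list.
#' @export
validate_config <- function(config, kind = c("calibration", "freeliving")) {
  kind <- match.arg(kind)
  defaults <- if (kind == "calibration") {
    list(seed = 1, n_subjects = 10, age_groups = c("adult", "child"),
         variants = c("ag_original", "bp4hz", "bp10hz", "hp_only"),
         protocol_speeds = c(3, 4, 5, 6, 8, 10), stage_duration_s = 240,
         smoothing = 0.1, noise_sd_g = 0.01, vo2_noise_sd = 0.03,
         sample_rate_hz = 30, truncation_g = 6, subject_sd = 0.08)
  } else {
    list(seed = 1, age_group = "adult", n_days = 7, epoch_length_s = 3,
         variants = c("ag_original", "bp4hz", "bp10hz", "hp_only"),
         min_wear_h = 12, window_start = "06:00", window_end = "23:00",
         noise_sd_g = 0.01, amp_sdlog = 0.25, freq_sdlog = 0.08,
         subbands = TRUE)
  }
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config)
}
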