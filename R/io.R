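# CSV schemas, configuration and round-trip IO. All files are
# comma-separated UTF-8 with '.' decimal separator; timestamps are
# ISO-8601 in a single configured time zone (written with microsecond
# precision, which bounds round-trip error well below sensor resolution).

parse_timestamp <- function(x, tz = "UTC") {
  x <- sub("T", " ", as.character(x), fixed = TRUE)
  out <- as.POSIXct(strptime(x, "%Y-%m-%d %H:%M:%OS", tz = tz))
  miss <- which(is.na(out))
  if (length(miss))  # date-only stamps; anything else stays NA
    out[miss] <- as.POSIXct(strptime(x[miss], "%Y-%m-%d", tz = tz))
  out
}

format_timestamp <- function(x) format(x, "%Y-%m-%dT%H:%M:%OS6")

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " file is missing required column(s): ",
         paste(miss, collapse = ", "))
}

#' Read a detection-event CSV
#'
#' Expects columns `timestamp` (ISO-8601), `pig_id`, `receiver_id`,
#' `rssi_dbm`. Rows with unparseable timestamps or non-numeric RSSI are
#' skipped with a warning (the count is attached as attribute
#' `"n_malformed"`); a missing column is a hard failure naming the
#' column. Events are sorted per pig by timestamp.
#'
#' @param path CSV file path.
#' @param tz Time zone of the timestamps.
#' @return A data.frame of detection events.
#' @export
read_detections <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "pig_id", "receiver_id", "rssi_dbm"),
                "detections")
  ts <- parse_timestamp(df$timestamp, tz)
  rssi <- suppressWarnings(as.numeric(df$rssi_dbm))
  bad <- is.na(ts) | is.na(rssi)
  if (any(bad))
    warning(sum(bad), " malformed detection row(s) skipped")
  out <- data.frame(timestamp = ts[!bad],
                    pig_id = as.character(df$pig_id)[!bad],
                    receiver_id = as.character(df$receiver_id)[!bad],
                    rssi_dbm = rssi[!bad])
  out <- out[order(out$pig_id, out$timestamp, method = "radix"), ]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(bad)
  out
}

#' @rdname read_detections
#' @param events Detection events to write.
#' @export
write_detections <- function(events, path) {
  out <- events
  out$timestamp <- format_timestamp(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write calibration records
#'
#' Schema: `distance_m`, `rssi_dbm`.
#' @param path CSV file path.
#' @return A data.frame of calibration records.
#' @export
read_calibration <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("distance_m", "rssi_dbm"), "calibration")
  df
}

#' Read / write environmental sensor records
#'
#' Schema: `timestamp`, `temp_c`, `rh_pct`, `pm1`, `pm25`, `pm10`.
#' @param path CSV file path.
#' @param tz Time zone of the timestamps.
#' @return A data.frame of environmental records.
#' @export
read_env <- function(path, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("timestamp", "temp_c", "rh_pct", "pm1", "pm25",
                      "pm10"), "environment")
  ts <- parse_timestamp(df$timestamp, tz)
  bad <- is.na(ts)
  if (any(bad)) warning(sum(bad), " malformed environment row(s) skipped")
  df <- df[!bad, ]
  df$timestamp <- ts[!bad]
  rownames(df) <- NULL
  df
}

#' @rdname read_env
#' @param records Environmental records to write.
#' @export
write_env <- function(records, path) {
  out <- records
  out$timestamp <- format_timestamp(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an hourly movement table
#'
#' Schema: `pig_id`, `day`, `hour`, `dist_cm_per_h`, `n_detections`,
#' `valid`. Movement is serialized at 1 decimal place (cm/h, the
#' reporting precision of the metric).
#'
#' @param path CSV file path.
#' @return A data.frame with the hourly schema.
#' @export
read_hourly <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("pig_id", "day", "hour", "dist_cm_per_h", "valid"),
                "hourly movement")
  df$valid <- as.logical(df$valid)
  if (!"n_detections" %in% names(df)) df$n_detections <- NA_integer_
  df
}

#' @rdname read_hourly
#' @param hourly Hourly movement table to write.
#' @export
write_hourly <- function(hourly, path) {
  out <- hourly
  if (!"n_detections" %in% names(out)) out$n_detections <- NA_integer_
  out$dist_cm_per_h <- round(out$dist_cm_per_h, 1)
  out <- out[c("pig_id", "day", "hour", "dist_cm_per_h", "n_detections",
               "valid")]
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' A single configuration object drives every stage of [run_pipeline()]
#' (and the command-line interface): the study window, generator truths,
#' sensor noise/dropout, and analysis switches. Every stochastic stage
#' has its own recorded seed, so a config fully determines all outputs.
#' Configs round-trip losslessly through YAML ([read_config()] /
#' [write_config()]).
#'
#' @param ... Named overrides of the defaults (unknown names are an
#'   error). Nested lists (`truth`, `env`, `sensor`, `analysis`) are
#'   merged element-wise.
#' @return An object of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(n_pigs = 4, n_days = 2, seed = 7)
#' cfg$n_pigs
pipeline_config <- function(...) {
  cfg <- list(
    study_start = "2023-02-02", tz = "UTC",
    n_pigs = 8L, n_days = 5L, seed = 1L,
    event_level = TRUE, missing_prob = 0.05,
    truth = list(sigma2_pig = 15773, sigma2_res = 38884, rho = 0.19,
                 day_sd = 40, interaction_amplitude = 40,
                 peak = 1025.5, trough = 666.0, seed = 101L),
    sensor = list(tx_power = -45, n = 1.8, rssi_noise_sd = 2,
                  dropout_prob = 0.7, step_interval = c(3, 5),
                  distance_floor = 0.1, n_calibration = 50L),
    env = list(pm_cross_correlation = 0.98,
               records_per_day = c(80L, 97L), seed = 202L),
    analysis = list(ci_level = 0.95, r_threshold = 0.95, n_starts = 3L))
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad))
    stop("unknown configuration field(s): ", paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
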