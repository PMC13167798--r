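# From detection events to the hourly movement response.

#' Total incremental distance of an ordered distance sequence
#'
#' Sums the absolute change between consecutive distance estimates:
#' \eqn{\sum_k |d_{k+1} - d_k|}. A pig whose estimated range goes
#' 4 m -> 2 m -> 5 m has moved 5 m over that sequence. Sequences of length
#' 0 or 1 yield 0.
#'
#' @param distances Numeric vector of time-ordered distance estimates (m).
#' @return Total movement (same unit as input).
#' @export
#' @examples
#' total_incremental_distance(c(4, 2, 5))  # 5
total_incremental_distance <- function(distances) {
  distances <- as.numeric(distances)
  if (length(distances) <= 1) return(0)
  sum(abs(diff(distances)))
}

#' Aggregate detection events to hourly movement
#'
#' Converts each event's RSSI to a distance estimate through the
#' calibrated path-loss model, computes per-pig incremental distances
#' between consecutive detections, and sums them within clock hours to
#' give hourly distance moved, reported in cm per hour. Each increment is
#' credited to the hour (and day) containing the *later* of the two
#' detections, so every increment is counted exactly once and increments
#' crossing hour or midnight boundaries are retained. An hour is valid iff
#' at least one detection falls in it; invalid hours carry no movement
#' value. The output covers the complete pig x day x hour grid.
#'
#' Events stamped with a receiver other than `receiver` are dropped with a
#' warning (a single-receiver deployment is assumed; no fusion rule is
#' applied), as are events before day 1 or after day `n_days`.
#'
#' @param events Data.frame of detection events: `timestamp` (POSIXct),
#'   `pig_id`, `receiver_id`, `rssi_dbm`.
#' @param model A [path_loss_model()].
#' @param study_start `Date` defining day 1.
#' @param n_days Number of study days in the grid.
#' @param tz Time zone in which days and hours are reckoned.
#' @param receiver Receiver to keep; default the most frequent
#'   `receiver_id` in `events`.
#' @return A data.frame (`pig_id`, `day`, `hour`, `dist_cm_per_h`,
#'   `n_detections`, `valid`) over the full grid for the pigs present,
#'   ordered by pig, day, hour.
#' @export
aggregate_hourly <- function(events, model, study_start, n_days = 20,
                             tz = "UTC", receiver = NULL) {
  need <- c("timestamp", "pig_id", "receiver_id", "rssi_dbm")
  miss <- setdiff(need, names(events))
  if (length(miss))
    stop("events are missing required column(s): ",
         paste(miss, collapse = ", "))
  model <- as_path_loss_model(model)
  if (is.null(receiver)) {
    tab <- table(events$receiver_id)
    receiver <- names(tab)[which.max(tab)]
  }
  foreign <- events$receiver_id != receiver
  if (any(foreign)) {
    warning(sum(foreign), " event(s) from other receiver(s) dropped ",
            "(single-receiver aggregation, keeping '", receiver, "')")
    events <- events[!foreign, , drop = FALSE]
  }
  t0 <- as.POSIXct(study_start, tz = tz)
  el <- as.numeric(events$timestamp) - as.numeric(t0)
  day <- floor(el / 86400) + 1L
  hour <- floor((el %% 86400) / 3600)
  in_window <- day >= 1L & day <= n_days
  if (any(!in_window))
    warning(sum(!in_window), " event(s) outside days 1..", n_days,
            " dropped")
  events <- events[in_window, , drop = FALSE]
  day <- day[in_window]; hour <- hour[in_window]
  pigs <- sort(unique(as.character(events$pig_id)))
  grid <- expand.grid(hour = 0:23, day = seq_len(n_days),
                      pig = seq_along(pigs))
  grid <- grid[order(grid$pig, grid$day, grid$hour), ]
  cell_of <- function(p, d, h) ((p - 1L) * n_days + (d - 1L)) * 24L + h + 1L
  n_cells <- length(pigs) * n_days * 24L
  dist_cm <- numeric(n_cells)
  n_det <- integer(n_cells)
  if (nrow(events)) {
    ord <- order(match(events$pig_id, pigs), events$timestamp,
                 method = "radix")  # stable: ingestion order breaks ties
    pig_i <- match(events$pig_id, pigs)[ord]
    day <- day[ord]; hour <- hour[ord]
    d_est <- distance_from_rssi(events$rssi_dbm[ord], model)
    cell <- cell_of(pig_i, day, hour)
    cnt <- tabulate(cell, nbins = n_cells)
    n_det <- cnt
    same_prev <- c(FALSE, pig_i[-1] == pig_i[-length(pig_i)])
    inc <- c(0, abs(diff(d_est))) * 100  # m -> cm
    inc[!same_prev] <- 0                 # first detection of each pig
    sums <- rowsum(inc, group = cell)
    dist_cm[as.integer(rownames(sums))] <- sums[, 1]
  }
  valid <- n_det >= 1L
  out <- data.frame(pig_id = pigs[grid$pig], day = grid$day,
                    hour = grid$hour,
                    dist_cm_per_h = ifelse(valid, dist_cm, NA_real_),
                    n_detections = n_det, valid = valid)
  rownames(out) <- NULL
  out
}

#' Extract the analysis-ready rows of an hourly movement table
#'
#' Keeps only valid hours (hours with at least one detection, or
#' non-missing simulated cells) — hours without valid positioning data
#' reflect lack of information, not inactivity, and are excluded from
#' inference. Per-pig retained row counts are attached as attribute
#' `"pig_coverage"`.
#'
#' @param hourly An hourly movement table from [aggregate_hourly()] or
#'   [simulate_hourly()].
#' @return The valid rows, with a `"pig_coverage"` attribute (named
#'   integer vector).
#' @export
analysis_table <- function(hourly) {
  stopifnot(all(c("pig_id", "day", "hour", "dist_cm_per_h", "valid")
                %in% names(hourly)))
  keep <- hourly$valid & !is.na(hourly$dist_cm_per_h)
  out <- hourly[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (!nrow(out)) warning("no valid hourly observations remain")
  cov <- table(factor(out$pig_id, levels = sort(unique(hourly$pig_id))))
  attr(out, "pig_coverage") <- setNames(as.integer(cov), names(cov))
  out
}
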