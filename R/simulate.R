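# Synthetic barn/sensor data generators. These are first-class, tested
# components: they define the study conditions under which the estimation
# machinery is validated, since event-level farm data of this kind are not
# generally shareable.

maybe_seed <- function(seed, expr) {
  if (is.null(seed)) expr else with_seed(seed, expr)
}

# Fold an unconstrained 1-D walk into [0, L] (reflecting boundaries).
# For symmetric steps this is exactly the reflected walk.
reflect_into <- function(x, L) {
  m <- x %% (2 * L)
  ifelse(m > L, 2 * L - m, m)
}

#' Simulate one pig-day trajectory along the pen's long axis
#'
#' Generates a one-dimensional reflected random walk over a single day.
#' Detection-like sampling times are drawn with uniform 3-5 s spacing (the
#' typical inter-detection cadence of passive RFID ear tags near a reader),
#' and the Gaussian step scale varies by clock hour so that the expected
#' total displacement in hour h is proportional to the diurnal profile
#' value for h times `pig_baseline`.
#'
#' @param pig_baseline Non-negative activity multiplier for this pig
#'   (1 = an average pig; 0 = a motionless pig).
#' @param truth A [generative_truth()]; only the diurnal profile is used.
#' @param geometry A [barn_geometry()].
#' @param day Study day (1-based); sets the calendar date of timestamps.
#' @param step_interval Length-2 positive range (s) of inter-sample gaps.
#' @param study_start `Date` of day 1.
#' @param tz Time zone for timestamps.
#' @param seed Optional integer seed (same seed, same trajectory).
#' @return A data.frame with `timestamp` (POSIXct) and `position` (m,
#'   within `[0, pen_length]`).
#' @export
#' @examples
#' tr <- simulate_trajectory(1, generative_truth(), barn_geometry(),
#'                           day = 1, seed = 1)
#' range(tr$position)
simulate_trajectory <- function(pig_baseline, truth, geometry, day,
                                step_interval = c(3, 5),
                                study_start = as.Date("2023-02-02"),
                                tz = "UTC", seed = NULL) {
  stopifnot(inherits(truth, "generative_truth"),
            inherits(geometry, "barn_geometry"),
            pig_baseline >= 0, length(day) == 1, day >= 1)
  if (length(step_interval) != 2 || any(step_interval <= 0) ||
      step_interval[1] > step_interval[2])
    stop("step_interval must be a positive increasing range (s)")
  maybe_seed(seed, {
    n_max <- ceiling(86400 / step_interval[1]) + 1L
    gaps <- runif(n_max, step_interval[1], step_interval[2])
    t_s <- cumsum(gaps)
    t_s <- t_s[t_s < 86400]
    n <- length(t_s)
    hour <- floor(t_s / 3600)
    # calibrate the per-step SD so E[sum |step|] over an hour matches the
    # profile: E|N(0,s^2)| = s*sqrt(2/pi), ~3600/mean(gap) steps per hour
    steps_per_h <- 3600 / mean(step_interval)
    target_m <- pig_baseline * as.numeric(truth$diurnal)[hour + 1L] / 100
    s_h <- (target_m / steps_per_h) / sqrt(2 / pi)
    x0 <- runif(1, 0, geometry$pen_length)
    steps <- rnorm(n, 0, 1) * s_h
    pos <- reflect_into(x0 + cumsum(steps), geometry$pen_length)
    day0 <- as.POSIXct(study_start, tz = tz) + (day - 1) * 86400
    data.frame(timestamp = day0 + t_s, position = pos)
  })
}

#' Simulate RFID detections from a trajectory
#'
#' Converts positions into received-signal-strength readings through the
#' inverse log-distance path-loss model
#' \eqn{RSSI = TxPower - 10\,n\,\log_{10}(d)} plus Gaussian noise, with
#' independent per-detection dropout. The tag-receiver distance is floored
#' at `distance_floor` (physical tag-antenna separation never reaches 0).
#'
#' @param trajectory Output of [simulate_trajectory()].
#' @param model A [path_loss_model()] (or [fit_path_loss()] result).
#' @param geometry A [barn_geometry()].
#' @param rssi_noise_sd Gaussian RSSI noise SD (dBm), `>= 0`.
#' @param dropout_prob Probability a position produces no logged
#'   detection, in `[0, 1)`.
#' @param pig_id,receiver_id Identifiers stamped on the events.
#' @param distance_floor Minimum distance (m) used in the path-loss
#'   formula.
#' @param seed Optional integer seed.
#' @return A data.frame of detection events: `timestamp`, `pig_id`,
#'   `receiver_id`, `rssi_dbm`, time-ordered.
#' @export
simulate_detections <- function(trajectory, model, geometry,
                                rssi_noise_sd = 2, dropout_prob = 0,
                                pig_id = "pig01", receiver_id = "R1",
                                distance_floor = 0.1, seed = NULL) {
  stopifnot(inherits(geometry, "barn_geometry"),
            rssi_noise_sd >= 0, distance_floor > 0)
  if (dropout_prob < 0 || dropout_prob >= 1)
    stop("dropout_prob must lie in [0, 1)")
  model <- as_path_loss_model(model)
  maybe_seed(seed, {
    d <- pmax(abs(trajectory$position - geometry$receiver_position),
              distance_floor)
    n <- length(d)
    rssi <- model$tx_power - 10 * model$n * log10(d) +
      (if (rssi_noise_sd > 0) rnorm(n, 0, rssi_noise_sd) else 0)
    keep <- if (dropout_prob > 0) runif(n) > dropout_prob else rep(TRUE, n)
    out <- data.frame(timestamp = trajectory$timestamp[keep],
                      pig_id = pig_id, receiver_id = receiver_id,
                      rssi_dbm = rssi[keep])
    out[order(out$timestamp), , drop = FALSE]
  })
}

#' Simulate the hourly movement table directly from the model equation
#'
#' Draws a pig x day x hour table from
#' \eqn{y_{idh} = \mu + Day_d + Hour_h + (Day\times Hour)_{dh} + b_i +
#' \varepsilon_{idh}} with \eqn{b_i \sim N(0, \sigma^2_{pig})} and, within
#' each pig-day, a stationary AR(1) residual sequence over the 24 hours
#' with marginal variance \eqn{\sigma^2_{res}} and lag-1 correlation
#' \eqn{\rho}. Cells are independently marked invalid with probability
#' `missing_prob` (missing completely at random); invalid rows carry no
#' movement value.
#'
#' Responses are not floored at zero by default: the downstream model is
#' linear-Gaussian and flooring would bias variance-component recovery.
#' Set `floor_at_zero = TRUE` for realism studies.
#'
#' @param truth A [generative_truth()].
#' @param n_pigs Number of pigs (`>= 2`; variance components are
#'   unidentifiable below that).
#' @param n_days Number of days (`<= truth$n_days`).
#' @param missing_prob Per-cell invalidity probability in `[0, 1)`.
#' @param floor_at_zero Floor negative responses at 0 (default `FALSE`).
#' @param seed Optional integer seed.
#' @return A data.frame (`pig_id`, `day`, `hour`, `dist_cm_per_h`,
#'   `valid`), one row per grid cell, ordered by pig, day, hour. The
#'   realised pig intercepts are attached as attribute `"pig_effects"`.
#' @export
#' @examples
#' h <- simulate_hourly(generative_truth(), n_pigs = 16, n_days = 20,
#'                      seed = 1)
#' nrow(h)  # 7680 possible pig x day x hour cells
simulate_hourly <- function(truth, n_pigs = 16, n_days = truth$n_days,
                            missing_prob = 0, floor_at_zero = FALSE,
                            seed = NULL) {
  stopifnot(inherits(truth, "generative_truth"))
  if (n_pigs < 2)
    stop("n_pigs must be >= 2: pig and residual variance are not ",
         "separable from a single animal")
  if (n_days < 1 || n_days > truth$n_days)
    stop("n_days must lie in 1..truth$n_days")
  if (missing_prob < 0 || missing_prob >= 1)
    stop("missing_prob must lie in [0, 1)")
  maybe_seed(seed, {
    pigs <- sprintf("pig%02d", seq_len(n_pigs))
    grid <- expand.grid(hour = 0:23, day = seq_len(n_days),
                        pig = seq_len(n_pigs))
    grid <- grid[order(grid$pig, grid$day, grid$hour), ]
    b <- rnorm(n_pigs, 0, sqrt(truth$sigma2_pig))
    nb <- n_pigs * n_days
    sres <- sqrt(truth$sigma2_res)
    rho <- truth$rho
    z <- matrix(rnorm(24 * nb), nrow = 24, ncol = nb)
    eps <- matrix(0, 24, nb)
    eps[1, ] <- sres * z[1, ]
    if (abs(rho) > 0) {
      innov_sd <- sres * sqrt(1 - rho^2)
      for (k in 2:24) eps[k, ] <- rho * eps[k - 1, ] + innov_sd * z[k, ]
    } else eps[2:24, ] <- sres * z[2:24, ]
    # column order of eps is (pig, day); grid rows are sorted the same way
    mu_h <- as.numeric(truth$diurnal)[grid$hour + 1L]
    y <- mu_h + truth$day_effects[grid$day] +
      truth$interaction[cbind(grid$day, grid$hour + 1L)] +
      b[grid$pig] + as.vector(eps)
    if (floor_at_zero) y <- pmax(y, 0)
    valid <- if (missing_prob > 0) runif(nrow(grid)) > missing_prob
             else rep(TRUE, nrow(grid))
    out <- data.frame(pig_id = pigs[grid$pig], day = grid$day,
                      hour = grid$hour,
                      dist_cm_per_h = ifelse(valid, y, NA_real_),
                      valid = valid)
    rownames(out) <- NULL
    attr(out, "pig_effects") <- setNames(b, pigs)
    out
  })
}

#' Simulate the barn environmental sensor stream
#'
#' Generates temperature, relative humidity and three particulate-matter
#' fractions at a realistic cadence (a per-day record count drawn from
#' `env_truth$records_per_day`). The PM fractions load on a shared latent
#' factor with loading `sqrt(pm_cross_correlation)`, so their pairwise
#' Pearson correlations target the configured value; negative PM draws are
#' truncated at 0 and humidity is clamped to `[0, 100]`.
#'
#' @param env_truth An [env_truth()].
#' @param n_days Number of days to generate.
#' @param study_start `Date` of day 1.
#' @param tz Time zone for timestamps.
#' @param seed Optional integer seed.
#' @return A data.frame: `timestamp`, `temp_c`, `rh_pct`, `pm1`, `pm25`,
#'   `pm10`, time-ordered.
#' @export
simulate_env <- function(env_truth, n_days = 20,
                         study_start = as.Date("2023-02-02"), tz = "UTC",
                         seed = NULL) {
  stopifnot(inherits(env_truth, "env_truth"), n_days >= 1)
  maybe_seed(seed, {
    r <- env_truth$pm_cross_correlation
    pm_means <- env_truth$pm_base_mean * env_truth$pm_ratio
    pm_sds <- env_truth$pm_sd * env_truth$pm_ratio
    day0 <- as.POSIXct(study_start, tz = tz)
    per_day <- lapply(seq_len(n_days), function(d) {
      nrec <- sample(seq(env_truth$records_per_day[1],
                         env_truth$records_per_day[2]), 1L)
      t_s <- sort(runif(nrec, 0, 86400))
      tl <- timeline_of_hour(floor(t_s / 3600))
      # weather: day-level shift + day-by-timeline drift + record noise
      temp_day <- rnorm(1, 0, env_truth$temp_day_sd)
      temp_blk <- rnorm(3, 0, env_truth$temp_block_sd)[tl]
      rh_day <- rnorm(1, 0, env_truth$rh_day_sd)
      rh_blk <- rnorm(3, 0, env_truth$rh_block_sd)[tl]
      f <- rnorm(nrec)
      pm <- sapply(1:3, function(k) {
        pmax(0, pm_means[k] + pm_sds[k] *
               (sqrt(r) * f + sqrt(1 - r) * rnorm(nrec)))
      })
      data.frame(timestamp = day0 + (d - 1) * 86400 + t_s,
                 temp_c = env_truth$temp_mean + temp_day + temp_blk +
                   rnorm(nrec, 0, env_truth$temp_sd),
                 rh_pct = pmin(100, pmax(0, env_truth$rh_mean + rh_day +
                                           rh_blk +
                                           rnorm(nrec, 0,
                                                 env_truth$rh_sd))),
                 pm1 = pm[, 1], pm25 = pm[, 2], pm10 = pm[, 3])
    })
    out <- do.call(rbind, per_day)
    rownames(out) <- NULL
    out
  })
}
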