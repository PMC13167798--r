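# Constructors for the "generative truth" objects that drive the synthetic
# barn/sensor data generator. Defaults emulate a deep-straw finishing pen
# monitored for 20 days: 16 tagged pigs, a diurnal activity rhythm with a
# 01:00 trough and 15:00 peak, pig-level baseline heterogeneity (ICC ~ 0.29)
# and weak hour-to-hour residual autocorrelation (AR(1) ~ 0.19).

#' Barn and receiver geometry
#'
#' Describes the pen the tracked animals live in and where the single RFID
#' receiver is mounted along the pen's long axis. The default is a
#' 14.3 m x 4.8 m deep-straw pen with the receiver at the midpoint of a long
#' wall, covering about 7.15 m in each direction.
#'
#' @param pen_length Pen length along the monitored axis (m).
#' @param pen_width Pen width (m); informational only, the movement model
#'   is one-dimensional along the long axis.
#' @param receiver_position Receiver position along the long axis (m).
#' @param coverage_halfwidth Effective detection range each way (m).
#' @return An object of class `barn_geometry`.
#' @export
#' @examples
#' barn_geometry()
barn_geometry <- function(pen_length = 14.3, pen_width = 4.8,
                          receiver_position = pen_length / 2,
                          coverage_halfwidth = pen_length / 2) {
  stopifnot(pen_length > 0, pen_width > 0, coverage_halfwidth > 0)
  if (receiver_position <= 0 || receiver_position >= pen_length)
    stop("receiver_position must lie strictly inside (0, pen_length)")
  structure(list(pen_length = pen_length, pen_width = pen_width,
                 receiver_position = receiver_position,
                 coverage_halfwidth = coverage_halfwidth),
            class = "barn_geometry")
}

#' Diurnal activity profile
#'
#' The true marginal mean movement (cm per hour) for each of the 24 clock
#' hours. The default is a single-peak cosine
#' \eqn{\mu_h = c_0 + c_1 \cos(2\pi (h - 15)/24)} with the two constants
#' solved so that hour 15 equals `peak` and hour 1 equals `trough` — the
#' afternoon-peak / night-trough rhythm typical of finishing pigs on straw.
#'
#' @param hourly_mean Optional numeric vector of 24 non-negative values
#'   (cm/h), hours 0..23. Overrides the cosine construction.
#' @param peak Peak hourly mean at 15:00 (cm/h).
#' @param trough Trough hourly mean at 01:00 (cm/h).
#' @return An object of class `diurnal_profile`: numeric length 24, named
#'   "0".."23".
#' @export
#' @examples
#' p <- diurnal_profile()
#' p[["15"]]  # peak
#' p[["1"]]   # trough
diurnal_profile <- function(hourly_mean = NULL, peak = 1025.5, trough = 666.0) {
  if (is.null(hourly_mean)) {
    h <- 0:23
    # c0 + c1 = peak (h = 15); c0 + c1*cos(2*pi*(1-15)/24) = trough (h = 1)
    cos1 <- cos(2 * pi * (1 - 15) / 24)
    c1 <- (peak - trough) / (1 - cos1)
    c0 <- peak - c1
    hourly_mean <- c0 + c1 * cos(2 * pi * (h - 15) / 24)
  }
  hourly_mean <- as.numeric(hourly_mean)
  if (length(hourly_mean) != 24L)
    stop("a diurnal profile must have exactly 24 hourly values")
  if (any(hourly_mean < 0)) stop("diurnal profile values must be >= 0")
  structure(setNames(hourly_mean, as.character(0:23)),
            class = "diurnal_profile")
}

# Evaluate an expression with a private RNG stream, restoring the caller's
# .Random.seed afterwards so generators are reproducible without clobbering
# global state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generative truth for the hourly-movement model
#'
#' Bundles every parameter of the data-generating model
#' \deqn{y_{idh} = \mu + Day_d + Hour_h + (Day \times Hour)_{dh} + b_i +
#'   \varepsilon_{idh}}
#' used by [simulate_hourly()] and [simulate_trajectory()]: the diurnal
#' profile (which fixes \eqn{\mu + Hour_h}), day effects, a day-by-hour
#' interaction surface, the pig-intercept variance, the residual variance
#' and the AR(1) lag-1 residual correlation within pig-day.
#'
#' Day effects and the interaction surface are realised once, from `seed`,
#' when the truth object is constructed, and are double-centred so that the
#' hourly marginal truth equals the diurnal profile exactly. Defaults match
#' the variance decomposition reported for deep-straw finishing pigs:
#' pig variance 15,773 (cm/h)^2, residual variance 38,884 (cm/h)^2
#' (ICC 0.29) and AR(1) correlation 0.19.
#'
#' @param n_days Number of study days (day effects realised for 1..n_days).
#' @param diurnal A [diurnal_profile()].
#' @param day_effects Optional numeric vector of day effects (cm/h); centred
#'   internally. If `NULL`, drawn iid Gaussian with SD `day_sd`.
#' @param day_sd SD of random day effects (cm/h).
#' @param interaction_amplitude SD of the day-by-hour interaction cells
#'   (cm/h); 0 gives a purely additive day + hour truth.
#' @param sigma2_pig Variance of the pig random intercept ((cm/h)^2).
#' @param sigma2_res Marginal residual variance ((cm/h)^2).
#' @param rho AR(1) lag-1 correlation of hourly residuals within pig-day.
#' @param seed Integer seed that fixes the realised day effects and
#'   interaction surface.
#' @return An object of class `generative_truth`.
#' @export
#' @examples
#' tr <- generative_truth(seed = 42)
#' tr$sigma2_pig / (tr$sigma2_pig + tr$sigma2_res)  # true ICC ~ 0.29
generative_truth <- function(n_days = 20, diurnal = diurnal_profile(),
                             day_effects = NULL, day_sd = 40,
                             interaction_amplitude = 40,
                             sigma2_pig = 15773, sigma2_res = 38884,
                             rho = 0.19, seed = 1L) {
  stopifnot(n_days >= 1, sigma2_pig >= 0, sigma2_res > 0, abs(rho) < 1,
            day_sd >= 0, interaction_amplitude >= 0)
  diurnal <- diurnal_profile(unclass(diurnal))
  realised <- with_seed(seed, {
    de <- if (is.null(day_effects)) rnorm(n_days, 0, day_sd)
          else as.numeric(day_effects)
    if (length(de) != n_days) stop("day_effects must have length n_days")
    int <- matrix(rnorm(n_days * 24, 0, interaction_amplitude),
                  nrow = n_days, ncol = 24)
    list(de = de, int = int)
  })
  de <- realised$de - mean(realised$de)
  int <- realised$int
  if (interaction_amplitude > 0) {
    # double-centre so marginal means over days reproduce the diurnal
    # profile and marginal means over hours reproduce mu + Day_d
    int <- sweep(int, 1, rowMeans(int))
    int <- sweep(int, 2, colMeans(int))
  } else int[] <- 0
  structure(list(grand_mean = mean(diurnal),
                 day_effects = de,
                 diurnal = diurnal,
                 interaction = int,
                 interaction_amplitude = interaction_amplitude,
                 sigma2_pig = sigma2_pig, sigma2_res = sigma2_res,
                 rho = rho, n_days = n_days, seed = as.integer(seed)),
            class = "generative_truth")
}

#' @export
print.generative_truth <- function(x, ...) {
  cat("Generative truth for hourly movement\n")
  cat(sprintf("  days: %d   grand mean: %.1f cm/h\n", x$n_days, x$grand_mean))
  cat(sprintf("  diurnal trough/peak: %.1f (01:00) / %.1f (15:00) cm/h\n",
              x$diurnal[["1"]], x$diurnal[["15"]]))
  cat(sprintf("  sigma2_pig: %.0f  sigma2_res: %.0f  (ICC %.2f)   rho: %.2f\n",
              x$sigma2_pig, x$sigma2_res,
              x$sigma2_pig / (x$sigma2_pig + x$sigma2_res), x$rho))
  invisible(x)
}

#' Generative truth for the barn-environment sensors
#'
#' Parameters of the synthetic environmental stream produced by
#' [simulate_env()]: temperature, relative humidity and the three
#' particulate-matter fractions (PM1/PM2.5/PM10), recorded a few dozen
#' times per day. The PM fractions share a latent factor so that their
#' pairwise Pearson correlations target `pm_cross_correlation` — emulating
#' the near-collinearity (r = 0.97-0.99) typical of co-located optical dust
#' sensors. Default means/SDs correspond to moderate winter barn
#' conditions (about 16 degrees C, 71% RH, PM2.5 about 10 ug/m3).
#'
#' Temperature and humidity vary at three scales, mirroring real barn
#' climate: a day-level random shift (weather), a day-by-timeline shift
#' (within-day drift) and record-level sensor noise.
#'
#' @param temp_mean,temp_sd Temperature mean and record-level SD
#'   (degrees C).
#' @param temp_day_sd,temp_block_sd SD of the day-level and
#'   day-by-timeline temperature shifts (degrees C).
#' @param rh_mean,rh_sd Relative humidity mean and record-level SD (%).
#' @param rh_day_sd,rh_block_sd SD of the day-level and day-by-timeline
#'   humidity shifts (%).
#' @param pm_base_mean PM2.5 mean (ug/m3); PM1 and PM10 means are scaled by
#'   `pm_ratio`.
#' @param pm_sd PM2.5 SD (ug/m3); other fractions scale proportionally.
#' @param pm_ratio Length-3 multipliers (PM1, PM2.5, PM10) applied to
#'   `pm_base_mean` and `pm_sd`.
#' @param pm_cross_correlation Target pairwise Pearson correlation among
#'   the PM fractions, in (0, 1).
#' @param records_per_day Integer range (length 2) of sensor records per
#'   day.
#' @param seed Integer seed recorded with the truth (informational; the
#'   simulator takes its own seed).
#' @return An object of class `env_truth`.
#' @export
env_truth <- function(temp_mean = 16.05, temp_sd = 1.0,
                      temp_day_sd = 1.2, temp_block_sd = 0.8,
                      rh_mean = 71.05, rh_sd = 3.0,
                      rh_day_sd = 3.0, rh_block_sd = 1.5,
                      pm_base_mean = 9.76, pm_sd = 8.9,
                      pm_ratio = c(pm1 = 0.653, pm25 = 1, pm10 = 1.49),
                      pm_cross_correlation = 0.98,
                      records_per_day = c(80L, 97L), seed = 1L) {
  stopifnot(temp_sd >= 0, rh_sd >= 0, pm_sd >= 0, pm_base_mean >= 0,
            length(pm_ratio) == 3, all(pm_ratio > 0),
            length(records_per_day) == 2)
  if (!(pm_cross_correlation > 0 && pm_cross_correlation < 1))
    stop("pm_cross_correlation must lie strictly in (0, 1)")
  records_per_day <- as.integer(records_per_day)
  if (any(records_per_day < 1) || records_per_day[1] > records_per_day[2])
    stop("records_per_day must be an increasing integer range >= 1")
  stopifnot(temp_day_sd >= 0, temp_block_sd >= 0, rh_day_sd >= 0,
            rh_block_sd >= 0)
  structure(list(temp_mean = temp_mean, temp_sd = temp_sd,
                 temp_day_sd = temp_day_sd, temp_block_sd = temp_block_sd,
                 rh_mean = rh_mean, rh_sd = rh_sd,
                 rh_day_sd = rh_day_sd, rh_block_sd = rh_block_sd,
                 pm_base_mean = pm_base_mean, pm_sd = pm_sd,
                 pm_ratio = setNames(as.numeric(pm_ratio),
                                     c("pm1", "pm25", "pm10")),
                 pm_cross_correlation = pm_cross_correlation,
                 records_per_day = records_per_day,
                 seed = as.integer(seed)),
            class = "env_truth")
}
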