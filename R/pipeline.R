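# End-to-end pipeline: simulate (optional) -> calibrate -> movement ->
# movement model -> environmental model -> report.

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

# Descriptive summary of the valid hourly movement values plus
# record-level environmental summaries (mean, SE, min, max).
descriptive_table <- function(valid_mov, env_records) {
  mv <- valid_mov$dist_cm_per_h
  rows <- list(data.frame(
    variable = "hourly_movement_cm_per_h", n = length(mv),
    mean = mean(mv), se = sd(mv) / sqrt(length(mv)),
    min = min(mv), max = max(mv),
    q1 = unname(quantile(mv, 0.25)), q3 = unname(quantile(mv, 0.75))))
  for (v in c("temp_c", "rh_pct", "pm1", "pm25", "pm10")) {
    x <- env_records[[v]]
    rows[[v]] <- data.frame(
      variable = v, n = length(x), mean = mean(x),
      se = sd(x) / sqrt(length(x)), min = min(x), max = max(x),
      q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full movement-analysis pipeline
#'
#' Executes, in order: data simulation (event-level trajectories and
#' detections, or the hourly table directly, depending on
#' `config$event_level`), path-loss calibration, hourly aggregation, the
#' movement mixed model (variance components, LSMeans, Type-3 tests,
#' BLUPs), the environmental screen and model, and a descriptive report.
#' Every output is written to `out_dir` as CSV (plus `report.txt`), and
#' all randomness derives from the seeds recorded in the config, so the
#' same config always reproduces identical files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return (Invisibly) a list with the fitted objects, tables and file
#'   paths.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipeline_config(n_pigs = 4, n_days = 2, event_level = FALSE)
#' res <- run_pipeline(cfg, tempfile("run"))
#' res$fit$vc
#' }
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  study_start <- as.Date(config$study_start)
  paths <- character(0)

  truth <- stage("simulate", generative_truth(
    n_days = config$n_days,
    diurnal = diurnal_profile(peak = config$truth$peak,
                              trough = config$truth$trough),
    day_sd = config$truth$day_sd,
    interaction_amplitude = config$truth$interaction_amplitude,
    sigma2_pig = config$truth$sigma2_pig,
    sigma2_res = config$truth$sigma2_res,
    rho = config$truth$rho, seed = config$truth$seed))
  geometry <- barn_geometry()
  true_plm <- path_loss_model(config$sensor$tx_power, config$sensor$n)

  # calibration records are always generated: the calibrate stage refits
  # the path-loss model from them rather than trusting the truth values
  calib <- stage("simulate", with_seed(config$seed, {
    d <- rep(exp(seq(log(0.3), log(geometry$coverage_halfwidth),
                     length.out = 25)),
             length.out = config$sensor$n_calibration)
    data.frame(distance_m = d,
               rssi_dbm = true_plm$tx_power -
                 10 * true_plm$n * log10(d) +
                 rnorm(length(d), 0, config$sensor$rssi_noise_sd))
  }))
  write.csv(calib, paths["calibration"] <- fp("calibration.csv"),
            row.names = FALSE)

  plm <- stage("calibrate", fit_path_loss(calib))

  if (isTRUE(config$event_level)) {
    detections <- stage("simulate", with_seed(config$seed, {
      base_mult <- pmax(0.05, 1 + rnorm(config$n_pigs,
                                        0, sqrt(truth$sigma2_pig)) /
                          truth$grand_mean)
      evs <- lapply(seq_len(config$n_pigs), function(i) {
        per_day <- lapply(seq_len(config$n_days), function(d) {
          tr <- simulate_trajectory(base_mult[i], truth, geometry, d,
                                    step_interval =
                                      config$sensor$step_interval,
                                    study_start = study_start,
                                    tz = config$tz)
          simulate_detections(tr, true_plm, geometry,
                              rssi_noise_sd = config$sensor$rssi_noise_sd,
                              dropout_prob = config$sensor$dropout_prob,
                              pig_id = sprintf("pig%02d", i),
                              distance_floor =
                                config$sensor$distance_floor)
        })
        do.call(rbind, per_day)
      })
      do.call(rbind, evs)
    }))
    write_detections(detections,
                     paths["detections"] <- fp("detections.csv"))
    hourly <- stage("movement",
                    aggregate_hourly(detections, plm, study_start,
                                     n_days = config$n_days,
                                     tz = config$tz))
  } else {
    hourly <- stage("simulate",
                    simulate_hourly(truth, n_pigs = config$n_pigs,
                                    n_days = config$n_days,
                                    missing_prob = config$missing_prob,
                                    seed = config$seed))
  }
  write_hourly(hourly, paths["hourly"] <- fp("hourly.csv"))

  env <- stage("simulate", simulate_env(
    env_truth(pm_cross_correlation = config$env$pm_cross_correlation,
              records_per_day = config$env$records_per_day),
    n_days = config$n_days, study_start = study_start, tz = config$tz,
    seed = config$env$seed))
  write_env(env, paths["env"] <- fp("env.csv"))

  valid <- analysis_table(hourly)
  fit <- stage("fit-lmm", fit_lmm(valid,
                                  n_starts = config$analysis$n_starts))
  lsm_hour <- lsmeans(fit, "hour", level = config$analysis$ci_level)
  lsm_day <- lsmeans(fit, "day", level = config$analysis$ci_level)
  t3 <- type3_tests(fit)
  bl <- blups(fit, level = config$analysis$ci_level)
  vc_tab <- data.frame(component = c("sigma2_pig", "sigma2_res", "rho",
                                     "icc"),
                       estimate = c(fit$vc$sigma2_pig, fit$vc$sigma2_res,
                                    fit$vc$rho, icc(fit)))
  write.csv(rbind(lsm_hour, lsm_day),
            paths["lsmeans"] <- fp("lsmeans.csv"), row.names = FALSE)
  write.csv(t3, paths["type3"] <- fp("type3.csv"), row.names = FALSE)
  write.csv(bl, paths["blups"] <- fp("blups.csv"), row.names = FALSE)
  write.csv(vc_tab, paths["vc"] <- fp("variance_components.csv"),
            row.names = FALSE)

  env_blocks <- stage("fit-env", aggregate_env(env, study_start,
                                               config$tz))
  screen <- pm_screen(env_blocks,
                      r_threshold = config$analysis$r_threshold)
  mb <- movement_to_blocks(hourly)
  env_fit <- stage("fit-env", fit_env_model(
    mb, env_blocks,
    covariates = c("temp_mean", "rh_mean", screen$retained),
    n_starts = config$analysis$n_starts))
  write.csv(env_blocks, paths["env_blocks"] <- fp("env_blocks.csv"),
            row.names = FALSE)
  write.csv(mb, paths["movement_blocks"] <- fp("movement_blocks.csv"),
            row.names = FALSE)
  write.csv(env_fit$type3, paths["env_type3"] <- fp("env_type3.csv"),
            row.names = FALSE)

  desc <- stage("report", descriptive_table(valid, env))
  write.csv(desc, paths["descriptives"] <- fp("descriptives.csv"),
            row.names = FALSE)
  rpt <- c(
    "Movement pipeline report",
    sprintf("pigs: %d  days: %d  possible pig x day x hour cells: %d",
            config$n_pigs, config$n_days,
            config$n_pigs * config$n_days * 24L),
    sprintf("valid hourly observations analysed: %d", nrow(valid)),
    sprintf("path-loss calibration: TxPower %.2f dBm, n %.3f (SE %.2f dB)",
            plm$tx_power, plm$n, plm$sigma),
    sprintf("variance components: pig %.1f, residual %.1f, rho %.3f, ICC %.3f",
            fit$vc$sigma2_pig, fit$vc$sigma2_res, fit$vc$rho, icc(fit)),
    sprintf("PM screen retained: %s",
            paste(screen$retained, collapse = ", ")),
    "", "Descriptives (movement in cm/h; environment record-level):",
    utils::capture.output(print(format(desc, digits = 4),
                                row.names = FALSE)))
  writeLines(rpt, paths["report"] <- fp("report.txt"))

  invisible(list(config = config, truth = truth, path_loss = plm,
                 hourly = hourly, valid = valid, fit = fit,
                 lsmeans_hour = lsm_hour, lsmeans_day = lsm_day,
                 type3 = t3, blups = bl, env_blocks = env_blocks,
                 pm_screen = screen, movement_blocks = mb,
                 env_fit = env_fit, descriptives = desc, paths = paths))
}
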