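test_that("timeline blocks partition the 24 hours", {
  expect_identical(timeline_of_hour(c(0, 7, 8, 15, 16, 23)),
                   c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_identical(sort(unique(timeline_of_hour(0:23))), 1:3)
  expect_error(timeline_of_hour(24), "0..23")
  expect_error(timeline_of_hour(-1), "0..23")
})

test_that("environmental block means match a brute-force grouping oracle", {
  t0 <- as.POSIXct("2023-02-02 00:00:00", tz = "UTC")
  two <- data.frame(timestamp = t0 + c(3600, 7200),
                    temp_c = c(10, 20), rh_pct = c(60, 70),
                    pm1 = c(1, 2), pm25 = c(2, 3), pm10 = c(3, 4))
  ag <- aggregate_env(two)
  expect_identical(nrow(ag), 1L)
  expect_equal(ag$temp_mean, 15)
  expect_identical(ag$n_records, 2L)

  env <- simulate_env(env_truth(), n_days = 20, seed = 5)
  got <- aggregate_env(env)
  hr <- as.POSIXlt(env$timestamp, tz = "UTC")$hour
  key <- paste(as.integer(as.Date(env$timestamp) -
                            as.Date("2023-02-02")) + 1,
               timeline_of_hour(hr))
  for (v in c("temp_c", "pm25")) {
    want <- tapply(env[[v]], key, mean)
    gk <- paste(got$day, got$timeline)
    col <- if (v == "temp_c") got$temp_mean else got$pm25_mean
    expect_equal(col, as.numeric(want[gk]), tolerance = 1e-12)
  }
  expect_identical(sum(got$n_records), nrow(env))
})

test_that("the PM screen keeps only PM2.5 under collinearity", {
  base <- data.frame(pm1_mean = c(1, 2, 3, 4), pm25_mean = c(1, 2, 3, 4),
                     pm10_mean = c(1, 2, 3, 4))
  expect_identical(pm_screen(base)$retained, "pm25_mean")
  set.seed(2)
  indep <- data.frame(pm1_mean = rnorm(50), pm25_mean = rnorm(50),
                      pm10_mean = rnorm(50))
  expect_identical(pm_screen(indep)$retained,
                   c("pm1_mean", "pm25_mean", "pm10_mean"))
  env <- aggregate_env(simulate_env(env_truth(), n_days = 20, seed = 7))
  sc <- pm_screen(env)
  expect_identical(sc$retained, "pm25_mean")
  expect_true(all(sc$correlations[upper.tri(sc$correlations)] >= 0.95))
  # idempotence: screening the retained set returns it unchanged
  expect_identical(pm_screen(env[c("day", "timeline", sc$retained)])$retained,
                   sc$retained)
  flat <- transform(indep, pm10_mean = 1)
  expect_warning(sc2 <- pm_screen(flat), "zero-variance")
  expect_identical(sc2$flagged, "pm10_mean")
})

test_that("movement blocks average valid hours and conserve the partition", {
  hb <- data.frame(pig_id = "p1", day = 1, hour = 0:7,
                   dist_cm_per_h = 800, valid = TRUE)
  mb <- movement_to_blocks(hb)
  expect_equal(mb$dist_mean, 800)
  expect_identical(mb$n_hours, 8L)
  h3 <- data.frame(pig_id = "p1", day = 1, hour = c(8, 9, 10),
                   dist_cm_per_h = c(600, 700, 800), valid = TRUE)
  mb3 <- movement_to_blocks(h3)
  expect_equal(mb3$dist_mean, 700)
  expect_identical(mb3$n_hours, 3L)

  h <- simulate_hourly(generative_truth(n_days = 4, seed = 3), n_pigs = 4,
                       n_days = 4, missing_prob = 0.25, seed = 3)
  mb <- movement_to_blocks(h)
  at <- analysis_table(h)
  key <- paste(at$pig_id, at$day, timeline_of_hour(at$hour))
  want <- tapply(at$dist_cm_per_h, key, mean)
  expect_equal(mb$dist_mean,
               as.numeric(want[paste(mb$pig_id, mb$day, mb$timeline)]),
               tolerance = 1e-12)
  # every valid hour lands in exactly one block
  agg <- tapply(mb$n_hours, paste(mb$pig_id, mb$day), sum)
  cnt <- table(paste(at$pig_id, at$day))
  expect_equal(as.numeric(agg[names(cnt)]), as.numeric(cnt))
  expect_true(all(mb$n_hours >= 1 & mb$n_hours <= 8))
})

env_fixture <- function(seed, n_pigs = 6, n_days = 8, slope = 0) {
  h <- simulate_hourly(generative_truth(n_days = n_days, seed = seed),
                       n_pigs = n_pigs, n_days = n_days,
                       missing_prob = 0.1, seed = seed)
  mb <- movement_to_blocks(h)
  env <- aggregate_env(simulate_env(env_truth(), n_days = n_days,
                                    seed = seed + 1000))
  if (slope != 0) {
    key <- paste(mb$day, mb$timeline)
    ek <- paste(env$day, env$timeline)
    mb$dist_mean <- mb$dist_mean +
      slope * (env$temp_mean[match(key, ek)] - mean(env$temp_mean))
  }
  list(mb = mb, env = env)
}

test_that("uniform weights reproduce the unweighted fit and scaling is moot", {
  fx <- env_fixture(21)
  mb_eq <- fx$mb; mb_eq$n_hours <- 8L
  f1 <- fit_env_model(mb_eq, fx$env)
  mb_one <- fx$mb; mb_one$n_hours <- 1L
  f2 <- fit_env_model(mb_one, fx$env)
  expect_equal(f1$beta, f2$beta, tolerance = 1e-5)
  expect_equal(f1$type3$F, f2$type3$F, tolerance = 1e-3)
  mb_scaled <- fx$mb; mb_scaled$n_hours <- fx$mb$n_hours * 5
  f3 <- fit_env_model(fx$mb, fx$env)
  f4 <- fit_env_model(mb_scaled, fx$env)
  expect_equal(f3$beta, f4$beta, tolerance = 1e-5)
  expect_equal(f3$type3$F, f4$type3$F, tolerance = 1e-3)
})

test_that("a planted temperature slope is recovered", {
  # day-level temperature variation is absorbed by the Day factor, so the
  # slope is identified from day-by-timeline drift; a strong slope keeps
  # the single-fit check well-powered (unbiasedness over replicates is
  # asserted separately at the paper's scale)
  fx <- env_fixture(22, slope = 60, n_days = 12)
  fit <- fit_env_model(fx$mb, fx$env)
  b <- fit$beta[["temp_mean"]]
  se <- sqrt(fit$beta_cov[names(fit$beta) == "temp_mean",
                          names(fit$beta) == "temp_mean"])
  expect_lt(abs(b - 60), 3 * se)
  expect_lt(fit$type3$p[fit$type3$effect == "temp_mean"], 0.05)
})

test_that("temporal structure dominates null covariates, as in barn data", {
  fx <- env_fixture(23)
  fit <- fit_env_model(fx$mb, fx$env)
  t3 <- fit$type3
  expect_lt(t3$p[t3$effect == "timeline"], 1e-4)
  expect_gt(min(t3$p[t3$effect %in% c("temp_mean", "rh_pct", "pm25_mean")],
                na.rm = TRUE), 1e-4)
  expect_identical(t3$num_df[t3$effect == "timeline"], 2L)
})

test_that("degenerate environmental inputs are flagged", {
  fx <- env_fixture(24)
  envc <- fx$env; envc$temp_mean <- 16
  expect_warning(fit <- fit_env_model(fx$mb, envc), "constant across")
  expect_false("temp_mean" %in% fit$type3$effect)
  expect_error(fit_env_model(fx$mb, fx$env, covariates = "nope"),
               "absent")
})
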