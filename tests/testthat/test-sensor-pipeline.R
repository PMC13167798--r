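test_that("path-loss calibration: exact cases and least-squares oracle", {
  two <- fit_path_loss(data.frame(distance_m = c(1, 10),
                                  rssi_dbm = c(-50, -70)))
  expect_equal(two$tx_power, -50, tolerance = 1e-12)
  expect_equal(two$n, 2, tolerance = 1e-12)

  d <- c(1, 2, 4, 8)
  clean <- data.frame(distance_m = d,
                      rssi_dbm = -45 - 10 * 1.8 * log10(d))
  exact <- fit_path_loss(clean)
  expect_equal(exact$tx_power, -45, tolerance = 1e-10)
  expect_equal(exact$n, 1.8, tolerance = 1e-10)

  set.seed(42)
  dd <- runif(50, 0.5, 12)
  noisy <- data.frame(distance_m = dd,
                      rssi_dbm = -48 - 10 * 2.1 * log10(dd) + rnorm(50, 0, 3))
  fit <- fit_path_loss(noisy)
  # independent normal-equations solve on the (1, -10 log10 d) design
  A <- cbind(1, -10 * log10(dd))
  coefs <- solve(t(A) %*% A, t(A) %*% noisy$rssi_dbm)
  expect_equal(fit$tx_power, coefs[1], tolerance = 1e-8)
  expect_equal(fit$n, coefs[2], tolerance = 1e-8)
  expect_true(is.finite(fit$sigma) && fit$sigma > 0)

  expect_error(fit_path_loss(data.frame(distance_m = c(3, 3, 3),
                                        rssi_dbm = c(-60, -61, -59))),
               "distinct")
})

test_that("distance_from_rssi inverts the model and flags implausible ranges", {
  plm <- path_loss_model(-50, 2)
  expect_equal(distance_from_rssi(-50, plm), 1)
  expect_equal(distance_from_rssi(-70, plm), 10)
  rs <- seq(-90, -40, by = 0.5)
  expect_true(all(diff(distance_from_rssi(rs, plm)) < 0))
  expect_warning(d <- distance_from_rssi(c(-50, -95), plm, cap = 20),
                 "plausibility cap")
  expect_equal(as.numeric(d)[2], 10^(45 / 20))  # flagged, not altered
  expect_identical(attr(d, "implausible"), c(FALSE, TRUE))
})

test_that("incremental distance: worked example, degenerate input, loop oracle", {
  expect_identical(total_incremental_distance(c(4, 2, 5)), 5)
  expect_identical(total_incremental_distance(7.3), 0)
  expect_identical(total_incremental_distance(numeric(0)), 0)
  set.seed(1)
  x <- runif(1000, 0, 15)
  acc <- 0
  for (k in 2:1000) acc <- acc + abs(x[k] - x[k - 1])
  expect_equal(total_incremental_distance(x), acc, tolerance = 1e-12)
})

make_events <- function(times, distances, plm, pig = "p1", recv = "R1") {
  data.frame(timestamp = times, pig_id = pig, receiver_id = recv,
             rssi_dbm = plm$tx_power - 10 * plm$n * log10(distances))
}

test_that("hourly aggregation reproduces the 4 m -> 2 m -> 5 m worked example", {
  plm <- path_loss_model(-50, 2)
  t0 <- as.POSIXct("2023-02-02 10:00:00", tz = "UTC")
  ev <- make_events(t0 + c(0, 4, 8), c(4, 2, 5), plm)
  h <- aggregate_hourly(ev, plm, as.Date("2023-02-02"), n_days = 1)
  row10 <- h[h$hour == 10, ]
  expect_equal(row10$dist_cm_per_h, 500, tolerance = 1e-9)  # 5 m -> cm
  expect_identical(row10$n_detections, 3L)
  expect_true(row10$valid)
  # hours with no detections are invalid and carry no value
  expect_true(all(!h$valid[h$hour != 10]))
  expect_true(all(is.na(h$dist_cm_per_h[h$hour != 10])))
  # a stationary pig is valid with zero movement
  ev0 <- make_events(t0 + seq(0, 3600, by = 60), rep(3, 61), plm)
  h0 <- aggregate_hourly(ev0, plm, as.Date("2023-02-02"), n_days = 1)
  expect_equal(h0$dist_cm_per_h[h0$hour == 10], 0, tolerance = 1e-9)
  expect_true(h0$valid[h0$hour == 10])
})

test_that("increments are credited to the later detection across midnight", {
  plm <- path_loss_model(-50, 2)
  t0 <- as.POSIXct("2023-02-02 23:59:58", tz = "UTC")
  ev <- make_events(t0 + c(0, 4), c(2, 6), plm)
  h <- aggregate_hourly(ev, plm, as.Date("2023-02-02"), n_days = 2)
  expect_equal(h$dist_cm_per_h[h$day == 2 & h$hour == 0], 400,
               tolerance = 1e-9)
  expect_equal(h$dist_cm_per_h[h$day == 1 & h$hour == 23], 0,
               tolerance = 1e-9)
})

test_that("foreign receivers and out-of-window events are dropped with warnings", {
  plm <- path_loss_model(-50, 2)
  t0 <- as.POSIXct("2023-02-02 10:00:00", tz = "UTC")
  ev <- make_events(t0 + c(0, 4, 8), c(4, 2, 5), plm)
  ev$receiver_id[2] <- "R2"
  expect_warning(h <- aggregate_hourly(ev, plm, as.Date("2023-02-02"),
                                       n_days = 1),
                 "other receiver")
  expect_identical(h$n_detections[h$hour == 10], 2L)
  ev2 <- make_events(t0 + c(0, 4, 86400 * 3), c(4, 2, 5), plm)
  expect_warning(aggregate_hourly(ev2, plm, as.Date("2023-02-02"),
                                  n_days = 1),
                 "outside days")
  expect_error(aggregate_hourly(ev[, -4], plm, as.Date("2023-02-02")),
               "rssi_dbm")
})

test_that("deleting detections never increases total movement; units commute", {
  plm <- path_loss_model(-50, 2)
  set.seed(7)
  t0 <- as.POSIXct("2023-02-02 00:00:00", tz = "UTC")
  times <- t0 + cumsum(runif(500, 3, 5)) + 6 * 3600
  dists <- runif(500, 0.5, 7)
  ev <- make_events(times, dists, plm)
  h_full <- aggregate_hourly(ev, plm, as.Date("2023-02-02"), n_days = 1)
  for (rep in 1:5) {
    keep <- sort(sample(500, 300))
    h_sub <- aggregate_hourly(ev[keep, ], plm, as.Date("2023-02-02"),
                              n_days = 1)
    expect_lte(sum(h_sub$dist_cm_per_h, na.rm = TRUE),
               sum(h_full$dist_cm_per_h, na.rm = TRUE) + 1e-9)
  }
  # unit coherence: sum in m then convert = convert then sum
  expect_equal(sum(h_full$dist_cm_per_h, na.rm = TRUE),
               100 * total_incremental_distance(dists),
               tolerance = 1e-9 * sum(h_full$dist_cm_per_h, na.rm = TRUE))
})

test_that("analysis_table applies the validity rule and conserves counts", {
  h <- simulate_hourly(generative_truth(seed = 2), n_pigs = 4, n_days = 5,
                       missing_prob = 0.2, seed = 6)
  at <- analysis_table(h)
  expect_identical(nrow(at), nrow(h) - sum(!h$valid))
  expect_identical(sum(attr(at, "pig_coverage")), nrow(at))
  h_none <- h; h_none$valid <- FALSE
  h_none$dist_cm_per_h <- NA_real_
  expect_warning(empty <- analysis_table(h_none), "no valid")
  expect_identical(nrow(empty), 0L)
})
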