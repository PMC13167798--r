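test_that("ICC is the pig share of marginal variance", {
  expect_equal(round(icc(list(sigma2_pig = 15773, sigma2_res = 38884)), 2),
               0.29)
  expect_identical(icc(list(sigma2_pig = 0, sigma2_res = 5)), 0)
  expect_equal(icc(list(sigma2_pig = 5, sigma2_res = 1e-12)), 1,
               tolerance = 1e-9)
  # scale invariance: c^2 on both components cancels
  expect_equal(icc(list(sigma2_pig = 9 * 15773, sigma2_res = 9 * 38884)),
               icc(list(sigma2_pig = 15773, sigma2_res = 38884)))
})

test_that("LSMeans equal arithmetic means on balanced complete data", {
  at <- analysis_table(
    simulate_hourly(generative_truth(n_days = 3, seed = 6), n_pigs = 4,
                    n_days = 3, seed = 6))
  fit <- fit_lmm(at)
  lsm <- lsmeans(fit, "hour")
  arith <- tapply(at$dist_cm_per_h, at$hour, mean)
  expect_equal(lsm$estimate, as.numeric(arith), tolerance = 1e-8)
  lsd <- lsmeans(fit, "day")
  expect_equal(lsd$estimate,
               as.numeric(tapply(at$dist_cm_per_h, at$day, mean)),
               tolerance = 1e-8)
  expect_true(all(lsm$lower < lsm$estimate & lsm$estimate < lsm$upper))
})

test_that("halving the animals inflates every LSMean standard error", {
  h <- simulate_hourly(generative_truth(n_days = 3, seed = 8),
                       n_pigs = 8, n_days = 3, seed = 8)
  at <- analysis_table(h)
  fit_full <- fit_lmm(at)
  at_half <- at[at$pig_id %in% sprintf("pig%02d", 1:4), ]
  fit_half <- fit_lmm(at_half)
  theta <- fit_full$vc
  # compare at common variance components so only the data size changes
  refit <- function(a) {
    des <- build_design(a)
    pc <- strawtrack:::lmm_pieces(des, theta$sigma2_pig / theta$sigma2_res,
                                  theta$rho)
    sqrt(diag(theta$sigma2_res * chol2inv(pc$cholA)))
  }
  expect_true(all(refit(at_half) > refit(at) - 1e-12))
  se_full <- lsmeans(fit_full, "hour")$se
  se_half <- lsmeans(fit_half, "hour")$se
  expect_true(all(se_half > se_full))
})

test_that("LSMeans over missing cells are flagged inestimable, not dropped", {
  h <- simulate_hourly(generative_truth(n_days = 3, seed = 3),
                       n_pigs = 3, n_days = 3, seed = 3)
  at <- analysis_table(h)
  at <- at[!(at$day == 2 & at$hour == 5), ]  # empty one cell
  fit <- fit_lmm(at)
  lsm <- lsmeans(fit, "hour")
  expect_identical(nrow(lsm), 24L)
  expect_false(lsm$estimable[lsm$level == 5])
  expect_true(is.na(lsm$estimate[lsm$level == 5]))
  expect_true(all(lsm$estimable[lsm$level != 5]))
})

test_that("BLUPs equal the dense Henderson-equations oracle", {
  at <- gappy_fixture()
  fit <- fit_lmm(at)
  bl <- blups(fit)
  orc <- oracle_blups(build_design(at), fit$vc)
  expect_equal(bl$deviation, orc$b, tolerance = 1e-6)
  expect_equal(bl$se^2, orc$var, tolerance = 1e-6)
})

test_that("BLUPs shrink fully at sigma2_pig = 0 and respond to data volume", {
  at <- analysis_table(
    simulate_hourly(generative_truth(n_days = 3, seed = 5), n_pigs = 5,
                    n_days = 3, seed = 5))
  fit0 <- fit_lmm(at, fix = list(sigma2_pig = 0))
  expect_equal(blups(fit0)$deviation, rep(0, 5), tolerance = 1e-12)

  # starve one pig of data: wider CI and stronger shrinkage
  keep <- at$pig_id != "pig01" | (at$day == 1 & at$hour < 4)
  fit <- fit_lmm(at[keep, ])
  bl <- blups(fit)
  expect_identical(bl$n_obs_pig[bl$pig_id == "pig01"], 4L)
  expect_true(bl$se[bl$pig_id == "pig01"] > max(bl$se[bl$pig_id != "pig01"]))
  raw_dev <- abs(mean(at$dist_cm_per_h[keep & at$pig_id == "pig01"]) -
                   mean(at$dist_cm_per_h[keep]))
  expect_lt(abs(bl$deviation[bl$pig_id == "pig01"]), raw_dev + 1e-9)
})

test_that("Type-3 F tests match the ANOVA decomposition on balanced data", {
  at <- analysis_table(
    simulate_hourly(generative_truth(n_days = 3, seed = 7), n_pigs = 4,
                    n_days = 3, seed = 7))
  at <- at[at$hour < 4, ]  # compact 3 x 4 grid, 4 replicates per cell
  fit <- fit_lmm(at, fix = list(sigma2_pig = 0, rho = 0))
  t3 <- type3_tests(fit)
  ao <- summary(aov(dist_cm_per_h ~ factor(day) * factor(hour),
                    data = at))[[1]]
  aoF <- setNames(ao[["F value"]], trimws(rownames(ao)))
  expect_equal(t3$F[t3$effect == "day"], aoF[["factor(day)"]],
               tolerance = 1e-6)
  expect_equal(t3$F[t3$effect == "hour"], aoF[["factor(hour)"]],
               tolerance = 1e-6)
  expect_equal(t3$F[t3$effect == "day:hour"],
               aoF[["factor(day):factor(hour)"]],
               tolerance = 1e-6)
  expect_identical(t3$num_df, c(2L, 3L, 6L))
})

test_that("estimable results are invariant to the fixed-effects coding", {
  at <- analysis_table(
    simulate_hourly(generative_truth(n_days = 3, seed = 9), n_pigs = 3,
                    n_days = 3, missing_prob = 0.2, seed = 9))
  at <- at[!(at$day == 1 & at$hour == 3), ]
  fits <- lapply(c("cellmeans", "treatment", "sum"), function(cd)
    fit_lmm(at, coding = cd))
  base_lsm <- lsmeans(fits[[1]], "hour")
  base_t3 <- type3_tests(fits[[1]])
  for (f in fits[-1]) {
    expect_equal(lsmeans(f, "hour")$estimate, base_lsm$estimate,
                 tolerance = 1e-6)
    expect_equal(lsmeans(f, "hour")$se, base_lsm$se, tolerance = 1e-6)
    t3 <- type3_tests(f)
    expect_equal(t3$F, base_t3$F, tolerance = 1e-6)
    expect_identical(t3$num_df, base_t3$num_df)
  }
})

test_that("slice numerator df is the day's observed-hour count minus one", {
  at <- analysis_table(
    simulate_hourly(generative_truth(n_days = 3, seed = 10), n_pigs = 3,
                    n_days = 3, seed = 10))
  at <- at[!(at$day == 2 & at$hour >= 6), ]  # day 2 keeps 6 hours
  fit <- fit_lmm(at)
  st <- slice_tests(fit)
  expect_identical(st$num_df[st$day == 2], 5L)
  expect_identical(st$num_df[st$day == 1], 23L)
  expect_true(all(st$p >= 0 & st$p <= 1))
})

test_that("slice tests hold their size under a flat hourly profile", {
  flat <- generative_truth(n_days = 20,
                           diurnal = diurnal_profile(rep(800, 24)),
                           day_sd = 30, interaction_amplitude = 0,
                           sigma2_pig = 8000, sigma2_res = 30000,
                           rho = 0.2, seed = 12)
  ps <- unlist(lapply(1:3, function(i) {
    at <- analysis_table(simulate_hourly(flat, n_pigs = 8, n_days = 20,
                                         seed = 400 + i))
    slice_tests(fit_lmm(at, n_starts = 1))$p
  }))
  # 60 null slices: rejection rate should sit near the nominal 5%
  expect_lt(mean(ps < 0.05), 0.15)
  expect_gt(min(ps), 1e-4)
})
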