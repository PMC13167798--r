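# Inference on a fitted movement model: least-squares means, Type-3 F
# tests with containment denominator df, per-day slice tests and pig
# BLUPs. Everything is built from estimable functions of the observed
# day-hour cell means, so results do not depend on the fixed-effects
# coding used for fitting.

# Moore-Penrose solve for possibly rank-deficient Wald middle matrices.
mp_solve <- function(M, b, tol = 1e-10) {
  sv <- svd(M)
  pos <- sv$d > tol * max(sv$d, 0)
  sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], b)) / sv$d[pos])
}

wald_F <- function(L, beta, beta_cov, den_df) {
  L <- matrix(L, ncol = length(beta))
  r <- qr(L)$rank
  if (r == 0) return(list(F = NA_real_, num_df = 0L, p = NA_real_))
  Lb <- as.vector(L %*% beta)
  M <- L %*% beta_cov %*% t(L)
  Fstat <- as.numeric(crossprod(Lb, mp_solve(M, Lb))) / r
  list(F = Fstat, num_df = r,
       p = pf(Fstat, r, den_df, lower.tail = FALSE))
}

# Prediction rows for the observed day-hour cells, in the fit's coding.
cell_rows <- function(design) {
  as.matrix(design$X[design$cells$first_row, , drop = FALSE])
}

#' Least-squares means of day, hour or day-by-hour cells
#'
#' Model-based marginal means: each LSMean is the equal-weight average of
#' the day-hour cell means over the levels of the other factor. An LSMean
#' whose average would involve an unobserved cell is not estimable under
#' the interaction model; such levels are flagged, not silently dropped.
#' Standard errors come from the GLS covariance of the fixed effects, and
#' 95% confidence limits use the t distribution at the containment
#' denominator df.
#'
#' @param fit A [fit_lmm()] result.
#' @param effect `"hour"`, `"day"` or `"day_hour"`.
#' @param level Confidence level (default 0.95).
#' @return A data.frame: `effect`, `level` (factor level; for
#'   `"day_hour"`, `day` and `hour` columns), `estimate`, `se`, `df`,
#'   `lower`, `upper`, `estimable`.
#' @export
#' @examples
#' h <- simulate_hourly(generative_truth(), n_pigs = 4, n_days = 2,
#'                      seed = 1)
#' fit <- fit_lmm(analysis_table(h))
#' head(lsmeans(fit, "hour"))
lsmeans <- function(fit, effect = c("hour", "day", "day_hour"),
                    level = 0.95) {
  stopifnot(inherits(fit, "movement_lmm"))
  effect <- match.arg(effect)
  design <- fit$design
  cx <- cell_rows(design)
  cells <- design$cells
  tq <- qt(1 - (1 - level) / 2, fit$den_df)
  one <- function(lev, idx, n_required) {
    if (length(idx) < n_required)
      return(data.frame(level = lev, estimate = NA_real_, se = NA_real_,
                        df = fit$den_df, lower = NA_real_,
                        upper = NA_real_, estimable = FALSE))
    L <- colMeans(cx[idx, , drop = FALSE])
    est <- sum(L * fit$beta)
    se <- sqrt(max(0, as.numeric(t(L) %*% fit$beta_cov %*% L)))
    data.frame(level = lev, estimate = est, se = se, df = fit$den_df,
               lower = est - tq * se, upper = est + tq * se,
               estimable = TRUE)
  }
  out <- switch(effect,
    hour = do.call(rbind, lapply(design$hours, function(h)
      one(h, which(cells$hour == h), length(design$days)))),
    day = do.call(rbind, lapply(design$days, function(d)
      one(d, which(cells$day == d), length(design$hours)))),
    day_hour = {
      grid <- expand.grid(hour = design$hours, day = design$days)
      res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i)
        one(paste0("d", grid$day[i], ":h", grid$hour[i]),
            which(cells$day == grid$day[i] & cells$hour == grid$hour[i]),
            1L)))
      cbind(day = grid$day, hour = grid$hour, res)
    })
  out <- cbind(effect = effect, out)
  rownames(out) <- NULL
  out
}

#' Pig-level BLUPs of the random intercept
#'
#' Conditional modes of each pig's baseline deviation (cm/h) from the
#' fitted day-by-hour means, with 95% intervals from the conditional
#' prediction variance of \eqn{\hat b_i - b_i} (which accounts for
#' fixed-effect uncertainty). Pigs contributing few valid hours shrink
#' towards zero and get wider intervals.
#'
#' @param fit A [fit_lmm()] result.
#' @param level Confidence level.
#' @return A data.frame: `pig_id`, `deviation`, `se`, `lower`, `upper`,
#'   `n_obs_pig`.
#' @export
blups <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "movement_lmm"))
  s2p <- fit$vc$sigma2_pig; s2r <- fit$vc$sigma2_res
  pc <- fit$pieces
  denom <- s2r + s2p * pc$ng
  dev <- s2p * pc$dg / denom
  W <- pc$Mx / denom
  var_beta <- rowSums((W %*% fit$beta_cov) * W)
  v <- pmax(0, s2p - s2p^2 * pc$ng / denom + s2p^2 * var_beta)
  se <- sqrt(v)
  tq <- qt(1 - (1 - level) / 2, fit$den_df)
  out <- data.frame(pig_id = fit$design$pigs, deviation = dev, se = se,
                    lower = dev - tq * se, upper = dev + tq * se,
                    n_obs_pig = unname(fit$group_sizes))
  rownames(out) <- NULL
  out
}

# Re-express the fitted fixed effects in a pivot-reduced sum-to-zero
# coding: gamma = B beta, where mu = X beta = Xs gamma. Used so Type-3
# hypotheses are identical whatever coding the model was fitted in.
sum_coding_map <- function(fit) {
  design <- fit$design
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  mm <- model.matrix(~ fday * fhour,
                     data = data.frame(fday = design$fday,
                                       fhour = design$fhour))
  assign <- attr(mm, "assign")
  cp <- crossprod(mm)
  qr_cp <- qr(cp, tol = 1e-9)
  kept <- sort(qr_cp$pivot[seq_len(qr_cp$rank)])
  Xs <- mm[, kept, drop = FALSE]
  XtX <- crossprod(Xs)
  XtF <- as.matrix(crossprod(Matrix(Xs, sparse = TRUE), design$X))
  B <- solve(XtX, XtF)
  list(B = B, assign = assign[kept])
}

#' Type-3 F tests of the fixed effects
#'
#' Wald F tests of each effect's Type-3 estimable contrast (the effect's
#' coefficients in a full-rank sum-to-zero reparameterisation, adjusted
#' for all other terms), with the containment denominator degrees of
#' freedom: none of the fixed effects contains the pig grouping factor,
#' so all receive the residual containment df
#' `n_obs - rank([X, Z_pig])`. On a balanced complete design with
#' `rho = 0` and `sigma2_pig = 0` these F statistics coincide with the
#' classical two-way ANOVA F tests.
#'
#' @param fit A [fit_lmm()] result.
#' @return A data.frame: `effect`, `num_df`, `den_df`, `F`, `p`.
#' @export
type3_tests <- function(fit) {
  stopifnot(inherits(fit, "movement_lmm"))
  map <- sum_coding_map(fit)
  labels <- c("day", "hour", "day:hour")
  out <- lapply(1:3, function(e) {
    idx <- which(map$assign == e)
    if (!length(idx)) {
      message("effect '", labels[e], "' has no estimable contrast; skipped")
      return(NULL)
    }
    w <- wald_F(map$B[idx, , drop = FALSE], fit$beta, fit$beta_cov,
                fit$den_df)
    data.frame(effect = labels[e], num_df = w$num_df, den_df = fit$den_df,
               F = w$F, p = w$p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Within-day slice tests of the hour effect
#'
#' For each day, an F test of equality of that day's observed hourly cell
#' means (numerator df = observed hours that day minus 1), using the
#' containment denominator df. Days with fewer than two observed hours
#' are skipped with a note.
#'
#' @param fit A [fit_lmm()] result.
#' @return A data.frame: `day`, `num_df`, `den_df`, `F`, `p`.
#' @export
slice_tests <- function(fit) {
  stopifnot(inherits(fit, "movement_lmm"))
  design <- fit$design
  cx <- cell_rows(design)
  cells <- design$cells
  out <- lapply(design$days, function(d) {
    idx <- which(cells$day == d)
    if (length(idx) < 2) {
      message("day ", d, " has < 2 observed hours; slice skipped")
      return(NULL)
    }
    L <- cx[idx[-1], , drop = FALSE] -
      matrix(cx[idx[1], ], nrow = length(idx) - 1,
             ncol = ncol(cx), byrow = TRUE)
    w <- wald_F(L, fit$beta, fit$beta_cov, fit$den_df)
    data.frame(day = d, num_df = w$num_df, den_df = fit$den_df,
               F = w$F, p = w$p)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
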