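# Day x timeline environmental aggregation, the collinearity screen for
# particulate-matter fractions, and the weighted mixed model of movement
# on environmental covariates.

#' Timeline block of a clock hour
#'
#' Maps hours to the three 8-hour timeline blocks used for environmental
#' aggregation: block 1 = 00:00-07:00, block 2 = 08:00-15:00,
#' block 3 = 16:00-23:00.
#'
#' @param hour Integer vector of clock hours in 0..23.
#' @return Integer vector of blocks in 1..3.
#' @export
#' @examples
#' timeline_of_hour(c(0, 8, 23))  # 1 2 3
timeline_of_hour <- function(hour) {
  if (any(is.na(hour)) || any(hour < 0 | hour > 23))
    stop("hour must lie in 0..23")
  as.integer(hour) %/% 8L + 1L
}

#' Aggregate environmental records to day x timeline blocks
#'
#' Arithmetic means of temperature, relative humidity and the PM
#' fractions per day and timeline block, with the contributing record
#' count. Blocks with no records are absent from the output.
#'
#' @param records Data.frame with `timestamp`, `temp_c`, `rh_pct`, `pm1`,
#'   `pm25`, `pm10` (see [simulate_env()] / [read_env()]).
#' @param study_start `Date` defining day 1.
#' @param tz Time zone in which days and hours are reckoned.
#' @return A data.frame: `day`, `timeline`, `temp_mean`, `rh_mean`,
#'   `pm1_mean`, `pm25_mean`, `pm10_mean`, `n_records`.
#' @export
aggregate_env <- function(records, study_start = as.Date("2023-02-02"),
                          tz = "UTC") {
  need <- c("timestamp", "temp_c", "rh_pct", "pm1", "pm25", "pm10")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("environmental records are missing column(s): ",
         paste(miss, collapse = ", "))
  t0 <- as.POSIXct(study_start, tz = tz)
  el <- as.numeric(records$timestamp) - as.numeric(t0)
  day <- floor(el / 86400) + 1
  hour <- floor((el %% 86400) / 3600)
  tl <- timeline_of_hour(hour)
  g <- data.frame(day = day, timeline = tl)
  means <- aggregate(records[c("temp_c", "rh_pct", "pm1", "pm25", "pm10")],
                     by = g, FUN = mean)
  names(means)[3:7] <- c("temp_mean", "rh_mean", "pm1_mean", "pm25_mean",
                         "pm10_mean")
  counts <- aggregate(list(n_records = records$temp_c), by = g,
                      FUN = length)
  out <- merge(means, counts, by = c("day", "timeline"))
  out <- out[order(out$day, out$timeline), ]
  rownames(out) <- NULL
  out
}

#' Screen the particulate-matter fractions for collinearity
#'
#' Computes pairwise Pearson correlations among the PM block means. When
#' every pair exceeds `r_threshold`, the fractions are effectively
#' redundant and only PM2.5 is retained for modelling; otherwise all are
#' kept. Zero-variance columns have undefined correlations and are
#' flagged.
#'
#' @param env_table Output of [aggregate_env()] (any subset of the PM
#'   mean columns is accepted).
#' @param r_threshold Collinearity threshold (default 0.95).
#' @return A list of class `pm_screen`: `retained` (character vector of
#'   kept PM columns), `correlations` (matrix of pairwise r),
#'   `flagged` (zero-variance columns), `r_threshold`.
#' @export
pm_screen <- function(env_table, r_threshold = 0.95) {
  pm_cols <- intersect(c("pm1_mean", "pm25_mean", "pm10_mean"),
                       names(env_table))
  if (length(pm_cols) >= 2 && nrow(env_table) < 3)
    stop("pm_screen needs at least 3 blocks to estimate correlations")
  flagged <- pm_cols[vapply(pm_cols, function(cl)
    sd(env_table[[cl]]) == 0, logical(1))]
  if (length(flagged))
    warning("zero-variance PM column(s): ",
            paste(flagged, collapse = ", "),
            " (correlation undefined)")
  usable <- setdiff(pm_cols, flagged)
  cors <- if (length(usable) >= 2)
    cor(env_table[usable]) else matrix(1, 0, 0)
  all_high <- length(usable) >= 2 &&
    all(cors[upper.tri(cors)] > r_threshold)
  retained <- if (all_high && "pm25_mean" %in% usable) "pm25_mean"
              else pm_cols
  structure(list(retained = retained, correlations = cors,
                 flagged = flagged, r_threshold = r_threshold),
            class = "pm_screen")
}

#' @export
print.pm_screen <- function(x, ...) {
  cat("PM collinearity screen (threshold r >", x$r_threshold, ")\n")
  if (length(x$correlations)) print(round(x$correlations, 3))
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Aggregate hourly movement to pig x day x timeline blocks
#'
#' Mean movement over the valid hours of each pig in each day-timeline
#' block (`dist_mean`, cm/h) together with the number of contributing
#' hours (`n_hours`, the weight of the block in the environmental model).
#' Blocks with no valid hours are absent.
#'
#' @param hourly An hourly movement table ([aggregate_hourly()] or
#'   [simulate_hourly()]).
#' @return A data.frame: `pig_id`, `day`, `timeline`, `dist_mean`,
#'   `n_hours`.
#' @export
movement_to_blocks <- function(hourly) {
  valid <- analysis_table(hourly)
  g <- data.frame(pig_id = valid$pig_id, day = valid$day,
                  timeline = timeline_of_hour(valid$hour))
  means <- aggregate(list(dist_mean = valid$dist_cm_per_h), by = g,
                     FUN = mean)
  counts <- aggregate(list(n_hours = valid$dist_cm_per_h), by = g,
                      FUN = length)
  out <- merge(means, counts, by = c("pig_id", "day", "timeline"))
  out <- out[order(out$pig_id, out$day, out$timeline), ]
  rownames(out) <- NULL
  out
}

# Weighted REML with independent crossed random intercepts, via the
# Woodbury identity: V = sigma2_res * (diag(1/w) + sum_j gamma_j Z_j Z_j'),
# so one objective evaluation costs O(n q^2) with q the total number of
# random levels. sigma2_res is profiled out analytically.
reml_crossed <- function(y, X, Zlist, w, n_starts = 3) {
  n <- length(y); p <- ncol(X)
  U <- do.call(cbind, Zlist)
  qj <- vapply(Zlist, ncol, integer(1))
  jidx <- rep(seq_along(Zlist), qj)
  WU <- Diagonal(x = w) %*% U
  Cuu <- as.matrix(crossprod(U, WU))
  UtWX <- as.matrix(crossprod(WU, X))
  UtWy <- as.vector(crossprod(WU, y))
  XtWX <- crossprod(X * w, X)
  XtWy <- as.vector(crossprod(X, w * y))
  ytWy <- sum(w * y^2)
  sum_log_w <- sum(log(w))

  pieces <- function(gam) {
    sg <- sqrt(gam)[jidx]
    K <- diag(sum(qj)) + (sg %o% sg) * Cuu
    cholK <- tryCatch(chol(K), error = function(e) NULL)
    if (is.null(cholK)) return(list(ok = FALSE))
    TX <- sg * UtWX
    Ty <- sg * UtWy
    KiTX <- backsolve(cholK, backsolve(cholK, TX, transpose = TRUE))
    KiTy <- backsolve(cholK, backsolve(cholK, Ty, transpose = TRUE))
    A <- XtWX - crossprod(TX, KiTX)
    b <- XtWy - as.vector(crossprod(TX, KiTy))
    q2 <- ytWy - sum(Ty * KiTy)
    cholA <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(cholA)) return(list(ok = FALSE))
    beta <- backsolve(cholA, backsolve(cholA, b, transpose = TRUE))
    rGr <- q2 - sum(b * beta)
    list(ok = TRUE, beta = beta, cholA = cholA, rGr = rGr,
         logdetA = 2 * sum(log(diag(cholA))),
         logdetG = 2 * sum(log(diag(cholK))) - sum_log_w)
  }
  obj <- function(par) {
    pc <- pieces(exp(par))
    if (!pc$ok || pc$rGr <= 0) return(1e10)
    s2r <- pc$rGr / (n - p)
    val <- (n - p) * (log(s2r) + 1 + log(2 * pi)) + pc$logdetG +
      pc$logdetA
    if (is.finite(val)) val else 1e10
  }
  starts <- list(c(-1, -1), c(-3, 0), c(0, -3))
  starts <- starts[seq_len(max(1, min(n_starts, 3)))]
  best <- NULL; trace <- list()
  for (st in starts) {
    res <- tryCatch(
      optim(st[seq_along(Zlist)], obj, method = "L-BFGS-B",
            lower = -20, upper = 10, control = list(maxit = 200L)),
      error = function(e) list(value = Inf, convergence = 99L))
    trace[[length(trace) + 1L]] <- res
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("weighted REML optimization failed to find a finite objective")
  gam <- exp(best$par)
  pc <- pieces(gam)
  s2r <- pc$rGr / (n - p)
  list(beta = pc$beta, beta_cov = s2r * chol2inv(pc$cholA),
       gamma = gam, sigma2_res = s2r, sigma2_random = gam * s2r,
       reml_value = best$value,
       converged = any(vapply(trace, function(r)
         identical(r$convergence, 0L) &&
           r$value <= best$value + 1e-6, logical(1))),
       optim_trace = trace)
}

#' Fit the environmental-covariate model of block movement
#'
#' Weighted linear mixed model
#' `dist_mean ~ Day + Timeline + <covariates>` with independent crossed
#' random intercepts for pig and for day-by-timeline, REML estimation,
#' and residual variance `sigma2_res / n_hours` for a block averaging
#' `n_hours` valid hours (inverse-variance weighting of block means).
#' Movement blocks without a matching environmental block are dropped
#' with a message. Type-3 F tests use the containment denominator df
#' `n - rank([X, Z_pig, Z_daytl])`.
#'
#' @param movement_blocks Output of [movement_to_blocks()].
#' @param env_table Output of [aggregate_env()].
#' @param covariates Environmental covariate columns to include
#'   (typically `pm_screen()$retained` plus temperature and humidity).
#' @param n_starts Optimizer starts for the variance components.
#' @return An object of class `env_lmm`: `type3` (data.frame), `beta`,
#'   `beta_cov`, `vc` (list: `sigma2_pig`, `sigma2_daytl`, `sigma2_res`),
#'   `reml_value`, `n_obs`, `den_df`, `dropped_blocks`, `data`.
#' @export
fit_env_model <- function(movement_blocks, env_table,
                          covariates = c("temp_mean", "rh_mean",
                                         "pm25_mean"),
                          n_starts = 3) {
  stopifnot(all(c("pig_id", "day", "timeline", "dist_mean", "n_hours")
                %in% names(movement_blocks)))
  miss <- setdiff(covariates, names(env_table))
  if (length(miss))
    stop("covariate(s) absent from env_table: ",
         paste(miss, collapse = ", "))
  d <- merge(movement_blocks,
             env_table[c("day", "timeline", covariates)],
             by = c("day", "timeline"))
  dropped <- nrow(movement_blocks) - nrow(d)
  if (dropped > 0)
    message(dropped, " movement block(s) had no matching environmental ",
            "block and were dropped")
  if (!nrow(d)) stop("no joined day-timeline blocks to fit")
  d <- d[order(d$pig_id, d$day, d$timeline), ]

  flagged <- covariates[vapply(covariates, function(cl)
    sd(d[[cl]]) == 0, logical(1))]
  if (length(flagged)) {
    warning("covariate(s) constant across blocks, slope inestimable: ",
            paste(flagged, collapse = ", "))
    covariates <- setdiff(covariates, flagged)
  }

  fday <- factor(d$day)
  ftl <- factor(d$timeline)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  fml <- stats::reformulate(c("fday", "ftl", covariates))
  mf <- cbind(data.frame(fday = fday, ftl = ftl), d[covariates])
  mm <- model.matrix(fml, data = mf)
  assign <- attr(mm, "assign")
  qr_cp <- qr(crossprod(mm), tol = 1e-9)
  kept <- sort(qr_cp$pivot[seq_len(qr_cp$rank)])
  X <- mm[, kept, drop = FALSE]
  assign <- assign[kept]

  pigs <- sort(unique(d$pig_id))
  dtl <- paste(d$day, d$timeline, sep = ".")
  dtls <- sort(unique(dtl))
  Z1 <- sparseMatrix(i = seq_len(nrow(d)), j = match(d$pig_id, pigs),
                     x = 1, dims = c(nrow(d), length(pigs)))
  Z2 <- sparseMatrix(i = seq_len(nrow(d)), j = match(dtl, dtls),
                     x = 1, dims = c(nrow(d), length(dtls)))

  res <- reml_crossed(d$dist_mean, X, list(Z1, Z2), w = d$n_hours,
                      n_starts = n_starts)

  rank_xz <- qr(as.matrix(crossprod(cbind2(Matrix(X, sparse = TRUE),
                                           cbind2(Z1, Z2)))),
                tol = 1e-9)$rank
  den_df <- nrow(d) - rank_xz

  term_labels <- c("day", "timeline", covariates)
  type3 <- do.call(rbind, lapply(seq_along(term_labels), function(e) {
    idx <- which(assign == e)
    if (!length(idx)) return(NULL)
    S <- matrix(0, length(idx), ncol(X))
    S[cbind(seq_along(idx), idx)] <- 1
    w <- wald_F(S, res$beta, res$beta_cov, den_df)
    data.frame(effect = term_labels[e], num_df = w$num_df,
               den_df = den_df, F = w$F, p = w$p)
  }))
  rownames(type3) <- NULL

  structure(list(
    type3 = type3,
    beta = setNames(res$beta, colnames(X)), beta_cov = res$beta_cov,
    vc = list(sigma2_pig = res$sigma2_random[1],
              sigma2_daytl = res$sigma2_random[2],
              sigma2_res = res$sigma2_res),
    reml_value = res$reml_value, n_obs = nrow(d), den_df = den_df,
    dropped_blocks = dropped, covariates = covariates,
    flagged = flagged, converged = res$converged, data = d),
    class = "env_lmm")
}

#' @export
print.env_lmm <- function(x, ...) {
  cat("Weighted mixed model of block movement on environment (REML)\n")
  cat(sprintf("  %d pig x day x timeline blocks (%d dropped in join)\n",
              x$n_obs, x$dropped_blocks))
  cat(sprintf("  sigma2_pig = %.1f  sigma2_daytl = %.1f  sigma2_res = %.1f\n",
              x$vc$sigma2_pig, x$vc$sigma2_daytl, x$vc$sigma2_res))
  cat("  Type-3 tests:\n")
  t3 <- x$type3
  t3$F <- round(t3$F, 2)
  t3$p <- signif(t3$p, 4)
  print(t3, row.names = FALSE)
  invisible(x)
}
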