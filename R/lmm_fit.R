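# REML engine for the movement model: random pig intercept + AR(1)
# residual correlation within pig-day, with rho^|gap| across missing
# hours. The marginal covariance for pig i is
#   V_i = sigma2_pig * J + sigma2_res * C_i(rho),
# with C_i block-diagonal over that pig's days. The engine never forms
# V: each pig-day block is whitened through the (bidiagonal) inverse
# Cholesky of its AR(1) correlation, and the rank-one pig intercept is
# absorbed by Sherman-Morrison, so one objective evaluation is O(n p).

pig_indicator <- function(design) {
  sparseMatrix(i = seq_len(design$n), j = design$pig, x = 1,
               dims = c(design$n, length(design$pigs)))
}

# Core linear algebra shared by the objective, the fit and the BLUPs.
# gamma = sigma2_pig / sigma2_res. Returns cross-products with respect to
# G^{-1}, where V = sigma2_res * G.
lmm_pieces <- function(design, gamma, rho, keep_resid = FALSE) {
  n <- design$n
  a <- ifelse(design$new_block, 0, rho^design$delta)
  s <- sqrt(1 - a^2)
  y <- design$y
  yt <- (y - a * y[design$prev]) / s
  Xp <- design$X[design$prev, , drop = FALSE]
  Xt <- Diagonal(x = 1 / s) %*% (design$X - Diagonal(x = a) %*% Xp)
  ut <- (1 - a) / s
  logdetC <- 2 * sum(log(s))
  P <- pig_indicator(design)
  Mx <- as.matrix(crossprod(P, Diagonal(x = ut) %*% Xt))
  My <- as.vector(crossprod(P, ut * yt))
  ng <- as.vector(crossprod(P, ut^2))
  k <- if (gamma > 0) gamma / (1 + gamma * ng) else numeric(length(ng))
  A <- as.matrix(crossprod(Xt)) -
    (if (gamma > 0) crossprod(sqrt(k) * Mx) else 0)
  bvec <- as.vector(crossprod(Xt, yt)) -
    (if (gamma > 0) as.vector(crossprod(Mx, k * My)) else 0)
  q <- sum(yt^2) - sum(k * My^2)
  cholA <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(cholA)) return(list(ok = FALSE))
  beta <- backsolve(cholA, backsolve(cholA, bvec, transpose = TRUE))
  rGr <- q - sum(bvec * beta)
  out <- list(ok = TRUE, beta = beta, cholA = cholA, rGr = rGr,
              logdetA = 2 * sum(log(diag(cholA))),
              logdetG = logdetC + sum(log1p(gamma * ng)),
              Mx = Mx, My = My, ng = ng, k = k)
  if (keep_resid) {
    rt <- yt - as.vector(Xt %*% beta)
    out$dg <- as.vector(crossprod(P, ut * rt))
  }
  out
}

#' Evaluate -2 times the restricted log-likelihood
#'
#' Computes \eqn{-2\ell_R(\theta) = \log|V| + \log|X'V^{-1}X| +
#' r'V^{-1}r + (n - p)\log 2\pi} (with \eqn{r} the GLS residual and
#' \eqn{p} the fixed-effects rank) for the movement model at the given
#' variance components, without forming the \eqn{n \times n} covariance.
#' Non-finite evaluations are reported as `Inf` so optimizers can treat
#' them as rejected steps.
#'
#' @param theta Named list or vector with `sigma2_pig` (`>= 0`),
#'   `sigma2_res` (`> 0`) and `rho` (`|rho| < 1`).
#' @param design An [build_design()] result.
#' @return Scalar: `-2` restricted log-likelihood.
#' @export
neg2_reml <- function(theta, design) {
  theta <- as.list(theta)
  s2p <- theta$sigma2_pig; s2r <- theta$sigma2_res; rho <- theta$rho
  stopifnot(s2p >= 0, s2r > 0, abs(rho) < 1)
  pc <- lmm_pieces(design, gamma = s2p / s2r, rho = rho)
  if (!pc$ok || pc$rGr <= 0) return(Inf)
  np <- design$n - design$p
  val <- np * log(2 * pi) + np * log(s2r) + pc$logdetG + pc$logdetA +
    pc$rGr / s2r
  if (!is.finite(val)) Inf else val
}

# Profiled objective: sigma2_res maximised out analytically.
profiled_obj <- function(design, gamma, rho) {
  pc <- lmm_pieces(design, gamma, rho)
  np <- design$n - design$p
  if (!pc$ok || pc$rGr <= 0) return(1e10)
  s2r <- pc$rGr / np
  val <- np * (log(s2r) + 1 + log(2 * pi)) + pc$logdetG + pc$logdetA
  if (!is.finite(val)) 1e10 else val
}

#' Fit the hourly-movement mixed model by REML
#'
#' Estimates the model with fixed day, hour and day-by-hour effects, a
#' random pig intercept and AR(1) residual correlation within pig-day.
#' The restricted likelihood is maximised over
#' \eqn{(\log\gamma, \mathrm{atanh}\,\rho)} with
#' \eqn{\gamma = \sigma^2_{pig}/\sigma^2_{res}} and \eqn{\sigma^2_{res}}
#' profiled out analytically; several starting points guard against
#' flat likelihood ridges. Fixed effects are then the GLS solution at the
#' REML estimates.
#'
#' @param records Valid hourly observations (see [analysis_table()]), or
#'   a prebuilt [build_design()] object.
#' @param spec An [lmm_spec()] (ignored when `records` is a design).
#' @param coding Fixed-effects coding passed to [build_design()].
#' @param fix Optional list pinning components instead of estimating
#'   them: `sigma2_pig = 0` and/or `rho = <value>` (e.g.
#'   `fix = list(sigma2_pig = 0, rho = 0)` reproduces ordinary least
#'   squares).
#' @param n_starts Number of optimizer starts (1-3).
#' @param control Passed to [stats::optim()] (`method = "L-BFGS-B"`).
#' @return An object of class `movement_lmm` with elements `beta`,
#'   `beta_cov`, `vc` (list: `sigma2_pig`, `sigma2_res`, `rho`),
#'   `reml_value` (-2 restricted log-likelihood), `n_obs`, `rank_X`,
#'   `group_sizes`, `den_df` (containment denominator df), `converged`
#'   and the `design`.
#' @export
#' @examples
#' h <- simulate_hourly(generative_truth(), n_pigs = 4, n_days = 2,
#'                      seed = 1)
#' fit <- fit_lmm(analysis_table(h))
#' fit$vc
fit_lmm <- function(records, spec = lmm_spec(),
                    coding = c("cellmeans", "treatment", "sum"),
                    fix = list(), n_starts = 3, control = list()) {
  design <- if (inherits(records, "lmm_design")) records
            else build_design(records, spec, match.arg(coding))
  if (length(design$pigs) < 2)
    stop("at least 2 pigs are required to separate pig and residual ",
         "variance")
  if (design$n <= design$p)
    stop("no residual degrees of freedom: n <= rank(X)")
  fix_gamma0 <- FALSE
  if (!is.null(fix$sigma2_pig)) {
    if (fix$sigma2_pig != 0)
      stop("only sigma2_pig = 0 can be fixed; other values are not ",
           "supported")
    fix_gamma0 <- TRUE
  }
  rho_fixed <- fix$rho
  if (is.null(rho_fixed) && design$max_block < 2) {
    warning("no pig-day block has >= 2 observations: rho is not ",
            "identifiable and is fixed at 0")
    rho_fixed <- 0
  }
  if (!is.null(rho_fixed) && abs(rho_fixed) >= 1)
    stop("fixed rho must satisfy |rho| < 1")

  est_gamma <- !fix_gamma0
  est_rho <- is.null(rho_fixed)
  par_of <- function(gamma, rho)
    c(if (est_gamma) log(gamma), if (est_rho) atanh(rho))
  unpack <- function(par) {
    i <- 1L
    gamma <- if (est_gamma) { g <- exp(par[i]); i <- i + 1L; g } else 0
    rho <- if (est_rho) tanh(par[i]) else rho_fixed
    list(gamma = gamma, rho = rho)
  }
  fn <- function(par) {
    th <- unpack(par)
    profiled_obj(design, th$gamma, th$rho)
  }

  starts <- list(c(0.4, 0.2), c(0.05, 0), c(1.2, 0.45))
  starts <- starts[seq_len(max(1, min(n_starts, length(starts))))]
  lower <- c(if (est_gamma) -20, if (est_rho) -2.65)
  upper <- c(if (est_gamma) 10, if (est_rho) 2.65)
  ctrl <- utils::modifyList(list(maxit = 200L), control)

  best <- NULL; trace <- list()
  if (est_gamma || est_rho) {
    for (st in starts) {
      p0 <- par_of(max(st[1], 1e-6), if (est_rho) st[2] else 0)
      res <- tryCatch(
        optim(p0, fn, method = "L-BFGS-B", lower = lower, upper = upper,
              control = ctrl),
        error = function(e) list(value = Inf, convergence = 99L,
                                 message = conditionMessage(e)))
      trace[[length(trace) + 1L]] <- res
      if (is.null(best) || res$value < best$value) best <- res
    }
    if (!is.finite(best$value) || best$value >= 1e10)
      stop("REML optimization failed: no finite objective was found; ",
           "optimizer trace recorded in the condition call")
    th <- unpack(best$par)
    converged <- any(vapply(trace, function(r)
      identical(r$convergence, 0L) && r$value <= best$value + 1e-6,
      logical(1)))
  } else {
    th <- list(gamma = 0, rho = rho_fixed)
    best <- list(value = profiled_obj(design, 0, rho_fixed),
                 convergence = 0L)
    converged <- TRUE
  }
  if (!converged)
    warning("REML optimizer did not report clean convergence; ",
            "inspect $optim_trace")

  pc <- lmm_pieces(design, th$gamma, th$rho, keep_resid = TRUE)
  np <- design$n - design$p
  s2r <- pc$rGr / np
  s2p <- th$gamma * s2r
  beta <- setNames(pc$beta, colnames(design$X))
  beta_cov <- s2r * chol2inv(pc$cholA)
  dimnames(beta_cov) <- list(names(beta), names(beta))

  M <- cbind2(design$X, pig_indicator(design))
  rank_xz <- qr(as.matrix(crossprod(M)), tol = 1e-9)$rank
  den_df <- design$n - rank_xz

  structure(list(
    beta = beta, beta_cov = beta_cov,
    vc = list(sigma2_pig = s2p, sigma2_res = s2r, rho = th$rho),
    reml_value = best$value,
    n_obs = design$n, rank_X = design$p,
    group_sizes = setNames(tabulate(design$pig, length(design$pigs)),
                           design$pigs),
    den_df = den_df, rank_XZ = rank_xz,
    converged = converged, optim_trace = trace,
    pieces = pc[c("Mx", "My", "ng", "k", "dg")],
    design = design, call = match.call()),
    class = "movement_lmm")
}

#' @export
print.movement_lmm <- function(x, ...) {
  cat("Linear mixed model of hourly movement (REML)\n")
  cat(sprintf("  %d observations, %d pigs, rank(X) = %d\n",
              x$n_obs, length(x$group_sizes), x$rank_X))
  cat(sprintf("  sigma2_pig = %.1f (SD %.1f cm/h)\n",
              x$vc$sigma2_pig, sqrt(x$vc$sigma2_pig)))
  cat(sprintf("  sigma2_res = %.1f (SD %.1f cm/h)\n",
              x$vc$sigma2_res, sqrt(x$vc$sigma2_res)))
  cat(sprintf("  AR(1) rho  = %.3f   ICC = %.3f\n", x$vc$rho, icc(x)))
  cat(sprintf("  -2 restricted log-likelihood = %.2f%s\n", x$reml_value,
              if (x$converged) "" else "  (convergence not clean)"))
  invisible(x)
}

#' Intraclass correlation of the pig random intercept
#'
#' The share of non-temporal variance attributable to persistent
#' between-pig differences:
#' \eqn{ICC = \sigma^2_{pig} / (\sigma^2_{pig} + \sigma^2_{res})}.
#' The AR(1) parameter is deliberately excluded: it redistributes
#' residual covariance over time but does not change the marginal
#' residual variance.
#'
#' @param x A `movement_lmm` fit, or a list/vector with `sigma2_pig` and
#'   `sigma2_res`.
#' @return The ICC in `[0, 1]`.
#' @export
#' @examples
#' icc(list(sigma2_pig = 15773, sigma2_res = 38884))  # ~0.29
icc <- function(x) {
  vc <- if (inherits(x, "movement_lmm")) x$vc else as.list(x)
  s2p <- vc$sigma2_pig; s2r <- vc$sigma2_res
  stopifnot(s2p >= 0, s2r >= 0, s2p + s2r > 0)
  s2p / (s2p + s2r)
}
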