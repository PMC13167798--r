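# Independent brute-force oracles for the mixed-model engine. These build
# the full n x n covariance explicitly and use plain dense linear algebra,
# sharing no code with the structured implementation they check.

# Marginal covariance: sigma2_pig within pig + AR(1) (rho^|hour gap|)
# within pig-day, scaled by sigma2_res.
oracle_V <- function(design, theta) {
  n <- design$n
  pig <- design$pig; day <- design$day; hour <- design$hour
  V <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (pig[i] == pig[j]) {
      V[i, j] <- theta$sigma2_pig
      if (day[i] == day[j])
        V[i, j] <- V[i, j] +
          theta$sigma2_res * theta$rho^abs(hour[i] - hour[j])
    }
  }
  V
}

oracle_neg2_reml <- function(design, theta) {
  V <- oracle_V(design, theta)
  X <- as.matrix(design$X); y <- design$y
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  beta <- solve(XtVX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  as.numeric(determinant(V)$modulus + determinant(XtVX)$modulus +
               t(r) %*% Vi %*% r + (design$n - ncol(X)) * log(2 * pi))
}

oracle_gls <- function(design, theta) {
  V <- oracle_V(design, theta)
  X <- as.matrix(design$X); y <- design$y
  Vi <- solve(V)
  as.vector(solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y))
}

# Henderson mixed-model equations for the pig intercepts: returns the
# conditional modes and the prediction variances var(bhat - b).
oracle_blups <- function(design, theta) {
  n <- design$n
  # residual-only covariance (no pig component)
  R <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (design$pig[i] == design$pig[j] && design$day[i] == design$day[j])
      R[i, j] <- theta$sigma2_res *
        theta$rho^abs(design$hour[i] - design$hour[j])
  }
  X <- as.matrix(design$X); y <- design$y
  q <- length(design$pigs)
  Z <- matrix(0, n, q)
  Z[cbind(seq_len(n), design$pig)] <- 1
  Ri <- solve(R)
  M <- rbind(cbind(t(X) %*% Ri %*% X, t(X) %*% Ri %*% Z),
             cbind(t(Z) %*% Ri %*% X,
                   t(Z) %*% Ri %*% Z + diag(q) / theta$sigma2_pig))
  rhs <- c(t(X) %*% Ri %*% y, t(Z) %*% Ri %*% y)
  sol <- solve(M, rhs)
  p <- ncol(X)
  list(b = unname(sol[(p + 1):(p + q)]),
       var = unname(diag(solve(M))[(p + 1):(p + q)]))
}

# Small gappy fixture reused by several oracle tests: 2 pigs x 2 days with
# irregular hour coverage (< 50 observations).
gappy_fixture <- function(seed = 3) {
  h <- simulate_hourly(generative_truth(n_days = 2, seed = seed),
                       n_pigs = 2, n_days = 2, seed = seed)
  at <- analysis_table(h)
  at[c(1:6, 9, 14, 25:30, 41, 49:53, 60, 73:78, 90), ]
}
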