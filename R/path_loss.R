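# Log-distance path-loss calibration: RSSI (dBm) <-> distance (m).

#' Construct a path-loss model
#'
#' The log-distance propagation model used to convert received signal
#' strength to tag-receiver distance:
#' \deqn{RSSI = TxPower - 10\,n\,\log_{10}(d),\qquad
#'       d = 10^{(TxPower - RSSI)/(10 n)}}
#' where `tx_power` is the assumed received signal strength (dBm) at the
#' 1 m reference distance and `n` is the path-loss exponent (2 in free
#' space; often 1.6-3.5 indoors).
#'
#' @param tx_power Received signal strength at 1 m (dBm).
#' @param n Path-loss exponent, `> 0`.
#' @param sigma Residual standard error of the calibration fit (dB), if
#'   known.
#' @return An object of class `path_loss_model`.
#' @export
#' @examples
#' m <- path_loss_model(tx_power = -50, n = 2)
#' distance_from_rssi(-70, m)  # 10 m
path_loss_model <- function(tx_power, n, sigma = NA_real_) {
  stopifnot(is.finite(tx_power), is.finite(n))
  if (n <= 0) stop("the path-loss exponent n must be > 0")
  structure(list(tx_power = tx_power, n = n, sigma = sigma),
            class = "path_loss_model")
}

as_path_loss_model <- function(x) {
  if (inherits(x, "path_loss_model")) return(x)
  if (is.list(x) && all(c("tx_power", "n") %in% names(x)))
    return(path_loss_model(x$tx_power, x$n))
  stop("cannot interpret 'model' as a path-loss model")
}

#' @export
print.path_loss_model <- function(x, ...) {
  cat("Log-distance path-loss model\n")
  cat(sprintf("  TxPower (dBm at 1 m): %.3f\n  exponent n: %.4f\n",
              x$tx_power, x$n))
  if (is.finite(x$sigma))
    cat(sprintf("  residual SE: %.3f dB\n", x$sigma))
  invisible(x)
}

#' Fit the path-loss model to calibration records
#'
#' Least-squares fit of `rssi ~ tx_power - 10 n log10(distance)` to
#' calibration measurements taken at known tag-receiver distances. This is
#' an ordinary linear regression of RSSI on `-10 log10(distance)`, whose
#' intercept is `tx_power` and slope is `n`.
#'
#' @param records A data.frame with columns `distance_m` (> 0) and
#'   `rssi_dbm`, one row per calibration measurement.
#' @return A [path_loss_model()] with the residual standard error in
#'   `$sigma` and the underlying `lm` fit in attribute `"fit"`.
#' @export
#' @examples
#' cal <- data.frame(distance_m = c(1, 10), rssi_dbm = c(-50, -70))
#' fit_path_loss(cal)  # tx_power -50, n = 2
fit_path_loss <- function(records) {
  if (!all(c("distance_m", "rssi_dbm") %in% names(records)))
    stop("calibration records need columns 'distance_m' and 'rssi_dbm'")
  records <- records[complete.cases(records[c("distance_m", "rssi_dbm")]), ]
  if (any(records$distance_m <= 0))
    stop("calibration distances must be > 0")
  if (nrow(records) < 2 || length(unique(records$distance_m)) < 2)
    stop("path-loss calibration needs >= 2 records at >= 2 distinct ",
         "distances; with a single distance TxPower and n are confounded")
  x <- -10 * log10(records$distance_m)
  fit <- lm(records$rssi_dbm ~ x)
  sigma <- if (fit$df.residual > 0)
    sqrt(sum(fit$residuals^2) / fit$df.residual) else NA_real_
  out <- path_loss_model(tx_power = unname(coef(fit)[1]),
                         n = unname(coef(fit)[2]), sigma = sigma)
  attr(out, "fit") <- fit
  out
}

#' Convert RSSI readings to distance
#'
#' Inverts the log-distance model:
#' `distance = 10^((tx_power - rssi) / (10 n))` (m). The function is total
#' and strictly decreasing in RSSI. Distances above `cap` are flagged as
#' implausible (attribute `"implausible"`, with a warning) but never
#' altered.
#'
#' @param rssi Numeric vector of RSSI readings (dBm).
#' @param model A [path_loss_model()].
#' @param cap Plausibility cap (m); `Inf` disables flagging.
#' @return Numeric vector of distances (m); if any exceed `cap`, a logical
#'   attribute `"implausible"` marks them.
#' @export
distance_from_rssi <- function(rssi, model, cap = Inf) {
  model <- as_path_loss_model(model)
  d <- 10^((model$tx_power - rssi) / (10 * model$n))
  if (is.finite(cap)) {
    bad <- d > cap
    if (any(bad, na.rm = TRUE)) {
      warning(sum(bad, na.rm = TRUE),
              " distance estimate(s) above the plausibility cap of ",
              cap, " m (flagged, not altered)")
      attr(d, "implausible") <- bad
    }
  }
  d
}
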