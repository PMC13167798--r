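# Design construction for the hourly-movement mixed model:
# fixed Day, Hour and Day x Hour; random pig intercept; AR(1) residual
# correlation within each pig-day block (rho^|gap| across missing hours).

#' Specify the hourly-movement mixed model
#'
#' Declares the column names and factor levels of the model
#' \eqn{y_{idh} = \mu + Day_d + Hour_h + (Day\times Hour)_{dh} + b_i +
#' \varepsilon_{idh}} with a random pig intercept and AR(1) residuals
#' within pig-day, estimated by REML.
#'
#' @param response Response column (cm/h).
#' @param day,hour,pig Column names of the day, hour and pig identifiers.
#' @param days Declared day levels; `NULL` means the sorted observed days.
#' @param hours Declared hour levels (clock hours).
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(response = "dist_cm_per_h", day = "day",
                     hour = "hour", pig = "pig_id",
                     days = NULL, hours = 0:23) {
  structure(list(response = response, day = day, hour = hour, pig = pig,
                 days = days, hours = hours),
            class = "lmm_spec")
}

#' Build the fixed-effects design and grouping structure
#'
#' Assembles everything the REML engine needs: the fixed-effects matrix in
#' a declared coding, the pig grouping index, the pig-day residual blocks
#' and the hour gaps within each block (used for the `rho^|gap|` AR(1)
#' correlation across missing hours). Rows are sorted by pig, day, hour, so
#' fitted results are invariant to input row order.
#'
#' Codings: `"cellmeans"` (default; one indicator column per observed
#' day-hour cell — always full rank, sparse, and the fastest route for
#' large grids), `"treatment"` (reference coding: intercept, day mains,
#' hour mains, interaction) and `"sum"` (sum-to-zero contrasts). For the
#' latter two, aliased columns arising from empty cells are detected by a
#' pivoted decomposition and dropped, with the full column set tracked for
#' rank accounting. All estimable results downstream are invariant to the
#' coding choice.
#'
#' @param records Data.frame of valid hourly observations.
#' @param spec An [lmm_spec()].
#' @param coding Fixed-effects coding (see Details).
#' @return An object of class `lmm_design`.
#' @export
build_design <- function(records, spec = lmm_spec(),
                         coding = c("cellmeans", "treatment", "sum")) {
  coding <- match.arg(coding)
  need <- unlist(spec[c("response", "day", "hour", "pig")])
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing required column(s): ",
         paste(miss, collapse = ", "))
  y <- records[[spec$response]]
  dayv <- records[[spec$day]]
  hourv <- records[[spec$hour]]
  pigv <- as.character(records[[spec$pig]])
  bad <- which(!is.finite(y) | is.na(dayv) | is.na(hourv) | is.na(pigv))
  if (length(bad))
    stop("non-finite response or missing identifiers at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  hours <- spec$hours
  bad <- which(!(hourv %in% hours))
  if (length(bad))
    stop("hour value outside declared levels at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  days <- if (is.null(spec$days)) sort(unique(dayv)) else spec$days
  bad <- which(!(dayv %in% days))
  if (length(bad))
    stop("day value outside declared levels at row(s): ",
         paste(head(bad, 5), collapse = ", "))
  ord <- order(pigv, dayv, hourv, method = "radix")
  y <- y[ord]; dayv <- dayv[ord]; hourv <- hourv[ord]; pigv <- pigv[ord]
  pigs <- sort(unique(pigv))
  # declared levels bound the admissible values; the design (and the
  # levels LSMeans average over) use the levels actually observed
  days <- sort(unique(dayv))
  hours <- sort(unique(hourv))
  fday <- factor(dayv, levels = days)
  fhour <- factor(hourv, levels = hours)
  n <- length(y)

  # observed day-hour cells, in (day, hour) order
  cell_key <- (as.integer(fday) - 1L) * length(hours) + as.integer(fhour)
  obs_keys <- sort(unique(cell_key))
  cell_idx <- match(cell_key, obs_keys)
  cells <- data.frame(
    day = days[((obs_keys - 1L) %/% length(hours)) + 1L],
    hour = hours[((obs_keys - 1L) %% length(hours)) + 1L])
  cells$first_row <- match(seq_along(obs_keys), cell_idx)

  if (coding == "cellmeans") {
    X_full <- sparseMatrix(i = seq_len(n), j = cell_idx, x = 1,
                           dims = c(n, length(obs_keys)))
    colnames(X_full) <- paste0("cell.d", cells$day, ".h", cells$hour)
    kept <- seq_len(ncol(X_full))
    X <- X_full
    assign_full <- rep(3L, ncol(X_full))
  } else {
    contr <- if (coding == "treatment") "contr.treatment" else "contr.sum"
    old <- options(contrasts = c(contr, "contr.poly"))
    on.exit(options(old), add = TRUE)
    mm <- model.matrix(~ fday * fhour,
                       data = data.frame(fday = fday, fhour = fhour))
    assign_full <- attr(mm, "assign")
    X_full <- Matrix(mm, sparse = TRUE)
    # pivoted rank detection on the cross-product (indicator-like columns,
    # well scaled); aliased columns from empty cells are dropped
    cp <- as.matrix(crossprod(X_full))
    qr_cp <- qr(cp, tol = 1e-9)
    r <- qr_cp$rank
    kept <- sort(qr_cp$pivot[seq_len(r)])
    X <- X_full[, kept, drop = FALSE]
  }

  pig_i <- match(pigv, pigs)
  block <- paste(pig_i, dayv, sep = ".")
  new_block <- c(TRUE, block[-1] != block[-n])
  delta <- c(0, diff(as.numeric(hourv)))
  delta[new_block] <- 0
  prev <- c(1L, seq_len(n - 1L))
  prev[new_block] <- which(new_block)  # self; masked by a = 0

  structure(list(y = y, X = X, coding = coding,
                 colnames_full = colnames(X_full), kept = kept,
                 assign_full = assign_full,
                 n = n, p = ncol(X),
                 pig = pig_i, pigs = pigs,
                 day = dayv, hour = as.numeric(hourv),
                 days = days, hours = hours,
                 fday = fday, fhour = fhour,
                 cells = cells, cell_idx = cell_idx,
                 new_block = new_block, prev = prev, delta = delta,
                 max_block = max(table(block))),
            class = "lmm_design")
}

#' @export
print.lmm_design <- function(x, ...) {
  cat(sprintf(paste0("Mixed-model design: %d obs, %d pigs, %d observed ",
                     "day-hour cells\n  fixed-effects coding: %s ",
                     "(%d columns kept of %d)\n"),
              x$n, length(x$pigs), nrow(x$cells), x$coding, x$p,
              length(x$colnames_full)))
  invisible(x)
}
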