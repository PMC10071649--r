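#' Left-truncated censored survival response
#'
#' Packs the per-subject observation scheme into a response object for use on
#' the left-hand side of a [truncph()] model formula. Each subject enters the
#' study at time `entry` (the left-truncation time `A`, on the same scale as
#' the event times) and is observed either exactly (`status = 1`, event time
#' `time`) or censored into the interval `(lower, upper]` (`status = 0`,
#' `upper` may be `Inf`).
#'
#' Conventions: a subject is left-censored when `lower == entry`,
#' right-censored when `upper == Inf`, and interval-censored otherwise.
#'
#' @param entry entry (truncation) time `A >= 0`; the subject is sampled
#'   conditional on the event time exceeding `entry`.
#' @param status 1 if the event time is observed exactly, 0 if censored.
#' @param time exact event time, required (and only allowed) when `status = 1`;
#'   must satisfy `time >= entry`.
#' @param lower,upper censoring interval endpoints, required (and only allowed)
#'   when `status = 0`; must satisfy `entry <= lower < upper`, with
#'   `upper = Inf` meaning right censoring.
#' @return a numeric matrix of class `"TruncSurv"` with columns
#'   `entry, status, time, lower, upper` (unused cells `NA`).
#' @examples
#' TruncSurv(entry = c(0.1, 0.2), status = c(0, 1),
#'           time = c(NA, 0.5), lower = c(0.3, NA), upper = c(Inf, NA))
#' @export
TruncSurv <- function(entry, status, time = NULL, lower = NULL, upper = NULL) {
  n <- length(entry)
  if (n < 1L) input_error("empty response: need at least one subject")
  status <- as.numeric(status)
  time <- if (is.null(time)) rep(NA_real_, n) else as.numeric(time)
  lower <- if (is.null(lower)) rep(NA_real_, n) else as.numeric(lower)
  upper <- if (is.null(upper)) rep(NA_real_, n) else as.numeric(upper)
  if (any(lengths(list(status, time, lower, upper)) != n))
    input_error("entry, status, time, lower, upper must have equal length")
  m <- cbind(entry = as.numeric(entry), status = status,
             time = time, lower = lower, upper = upper)
  validate_truncsurv(m)
  class(m) <- c("TruncSurv", "matrix")
  m
}

validate_truncsurv <- function(m) {
  entry <- m[, "entry"]; status <- m[, "status"]
  time <- m[, "time"]; lower <- m[, "lower"]; upper <- m[, "upper"]
  bad <- function(which, msg) {
    if (any(which)) {
      input_error(sprintf("invalid record(s) %s: %s",
                          paste(utils::head(which(which), 5L), collapse = ", "),
                          msg))
    }
  }
  bad(!is.finite(entry) | entry < 0, "entry time must be finite and >= 0")
  bad(is.na(status) | !(status %in% c(0, 1)), "status must be 0 or 1")
  ex <- status == 1
  bad(ex & (!is.finite(time) | time < entry),
      "status = 1 requires a finite event time >= entry")
  bad(ex & (!is.na(lower) | !is.na(upper)),
      "status = 1 must not carry a censoring interval")
  ce <- status == 0
  bad(ce & !is.na(time), "status = 0 must not carry an exact event time")
  bad(ce & (is.na(lower) | !is.finite(lower)),
      "status = 0 requires a finite interval lower endpoint")
  bad(ce & is.na(upper), "status = 0 requires an interval upper endpoint")
  bad(ce & !is.na(lower) & lower < entry, "interval lower endpoint < entry")
  bad(ce & !is.na(lower) & !is.na(upper) & upper <= lower,
      "interval upper endpoint must exceed the lower endpoint")
  invisible(m)
}

#' @export
print.TruncSurv <- function(x, ...) {
  lab <- ifelse(x[, "status"] == 1,
                sprintf("%g (event, entry %g)", x[, "time"], x[, "entry"]),
                ifelse(is.infinite(x[, "upper"]),
                       sprintf("(%g, Inf] (entry %g)", x[, "lower"], x[, "entry"]),
                       sprintf("(%g, %g] (entry %g)", x[, "lower"], x[, "upper"],
                               x[, "entry"])))
  print(lab, quote = FALSE, ...)
  invisible(x)
}

## Internal preprocessed representation: the jump-time grid and, per subject,
## grid-index bounds so every later indicator test is an integer comparison.
##
## Index semantics (grid t_1 < ... < t_K, cs0 = c(0, cumsum(lam))):
##   iAlt  = #{k : t_k <  A_i}   -> sums over A_i <= t_k <= x are
##                                  cs0[ix + 1] - cs0[iAlt + 1]
##   iAle  = #{k : t_k <= A_i}   -> pairwise indicator I(t_k <= A_i) is k <= iAle
##   iT/iL/iR = #{k : t_k <= T/L/R}; for observed endpoints these locate the
##   endpoint itself since every endpoint is a grid point.
##   iRstar = index of R* = Delta*T + (1-Delta)*(L if R=Inf else R).
lt_prep <- function(entry, status, time, lower, upper, Z) {
  Z <- as.matrix(Z)
  storage.mode(Z) <- "double"
  n <- length(entry)
  if (n < 1L) input_error("empty dataset")
  if (nrow(Z) != n) input_error("covariate rows do not match subjects")
  if (any(!is.finite(Z))) input_error("covariates must be finite and non-missing")
  validate_truncsurv(cbind(entry = entry, status = status, time = time,
                           lower = lower, upper = upper))
  ## jump support: exact event times and finite censoring-interval endpoints.
  ## Entry times are not jump candidates (mass at an entry time inside the
  ## near-empty early risk set makes the estimated hazard erratic); they
  ## enter the likelihood only through the step function's value at A_i.
  grid <- sort(unique(c(time[status == 1], lower[status == 0],
                        upper[status == 0 & is.finite(upper)])))
  K <- length(grid)
  type <- ifelse(status == 1, 1L, ifelse(is.finite(upper), 2L, 3L))
  iAlt <- findInterval(entry, grid, left.open = TRUE)
  iAle <- findInterval(entry, grid)
  ## unused endpoint indices are stored as 0 (never dereferenced)
  iT <- as.integer(ifelse(type == 1L, findInterval(time, grid), 0L))
  iL <- as.integer(ifelse(type != 1L, findInterval(lower, grid), 0L))
  iR <- as.integer(ifelse(type == 2L, findInterval(upper, grid), 0L))
  iRstar <- as.integer(ifelse(type == 1L, iT, ifelse(type == 2L, iR, iL)))
  if (any(type == 2L & iR <= iL))
    input_error("censoring interval contains no grid point")
  list(n = n, p = ncol(Z), Z = Z, grid = grid, K = K, type = type,
       entry = entry, status = status, time = time, lower = lower,
       upper = upper, iAlt = iAlt, iAle = iAle, iT = iT, iL = iL, iR = iR,
       iRstar = iRstar)
}

## Evaluate the step cumulative hazard Lambda(t) = sum_{t_k <= t} lam_k.
step_cumhaz <- function(lam, grid, t) {
  cs0 <- c(0, cumsum(lam))
  cs0[findInterval(t, grid) + 1L]
}
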