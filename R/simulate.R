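## Simulator for left-truncated follow-up studies with periodic examinations.

.calib_cache <- new.env(parent = emptyenv())

#' Describe a truncated-sampling simulation design
#'
#' Encodes the data-generating mechanisms used throughout the package's
#' Monte Carlo evaluations. Failure times follow the proportional hazards
#' model with baseline cumulative hazard `Lambda(t) = t^2` (Weibull, shape 2,
#' scale 1) and covariates `Z1 ~ Bernoulli(0.5)` and `Z2 ~ Uniform(-h, h)`
#' with `h = 0.5` for the examination schemes and `h = 1` for the
#' right-censoring scheme. Entry (truncation) times are Uniform(0, tau) or
#' Exponential(rate theta), with the parameter calibrated by Monte Carlo
#' bisection so that the truncation probability `P(T* < A*)` matches
#' `trunc_rate` (about half the population never enters at the default).
#'
#' Censoring schemes:
#' \describe{
#'   \item{`"partly-interval"`}{periodic examinations start at the entry time
#'     with gaps `0.05 + Uniform(0, 0.5)` up to the study length 1.5; the
#'     event time is bracketed by adjacent examinations, except that brackets
#'     shorter than `exact_width` (default 0.2) are recorded as exact events.}
#'   \item{`"interval"`}{same schedule, but every event is bracketed.}
#'   \item{`"right"`}{no examinations; an independent censoring time
#'     `C ~ Uniform(0, C_max)` is applied at calendar time `entry + C`, with
#'     `C_max` calibrated to a `cens_rate` right-censoring fraction.}
#' }
#'
#' @param censoring censoring scheme.
#' @param truncation entry-time distribution family.
#' @param beta true regression coefficients (default `c(1, 1)`).
#' @param trunc_rate target truncation probability (default 0.5).
#' @param cens_rate target right-censoring fraction for the `"right"` scheme
#'   (default 0.3).
#' @param gap_min,gap_spread examination gaps are `gap_min + U(0, gap_spread)`.
#' @param study_length no examinations beyond this calendar time.
#' @param exact_width brackets shorter than this are recorded exactly
#'   (`"partly-interval"` only).
#' @param base_inv inverse of the baseline cumulative hazard (default
#'   `sqrt`, matching `Lambda(t) = t^2`).
#' @param true_cumhaz the baseline cumulative hazard itself (used as the truth
#'   in [simulation_study()]).
#' @return a list of class `"sim_design"`.
#' @export
sim_design <- function(censoring = c("partly-interval", "interval", "right"),
                       truncation = c("uniform", "exponential"),
                       beta = c(1, 1), trunc_rate = 0.5, cens_rate = 0.3,
                       gap_min = 0.05, gap_spread = 0.5, study_length = 1.5,
                       exact_width = 0.2, base_inv = sqrt,
                       true_cumhaz = function(t) t^2) {
  censoring <- match.arg(censoring)
  truncation <- match.arg(truncation)
  if (trunc_rate <= 0 || trunc_rate >= 1) input_error("trunc_rate must be in (0,1)")
  if (cens_rate <= 0 || cens_rate >= 1) input_error("cens_rate must be in (0,1)")
  if (gap_min <= 0 || study_length <= 0 || exact_width <= 0)
    input_error("schedule parameters must be positive")
  z2_half <- if (censoring == "right") 1 else 0.5
  structure(list(censoring = censoring, truncation = truncation, beta = beta,
                 trunc_rate = trunc_rate, cens_rate = cens_rate,
                 gap_min = gap_min, gap_spread = gap_spread,
                 study_length = study_length, exact_width = exact_width,
                 z2_half = z2_half, base_inv = base_inv,
                 true_cumhaz = true_cumhaz,
                 label = paste(censoring, truncation, sep = "/")),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("Simulation design: %s censoring, %s truncation\n",
              x$censoring, x$truncation))
  cat(sprintf("  beta = (%s), truncation target %.0f%%\n",
              paste(x$beta, collapse = ", "), 100 * x$trunc_rate))
  if (x$censoring == "right")
    cat(sprintf("  right-censoring target %.0f%%\n", 100 * x$cens_rate))
  invisible(x)
}

draw_covariates <- function(design, n) {
  cbind(Z1 = stats::rbinom(n, 1, 0.5),
        Z2 = stats::runif(n, -design$z2_half, design$z2_half))
}

#' Draw failure times from the proportional hazards model
#'
#' Inverse-transform sampling: `T = H^{-1}(E / exp(Z'beta))` with `E` a unit
#' exponential and `H^{-1}` the inverse baseline cumulative hazard, so that
#' `S(t | Z) = exp(-H(t) exp(Z'beta))`.
#'
#' @param Z covariate matrix (one row per draw).
#' @param beta coefficient vector.
#' @param base_inv inverse baseline cumulative hazard.
#' @return vector of failure times.
#' @export
draw_failure_time <- function(Z, beta, base_inv = sqrt) {
  n <- nrow(as.matrix(Z))
  E <- stats::rexp(n)
  base_inv(E / exp(drop(as.matrix(Z) %*% beta)))
}

draw_entry <- function(design, par, n) {
  switch(design$truncation,
         uniform = stats::runif(n, 0, par),
         exponential = stats::rexp(n, rate = par))
}

calib_key <- function(design, what, nsim, mc_seed) {
  paste(what, design$censoring, design$truncation,
        paste(design$beta, collapse = ","), design$trunc_rate,
        design$cens_rate, design$z2_half, nsim, mc_seed, sep = "|")
}

#' Calibrate the entry-time distribution to a target truncation rate
#'
#' Finds, by Monte Carlo bisection with common random numbers, the
#' Uniform(0, tau) upper bound or Exponential rate such that the truncation
#' probability `P(T* < A*)` under the design equals `design$trunc_rate`.
#' Results are cached per design and are deterministic given `mc_seed`; the
#' caller's RNG stream is left untouched.
#'
#' @param design a [sim_design()].
#' @param nsim Monte Carlo draws per bisection evaluation.
#' @param tol tolerance on the achieved rate.
#' @param mc_seed internal seed for the calibration sample.
#' @return the calibrated parameter (tau or theta).
#' @export
calibrate_truncation <- function(design, nsim = 1e5, tol = 0.005,
                                 mc_seed = 20230404L) {
  key <- calib_key(design, "trunc", nsim, mc_seed)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  par <- with_preserved_rng({
    set.seed(mc_seed)
    Z <- draw_covariates(design, nsim)
    Tstar <- draw_failure_time(Z, design$beta, design$base_inv)
    U <- stats::runif(nsim)
    rate_at <- function(par) {
      A <- switch(design$truncation,
                  uniform = par * U,
                  exponential = stats::qexp(U, rate = par))
      mean(Tstar < A)
    }
    increasing <- design$truncation == "uniform"
    lo <- 1e-6; hi <- 1
    expand <- function(h) if (increasing) rate_at(h) < design$trunc_rate
      else rate_at(h) > design$trunc_rate
    while (expand(hi) && hi < 1e6) hi <- hi * 2
    if (hi >= 1e6) input_error("truncation target unattainable")
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      r <- rate_at(mid)
      if (abs(r - design$trunc_rate) <= tol) { lo <- hi <- mid; break }
      up <- if (increasing) r < design$trunc_rate else r > design$trunc_rate
      if (up) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  .calib_cache[[key]] <- par
  par
}

#' Calibrate the right-censoring bound to a target censoring rate
#'
#' For the `"right"` scheme: finds `C_max` such that the fraction of accepted
#' (non-truncated) subjects with `T > A + C`, `C ~ Uniform(0, C_max)`,
#' matches `design$cens_rate`. Monte Carlo bisection with common random
#' numbers, cached and deterministic as in [calibrate_truncation()].
#'
#' @inheritParams calibrate_truncation
#' @return the calibrated `C_max`.
#' @export
calibrate_censoring <- function(design, nsim = 1e5, tol = 0.005,
                                mc_seed = 20230405L) {
  if (design$censoring != "right")
    input_error("censoring calibration applies to the right-censoring scheme")
  key <- calib_key(design, "cens", nsim, mc_seed)
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])
  trunc_par <- calibrate_truncation(design)
  cmax <- with_preserved_rng({
    set.seed(mc_seed)
    Z <- draw_covariates(design, 3L * nsim)
    Tstar <- draw_failure_time(Z, design$beta, design$base_inv)
    A <- draw_entry(design, trunc_par, 3L * nsim)
    keep <- Tstar >= A
    Tk <- Tstar[keep][seq_len(min(nsim, sum(keep)))]
    Ak <- A[keep][seq_len(length(Tk))]
    U <- stats::runif(length(Tk))
    rate_at <- function(cmax) mean(Tk > Ak + cmax * U)  # decreasing in cmax
    lo <- 1e-6; hi <- 1
    while (rate_at(hi) > design$cens_rate && hi < 1e6) hi <- hi * 2
    if (hi >= 1e6) input_error("censoring target unattainable")
    for (i in 1:60) {
      mid <- (lo + hi) / 2
      r <- rate_at(mid)
      if (abs(r - design$cens_rate) <= tol) { lo <- hi <- mid; break }
      if (r > design$cens_rate) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  })
  .calib_cache[[key]] <- cmax
  cmax
}

#' Simulate a left-truncated censored dataset
#'
#' Draws subjects from the design's truncated joint law by acceptance
#' sampling (a candidate `(Z, T*, A*)` is kept only when `T* >= A*`) and
#' applies the design's censoring scheme; see [sim_design()] for the
#' mechanisms. The output is a data frame in the package's standard layout
#' (`id, A, delta, T, L, R, Z1, ..., Zp`) ready for [truncph()] or
#' [write_ltdata()].
#'
#' @param design a [sim_design()].
#' @param n number of accepted subjects.
#' @param seed integer seed; output is reproducible given the seed.
#' @return a data frame with `n` rows.
#' @export
simulate_ltdata <- function(design, n, seed = 1L) {
  if (n < 1L) input_error("n must be >= 1")
  trunc_par <- calibrate_truncation(design)
  cmax <- if (design$censoring == "right") calibrate_censoring(design) else NULL
  set.seed(seed)
  ## acceptance sampling from the truncated joint law
  Zs <- NULL; Ts <- numeric(0); As <- numeric(0)
  while (length(Ts) < n) {
    m <- max(2L * n, 64L)
    Z <- draw_covariates(design, m)
    Tstar <- draw_failure_time(Z, design$beta, design$base_inv)
    A <- draw_entry(design, trunc_par, m)
    keep <- Tstar >= A
    Zs <- rbind(Zs, Z[keep, , drop = FALSE])
    Ts <- c(Ts, Tstar[keep]); As <- c(As, A[keep])
  }
  Zs <- Zs[seq_len(n), , drop = FALSE]
  Ts <- Ts[seq_len(n)]; As <- As[seq_len(n)]
  delta <- integer(n)
  Tobs <- L <- R <- rep(NA_real_, n)
  if (design$censoring == "right") {
    C <- stats::runif(n, 0, cmax)
    cens <- As + C
    ev <- Ts <= cens
    delta[ev] <- 1L
    Tobs[ev] <- Ts[ev]
    L[!ev] <- cens[!ev]; R[!ev] <- Inf
  } else {
    for (i in seq_len(n)) {
      exams <- As[i]
      s <- As[i]
      repeat {
        s <- s + design$gap_min + stats::runif(1, 0, design$gap_spread)
        if (s > design$study_length) break
        exams <- c(exams, s)
      }
      j <- findInterval(Ts[i], exams, left.open = TRUE)  # exams[j] < T
      if (j >= length(exams)) {          # event past the last examination
        delta[i] <- 0L
        L[i] <- exams[length(exams)]; R[i] <- Inf
      } else {
        j <- max(j, 1L)                  # T == A lands in the first bracket
        Li <- exams[j]; Ri <- exams[j + 1L]
        if (design$censoring == "partly-interval" &&
            (Ri - Li) < design$exact_width) {
          delta[i] <- 1L
          Tobs[i] <- Ts[i]
        } else {
          delta[i] <- 0L
          L[i] <- Li; R[i] <- Ri
        }
      }
    }
  }
  out <- data.frame(id = seq_len(n), A = As, delta = delta, T = Tobs,
                    L = L, R = R)
  out <- cbind(out, as.data.frame(Zs))
  validate_truncsurv(cbind(entry = out$A, status = out$delta, time = out$T,
                           lower = out$L, upper = out$R))
  out
}
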