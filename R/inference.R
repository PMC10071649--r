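#' Nonparametric bootstrap standard errors
#'
#' Resamples subjects with replacement, refits the model on every resample
#' (the jump-time grid is rebuilt per resample), and returns the sample
#' standard deviation of the estimates over converged resamples.
#'
#' @param object a [truncph()] fit.
#' @param B number of bootstrap resamples (>= 2).
#' @param eval_times times at which to bootstrap the baseline cumulative
#'   hazard (optional).
#' @param seed integer seed; results are reproducible given the seed.
#' @return a list of class `"truncph_boot"` with `se_beta`, `se_cumhaz`
#'   (named by `eval_times`), the resample draws, `B`, and `n_failed`, the
#'   number of non-converged resamples (excluded from the standard errors
#'   with a warning).
#' @export
truncph_boot <- function(object, B = 100L, eval_times = NULL, seed = 1L) {
  if (!inherits(object, "truncph")) input_error("object must be a truncph fit")
  if (B < 2L) input_error("B must be >= 2")
  n <- object$n
  set.seed(seed)
  idx <- matrix(sample.int(n, n * B, replace = TRUE), nrow = n, ncol = B)
  p <- length(object$coefficients)
  bet <- matrix(NA_real_, B, p, dimnames = list(NULL, names(object$coefficients)))
  ch <- matrix(NA_real_, B, length(eval_times))
  ok <- logical(B)
  ## warm start: a resample's jump grid is a subset of the original grid, so
  ## the fitted parameters transfer as initial values (floored at a tiny
  ## positive value to keep every censoring interval's initial mass positive)
  ctrl <- object$control
  ctrl$init_beta <- as.numeric(object$coefficients)
  lam_lookup <- function(grid_new) {
    v <- object$lambda[match(grid_new, object$times)]
    v[is.na(v)] <- 1 / length(grid_new)
    pmax(v, 1e-8)
  }
  for (b in seq_len(B)) {
    fb <- tryCatch({
      rows <- idx[, b]
      d <- object$data
      prep_b <- lt_prep(if (object$method == "ignore-truncation")
        rep(0, length(rows)) else d$entry[rows],
        d$status[rows], d$time[rows], d$lower[rows], d$upper[rows],
        d$Z[rows, , drop = FALSE])
      ctrl_b <- ctrl
      ctrl_b$trace_objective <- FALSE
      ctrl_b$init_lambda <- lam_lookup(prep_b$grid)
      em <- em_fit(prep_b, object$method, ctrl_b)
      list(coefficients = em$beta, lambda = em$lambda, times = prep_b$grid,
           converged = em$converged)
    }, error = function(e) NULL)
    if (is.null(fb) || !fb$converged) next
    ok[b] <- TRUE
    bet[b, ] <- fb$coefficients
    if (length(eval_times))
      ch[b, ] <- step_cumhaz(fb$lambda, fb$times, eval_times)
  }
  if (!any(ok)) stop("all bootstrap resamples failed to converge")
  n_failed <- sum(!ok)
  if (n_failed > 0L)
    warning(sprintf("%d of %d bootstrap resamples failed and were excluded",
                    n_failed, B))
  se_beta <- apply(bet[ok, , drop = FALSE], 2, stats::sd)
  se_cumhaz <- if (length(eval_times))
    stats::setNames(apply(ch[ok, , drop = FALSE], 2, stats::sd),
                    as.character(eval_times)) else numeric(0)
  structure(list(se_beta = se_beta, se_cumhaz = se_cumhaz,
                 eval_times = eval_times, B = B, n_failed = n_failed,
                 beta = bet[ok, , drop = FALSE],
                 cumhaz = ch[ok, , drop = FALSE], seed = seed),
            class = "truncph_boot")
}

#' @export
print.truncph_boot <- function(x, digits = 4, ...) {
  cat(sprintf("Bootstrap (B = %d, %d failed)\n", x$B, x$n_failed))
  cat("SE(beta):\n"); print(round(x$se_beta, digits))
  if (length(x$se_cumhaz)) {
    cat("SE(cumulative hazard):\n"); print(round(x$se_cumhaz, digits))
  }
  invisible(x)
}

#' Log-transformed confidence interval for a cumulative hazard value
#'
#' Computes `[L exp(-z s/L), L exp(z s/L)]` for an estimate `L` with standard
#' error `s`, the delta-method interval on the log scale that respects the
#' positivity of the cumulative hazard.
#'
#' @param cumhaz point estimate `L >= 0`; when 0 the degenerate interval
#'   `[0, 0]` is returned with a warning.
#' @param se standard error of the estimate.
#' @param level confidence level in (0, 1).
#' @return length-2 vector `(lower, upper)`.
#' @examples
#' cumhaz_ci(1, 0.1)
#' @export
cumhaz_ci <- function(cumhaz, se, level = 0.95) {
  if (level <= 0 || level >= 1) input_error("level must be in (0, 1)")
  if (se < 0) input_error("se must be >= 0")
  if (cumhaz <= 0) {
    if (cumhaz < 0) input_error("cumhaz must be >= 0")
    warning("cumulative hazard estimate is 0; returning a degenerate interval")
    return(c(lower = 0, upper = 0))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(lower = cumhaz * exp(-z * se / cumhaz),
    upper = cumhaz * exp(z * se / cumhaz))
}

#' Wald test for a single parameter
#'
#' @param est point estimate.
#' @param se positive standard error.
#' @return list with the z statistic and the two-sided normal p-value.
#' @examples
#' wald_test(0.122, 0.060)
#' @export
wald_test <- function(est, se) {
  if (!is.numeric(se) || se <= 0) input_error("se must be > 0")
  z <- est / se
  list(z = z, p.value = 2 * stats::pnorm(-abs(z)))
}

#' Monte Carlo evaluation of the estimators on a simulation design
#'
#' Generates `reps` datasets from `design`, fits the requested estimator
#' variants to each, and summarises per parameter (each regression
#' coefficient and the baseline cumulative hazard at `eval_times`): Bias
#' (mean estimate minus truth), SSE (sample standard deviation of the
#' estimates), and — when `B > 0` — SEE (mean bootstrap standard error) and
#' CP (% of nominal `level` normal confidence intervals covering the truth;
#' cumulative-hazard intervals use [cumhaz_ci()]).
#'
#' @param design a [sim_design()] object.
#' @param n subjects per replicate.
#' @param reps number of replicates (>= 2).
#' @param methods estimator variants to fit (all see the same datasets).
#' @param B bootstrap resamples per replicate (0 skips SEE/CP).
#' @param eval_times cumulative-hazard evaluation times.
#' @param level nominal confidence level.
#' @param seed integer seed; replicate seed streams are split from it so the
#'   whole summary is reproducible.
#' @param control fit control; the objective trace is disabled by default
#'   for speed.
#' @return a data frame with columns design, method, n, parameter, truth,
#'   bias, sse, see, cp; replicate-level estimates are attached as attribute
#'   `"estimates"` and non-converged counts as `"n_excluded"`. An error is
#'   raised if more than 10% of a method's replicates fail to converge.
#' @export
simulation_study <- function(design, n, reps,
                             methods = c("pairwise", "conditional",
                                         "ignore-truncation"),
                             B = 0L, eval_times = c(0.4, 0.8, 1.2),
                             level = 0.95, seed = 1L,
                             control = truncph_control(trace_objective = FALSE)) {
  if (reps < 2L) input_error("reps must be >= 2")
  methods <- match.arg(methods, several.ok = TRUE)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  boot_seeds <- sample.int(.Machine$integer.max - 1L, reps)
  pars <- c(paste0("beta", seq_along(design$beta)),
            if (length(eval_times)) paste0("cumhaz_", eval_times))
  truth <- c(design$beta, if (length(eval_times)) design$true_cumhaz(eval_times))
  est <- array(NA_real_, c(reps, length(pars), length(methods)),
               dimnames = list(NULL, pars, methods))
  see <- cov <- est
  z <- stats::qnorm(1 - (1 - level) / 2)
  for (r in seq_len(reps)) {
    dat <- simulate_ltdata(design, n, seed = rep_seeds[r])
    Z <- as.matrix(dat[, grep("^Z", names(dat)), drop = FALSE])
    for (m in methods) {
      fit <- tryCatch(
        truncph_fit(dat$A, dat$delta, dat$T, dat$L, dat$R, Z,
                    method = m, control = control),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      ev <- if (length(eval_times))
        step_cumhaz(fit$lambda, fit$times, eval_times) else numeric(0)
      est[r, , m] <- c(fit$coefficients, ev)
      if (B > 0L) {
        bt <- tryCatch(truncph_boot(fit, B = B, eval_times = eval_times,
                                    seed = boot_seeds[r]),
                       error = function(e) NULL)
        if (!is.null(bt)) {
          ses <- c(bt$se_beta, bt$se_cumhaz)
          see[r, , m] <- ses
          np <- length(design$beta)
          covb <- abs(est[r, seq_len(np), m] - truth[seq_len(np)]) <=
            z * ses[seq_len(np)]
          covl <- if (length(eval_times)) {
            mapply(function(e1, s1, tr) {
              ci <- suppressWarnings(cumhaz_ci(e1, s1, level))
              tr >= ci[1] && tr <= ci[2]
            }, est[r, -seq_len(np), m], ses[-seq_len(np)], truth[-seq_len(np)])
          } else logical(0)
          cov[r, , m] <- c(covb, covl)
        }
      }
    }
  }
  rows <- list()
  n_excl <- stats::setNames(integer(length(methods)), methods)
  for (m in methods) {
    ok <- !is.na(est[, 1, m])
    n_excl[m] <- sum(!ok)
    if (n_excl[m] > 0.1 * reps)
      stop(sprintf("method %s: %d of %d replicates failed to converge",
                   m, n_excl[m], reps))
    for (j in seq_along(pars)) {
      e <- est[ok, j, m]
      rows[[length(rows) + 1L]] <- data.frame(
        design = design$label, method = m, n = n, parameter = pars[j],
        truth = truth[j], bias = mean(e) - truth[j], sse = stats::sd(e),
        see = if (B > 0L) mean(see[ok, j, m], na.rm = TRUE) else NA_real_,
        cp = if (B > 0L) 100 * mean(cov[ok, j, m], na.rm = TRUE) else NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "estimates") <- est
  attr(out, "see") <- see
  attr(out, "n_excluded") <- n_excl
  attr(out, "seed") <- seed
  out
}
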