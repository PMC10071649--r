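#' Control parameters for the EM fit
#'
#' @param tol convergence threshold: iteration stops when the sum of absolute
#'   differences between successive estimates of all parameters (regression
#'   coefficients and every hazard jump) drops below `tol`.
#' @param max_iter iteration cap; reaching it returns a non-converged fit
#'   rather than an error. The EM trades per-iteration cost for iteration
#'   count (closed-form updates, sublinear tail convergence), so the default
#'   cap is generous.
#' @param init_beta optional initial coefficient vector (default all zero).
#' @param init_lambda optional initial jump sizes (default `1/K` at each of
#'   the `K` grid points).
#' @param lam_floor small positive value substituted when a closed-form jump
#'   update turns negative; activations are reported in the fit's warnings.
#' @param trace_objective record the composite objective at every iteration
#'   (costs an extra O(n^2) pass per iteration; Monte Carlo drivers turn it
#'   off).
#' @param newton_damping step factor for the damped ascent fallback used when
#'   the Newton system for the coefficients is singular.
#' @return a list of class `"truncph_control"`.
#' @export
truncph_control <- function(tol = 1e-3, max_iter = 10000L, init_beta = NULL,
                            init_lambda = NULL, lam_floor = 1e-10,
                            trace_objective = TRUE, newton_damping = 0.5) {
  if (!is.numeric(tol) || tol <= 0) input_error("tol must be > 0")
  if (max_iter < 1) input_error("max_iter must be >= 1")
  if (lam_floor <= 0) input_error("lam_floor must be > 0")
  structure(list(tol = tol, max_iter = as.integer(max_iter),
                 init_beta = init_beta, init_lambda = init_lambda,
                 lam_floor = lam_floor, trace_objective = trace_objective,
                 newton_damping = newton_damping),
            class = "truncph_control")
}

#' Cox regression for left-truncated data under general censoring
#'
#' Fits the proportional hazards model `Lambda(t | Z) = Lambda(t) exp(Z'beta)`
#' to left-truncated failure time data observed under right, interval, left,
#' or partly interval censoring. The baseline cumulative hazard is a step
#' function with jumps at every observed entry, examination, and event time;
#' jumps and coefficients are estimated jointly by nonparametric maximum
#' (pseudo-)likelihood via an EM algorithm with Poisson data augmentation.
#'
#' Three estimators are available. `"pairwise"` (the default) augments the
#' conditional likelihood of the event data with the pairwise pseudo-likelihood
#' of the observed entry times, which carries information about the survival
#' parameters from the truncation mechanism while the unknown entry-time
#' density cancels pair by pair. `"conditional"` maximises the conditional
#' likelihood alone. `"ignore-truncation"` sets every entry time to zero and
#' fits the plain NPMLE, which is biased under truncation and included for
#' comparison.
#'
#' @param formula a model formula whose response is a [TruncSurv()] object,
#'   e.g. `TruncSurv(A, delta, T, L, R) ~ Z1 + Z2`.
#' @param data a data frame containing the variables in the formula, e.g. as
#'   returned by [simulate_ltdata()] or [read_ltdata()].
#' @param method estimator variant, see Details.
#' @param control a [truncph_control()] list.
#' @return an object of class `"truncph"` with components `coefficients`,
#'   `lambda` (jump sizes), `times` (jump locations), `cumhaz` (their cumsum),
#'   `converged`, `n_iter`, `objective` (composite-objective trace), `method`,
#'   `warnings`, and the data needed for bootstrapping.
#' @seealso [truncph_boot()] for standard errors, [predict.truncph()],
#'   [simulate_ltdata()].
#' @examples
#' d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 80,
#'                      seed = 7)
#' fit <- truncph(TruncSurv(A, delta, T, L, R) ~ Z1 + Z2, data = d)
#' coef(fit)
#' predict(fit, times = c(0.4, 0.8, 1.2))
#' @export
truncph <- function(formula, data,
                    method = c("pairwise", "conditional", "ignore-truncation"),
                    control = truncph_control()) {
  method <- match.arg(method)
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  y <- stats::model.response(mf)
  if (!inherits(y, "TruncSurv"))
    input_error("the formula response must be a TruncSurv() object")
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  if (ncol(X) < 1L) input_error("at least one covariate is required")
  fit <- truncph_fit(entry = y[, "entry"], status = y[, "status"],
                     time = y[, "time"], lower = y[, "lower"],
                     upper = y[, "upper"], Z = X,
                     method = method, control = control)
  fit$call <- cl
  fit$formula <- formula
  fit
}

#' Workhorse fitter on raw vectors
#'
#' Lower-level interface behind [truncph()], taking the subject-level vectors
#' directly (in the same encoding as [TruncSurv()]).
#'
#' @inheritParams TruncSurv
#' @param Z numeric covariate matrix (one row per subject).
#' @param method,control as in [truncph()].
#' @return an object of class `"truncph"`.
#' @export
truncph_fit <- function(entry, status, time, lower, upper, Z,
                        method = c("pairwise", "conditional",
                                   "ignore-truncation"),
                        control = truncph_control()) {
  method <- match.arg(method)
  Z <- as.matrix(Z)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("Z", seq_len(ncol(Z)))
  entry_fit <- if (method == "ignore-truncation") rep(0, length(entry)) else entry
  prep <- lt_prep(entry_fit, status, time, lower, upper, Z)
  em <- em_fit(prep, method, control)
  beta <- stats::setNames(em$beta, colnames(Z))
  structure(list(coefficients = beta, lambda = em$lambda, times = prep$grid,
                 cumhaz = cumsum(em$lambda), converged = em$converged,
                 n_iter = em$n_iter, objective = em$objective,
                 n_floored = em$n_floored, warnings = em$warnings,
                 method = method, control = control, n = prep$n,
                 nevent = sum(status == 1),
                 data = list(entry = entry, status = status, time = time,
                             lower = lower, upper = upper, Z = Z)),
            class = "truncph")
}

## Refit on a row subset with the same method/control (bootstrap path).
refit_rows <- function(object, rows, control = NULL) {
  d <- object$data
  control <- control %||% object$control
  control$trace_objective <- FALSE
  truncph_fit(d$entry[rows], d$status[rows], d$time[rows], d$lower[rows],
              d$upper[rows], d$Z[rows, , drop = FALSE],
              method = object$method, control = control)
}

#' @export
print.truncph <- function(x, digits = 4, ...) {
  if (!is.null(x$call)) {
    cat("Call:\n"); print(x$call); cat("\n")
  }
  cat(sprintf("Left-truncated PH fit (%s), n = %d (%d exact events)\n",
              x$method, x$n, x$nevent))
  cat("Coefficients:\n")
  print(round(x$coefficients, digits))
  cat(sprintf("Baseline hazard: %d jumps on [%g, %g]\n",
              length(x$lambda), min(x$times), max(x$times)))
  cat(sprintf("EM iterations: %d (%s)\n", x$n_iter,
              if (x$converged) "converged" else "NOT converged"))
  if (length(x$warnings)) cat("Warnings:", paste(x$warnings, collapse = "; "),
                              "\n")
  invisible(x)
}

#' Summarise a truncph fit
#'
#' With a bootstrap result, prints a coefficient table with standard errors,
#' Wald z statistics and two-sided normal p-values, plus log-transformed
#' confidence intervals for the cumulative hazard at the bootstrap evaluation
#' times.
#'
#' @param object a [truncph()] fit.
#' @param boot optional [truncph_boot()] result for the same fit.
#' @param level confidence level for the cumulative-hazard intervals.
#' @param ... unused.
#' @export
summary.truncph <- function(object, boot = NULL, level = 0.95, ...) {
  est <- object$coefficients
  if (!is.null(boot)) {
    se <- boot$se_beta
    z <- est / se
    tab <- cbind(Est = est, Std = se, z = z,
                 `p-value` = 2 * stats::pnorm(-abs(z)))
  } else {
    tab <- cbind(Est = est)
  }
  ch <- NULL
  if (!is.null(boot) && length(boot$eval_times)) {
    Lhat <- step_cumhaz(object$lambda, object$times, boot$eval_times)
    ci <- t(mapply(cumhaz_ci, Lhat, boot$se_cumhaz,
                   MoreArgs = list(level = level)))
    ch <- cbind(time = boot$eval_times, cumhaz = Lhat, se = boot$se_cumhaz,
                lower = ci[, 1], upper = ci[, 2])
  }
  structure(list(call = object$call, method = object$method, n = object$n,
                 coefficients = tab, cumhaz = ch, converged = object$converged,
                 n_iter = object$n_iter, B = boot$B, n_failed = boot$n_failed),
            class = "summary.truncph")
}

#' @export
print.summary.truncph <- function(x, digits = 4, ...) {
  cat(sprintf("Left-truncated PH fit (%s), n = %d\n\n", x$method, x$n))
  stats::printCoefmat(x$coefficients, digits = digits,
                      has.Pvalue = "p-value" %in% colnames(x$coefficients))
  if (!is.null(x$cumhaz)) {
    cat("\nBaseline cumulative hazard:\n")
    print(round(x$cumhaz, digits))
  }
  if (!is.null(x$B))
    cat(sprintf("\nBootstrap: B = %d (%d resample(s) failed)\n",
                x$B, x$n_failed))
  invisible(x)
}

#' @export
coef.truncph <- function(object, ...) object$coefficients

#' Predict from a truncph fit
#'
#' @param object a [truncph()] fit.
#' @param times evaluation times.
#' @param newdata optional data frame of covariates; when omitted the baseline
#'   (all covariates zero) is used.
#' @param type `"cumhaz"` for the cumulative hazard `Lambda(t) exp(Z'beta)`,
#'   `"survival"` for `exp(-Lambda(t) exp(Z'beta))`.
#' @param ... unused.
#' @return a numeric vector (baseline) or a matrix with one row per `newdata`
#'   row and one column per time.
#' @export
predict.truncph <- function(object, times, newdata = NULL,
                            type = c("cumhaz", "survival"), ...) {
  type <- match.arg(type)
  base <- step_cumhaz(object$lambda, object$times, times)
  if (is.null(newdata)) {
    out <- base
    names(out) <- as.character(times)
  } else {
    Z <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
    risk <- exp(drop(Z %*% object$coefficients))
    out <- outer(risk, base)
    dimnames(out) <- list(rownames(newdata), as.character(times))
  }
  if (type == "survival") out <- exp(-out)
  out
}

#' Plot the estimated baseline cumulative hazard
#'
#' @param x a [truncph()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.truncph <- function(x, ...) {
  f <- stats::stepfun(x$times, c(0, x$cumhaz))
  graphics::plot(f, do.points = FALSE, xlab = "t",
                 ylab = expression(hat(Lambda)(t)),
                 main = sprintf("Baseline cumulative hazard (%s)", x$method),
                 ...)
  invisible(x)
}

#' @export
logLik.truncph <- function(object, ...) {
  prep <- with(object$data,
               lt_prep(if (object$method == "ignore-truncation")
                 rep(0, length(entry)) else entry,
                 status, time, lower, upper, Z))
  val <- as.numeric(cond_loglik(object$coefficients, object$lambda, prep))
  structure(val, df = length(object$coefficients) + length(object$lambda),
            nobs = object$n, class = "logLik")
}
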