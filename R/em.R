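## EM machinery: Poisson-augmentation E-step, closed-form jump updates,
## composite score and one-step Newton update for the regression coefficients.
## The O(n^2) pair sums behind the pairwise terms are computed in compiled
## code (src/pairwise.cpp).

## E-step summaries at the current (beta, lam). For each subject the latent
## Poisson counts W_ik live on the window A_i <= t_k <= R*_i; their
## conditional means are
##   exact:            0 before T_i, 1 at T_i;
##   censored, R<Inf:  0 on [A_i, L_i], lam_k e^{Z'b} / (1 - exp(-mu_i))
##                     on (L_i, R_i] with mu_i the window mass (left censoring
##                     is the special case L_i = A_i);
##   censored, R=Inf:  0 on the whole window.
## Returns the per-subject multiplier cI (so e_ik = lam_k * cI_i on the
## positive region) and the expected window total Wi.
estep_coefs <- function(beta, lam, prep) {
  eta <- drop(prep$Z %*% beta)
  ee <- exp(eta)
  cs0 <- c(0, cumsum(lam))
  n <- prep$n
  Wi <- numeric(n)
  cI <- numeric(n)
  Wi[prep$type == 1L] <- 1
  ic <- which(prep$type == 2L)
  if (length(ic)) {
    csd <- cs0[prep$iR[ic] + 1L] - cs0[prep$iL[ic] + 1L]
    mu <- ee[ic] * csd
    c1 <- ifelse(mu > 0, ee[ic] / (-expm1(-mu)), 0)
    ## mass underflow: fall back to the mu -> 0 limit lam_k / sum(lam) so the
    ## M-step numerator stays defined
    tiny <- mu < 1e-300
    c1[tiny] <- ifelse(csd[tiny] > 0, 1 / csd[tiny], 0)
    cI[ic] <- c1
    Wi[ic] <- c1 * csd
  }
  list(eta = eta, ee = ee, Wi = Wi, cI = cI)
}

## Full per-subject E(W_ik) vectors (index k over the subject's window);
## used by tests and diagnostics, not by the fast fitting path.
estep_expectations <- function(beta, lam, prep) {
  co <- estep_coefs(beta, lam, prep)
  lapply(seq_len(prep$n), function(i) {
    ks <- seq.int(prep$iAlt[i] + 1L, prep$iRstar[i])
    e <- numeric(length(ks))
    if (prep$type[i] == 1L) {
      e[ks == prep$iT[i]] <- 1
    } else if (prep$type[i] == 2L) {
      pos <- ks > prep$iL[i]
      e[pos] <- lam[ks[pos]] * co$cI[i]
    }
    data.frame(k = ks, t = prep$grid[ks], e = e)
  })
}

## One compiled pass over all subject pairs at the supplied (beta, lam):
## the jump-update denominator term P_k, the U_beta pair term and (optionally)
## its beta-derivative, and the pairwise log-likelihood.
pair_stats <- function(beta, lam, prep, want_jac = FALSE) {
  ee <- exp(drop(prep$Z %*% beta))
  cs0 <- c(0, cumsum(lam))
  LamA <- cs0[prep$iAle + 1L]
  pair_terms(LamA, ee, prep$Z, as.integer(prep$iAle), prep$K, want_jac)
}

## Closed-form self-consistent update of each jump lam_k; `pt` carries the
## pairwise denominator term evaluated at the pre-update parameters.
update_lambda <- function(co, beta, lam, prep, pairwise, lam_floor = 1e-10,
                          pt = NULL) {
  n <- prep$n; K <- prep$K
  Nk <- index_sum(prep$iT[prep$type == 1L],
                  rep(1, sum(prep$type == 1L)), K)
  ic <- which(prep$type == 2L & co$cI > 0)
  if (length(ic)) {
    cvec <- range_sum(prep$iL[ic] + 1L, prep$iR[ic], co$cI[ic], K)
    Nk <- Nk + lam * cvec
  }
  rvec <- range_sum(prep$iAlt + 1L, prep$iRstar, co$ee, K)
  den <- rvec / n
  if (pairwise && n > 1L) {
    pt <- pt %||% pair_stats(beta, lam, prep)
    den <- den + pt$P / (n * (n - 1))
  }
  num <- Nk / n
  if (any(num > 0 & den == 0))
    stop(sprintf("zero at-risk denominator with positive mass at t = %g",
                 prep$grid[which(num > 0 & den == 0)[1L]]))
  lam_new <- ifelse(num > 0, num / den, 0)
  nfloor <- sum(lam_new < 0)
  lam_new[lam_new < 0] <- lam_floor
  list(lam = lam_new, nfloor = nfloor)
}

## Composite score U_beta at (beta, lam) with E(W) fixed from the E-step.
score_beta <- function(co, beta, lam, prep, pairwise, pt = NULL) {
  n <- prep$n
  ee <- exp(drop(prep$Z %*% beta))
  cs0 <- c(0, cumsum(lam))
  Lwin <- cs0[prep$iRstar + 1L] - cs0[prep$iAlt + 1L]
  U <- colSums(prep$Z * (co$Wi - ee * Lwin)) / n
  if (pairwise && n > 1L) {
    pt <- pt %||% pair_stats(beta, lam, prep)
    U <- U - pt$score / (n * (n - 1))
  }
  U
}

## Analytic Jacobian dU_beta/dbeta (E(W) and lam held fixed; the pair
## weights' dependence on beta is included).
jacobian_beta <- function(co, beta, lam, prep, pairwise, pt = NULL) {
  n <- prep$n
  ee <- exp(drop(prep$Z %*% beta))
  cs0 <- c(0, cumsum(lam))
  Lwin <- cs0[prep$iRstar + 1L] - cs0[prep$iAlt + 1L]
  J <- -crossprod(prep$Z * (ee * Lwin), prep$Z) / n
  if (pairwise && n > 1L) {
    pt <- pt %||% pair_stats(beta, lam, prep, want_jac = TRUE)
    J <- J - pt$jac / (n * (n - 1))
  }
  J
}

## One Newton-Raphson step for beta; falls back to a damped ascent step along
## U when the Jacobian is unusable.
newton_step_beta <- function(co, beta, lam, prep, pairwise, damping = 0.5) {
  pt <- if (pairwise && prep$n > 1L) pair_stats(beta, lam, prep, TRUE)
  U <- score_beta(co, beta, lam, prep, pairwise, pt)
  J <- jacobian_beta(co, beta, lam, prep, pairwise, pt)
  step <- tryCatch(solve(J, U), error = function(e) NULL)
  if (is.null(step) || !all(is.finite(step))) {
    return(list(beta = beta + damping * U, fallback = TRUE))
  }
  list(beta = beta - step, fallback = FALSE)
}

## One EM iteration via the reference R implementation (E-step, jump update,
## one-step Newton). The compiled engine reproduces exactly this arithmetic;
## tests assert the two paths agree.
em_iterate_r <- function(beta, lam, prep, pairwise, control) {
  co <- estep_coefs(beta, lam, prep)
  pt_old <- if (pairwise && prep$n > 1L) pair_stats(beta, lam, prep)
  upd <- update_lambda(co, beta, lam, prep, pairwise, control$lam_floor,
                       pt_old)
  st <- newton_step_beta(co, beta, upd$lam, prep, pairwise,
                         control$newton_damping)
  list(beta = st$beta, lambda = upd$lam,
       delta = sum(abs(st$beta - beta)) + sum(abs(upd$lam - lam)),
       nfloor = upd$nfloor, nfallback = as.integer(st$fallback))
}

em_engine <- function(beta, lam, prep, pairwise, control, maxit) {
  em_run(prep$Z, prep$type, prep$iAlt, prep$iAle, prep$iT, prep$iL, prep$iR,
         prep$iRstar, prep$K, beta, lam, pairwise, control$tol, maxit,
         control$lam_floor, control$newton_damping)
}

## EM driver. method: "pairwise" keeps the pairwise terms in both updates;
## "conditional" (and "ignore-truncation", whose entry times were zeroed
## upstream) drops them. The untraced path runs entirely in compiled code;
## with trace_objective the engine is advanced one iteration at a time so the
## composite objective can be recorded.
em_fit <- function(prep, method, control) {
  pairwise <- method == "pairwise"
  p <- prep$p; K <- prep$K
  beta <- control$init_beta %||% rep(0, p)
  lam <- control$init_lambda %||% rep(1 / K, K)
  if (length(beta) != p || length(lam) != K)
    input_error("initial values have the wrong dimension")
  if (any(lam < 0)) input_error("initial jump sizes must be non-negative")
  ll0 <- cond_loglik(beta, lam, prep)
  if (!is.finite(ll0))
    input_error("conditional log-likelihood is -Inf at the initial values")
  nfloor <- 0L
  nfallback <- 0L
  if (control$trace_objective) {
    trace_obj <- composite_objective(beta, lam, prep)
    converged <- FALSE
    it <- 0L
    while (it < control$max_iter) {
      res <- em_engine(beta, lam, prep, pairwise, control, 1L)
      it <- it + 1L
      beta <- res$beta
      lam <- res$lambda
      nfloor <- nfloor + res$nfloor
      nfallback <- nfallback + res$nfallback
      trace_obj <- c(trace_obj, composite_objective(beta, lam, prep))
      if (res$converged) { converged <- TRUE; break }
    }
  } else {
    res <- em_engine(beta, lam, prep, pairwise, control, control$max_iter)
    beta <- res$beta
    lam <- res$lambda
    it <- res$n_iter
    converged <- res$converged
    nfloor <- res$nfloor
    nfallback <- res$nfallback
    trace_obj <- composite_objective(beta, lam, prep)
  }
  warn <- character(0)
  if (nfloor > 0L)
    warn <- c(warn, sprintf("%d negative jump update(s) clamped to the floor",
                            nfloor))
  if (nfallback > 0L)
    warn <- c(warn, sprintf("%d damped-gradient fallback step(s) for beta",
                            nfallback))
  list(beta = beta, lambda = lam, converged = converged, n_iter = it,
       objective = trace_obj, n_floored = nfloor, warnings = warn)
}
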