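test_that("E-step means match the constrained-Poisson conditional expectations", {
  # exact event: zero before the event time, one at it
  pr <- manual_prep(grid = c(0.3, 0.5, 0.8), A = 0.1, delta = 1, T = 0.8,
                    Z = matrix(0.5, 1, 1))
  e <- truncph:::estep_expectations(0.2, c(0.1, 0.2, 0.3), pr)[[1]]
  expect_equal(e$e, c(0, 0, 1))

  # right censoring: zero on the whole window
  pr <- manual_prep(grid = c(0.3, 0.5), A = 0, delta = 0, L = 0.5, R = Inf,
                    Z = matrix(1, 1, 1))
  expect_equal(truncph:::estep_expectations(0.3, c(0.2, 0.1), pr)[[1]]$e,
               c(0, 0))

  # single support point with unit mass: mean of Poisson(1) given positivity
  pr <- manual_prep(grid = c(0.2, 0.6), A = 0, delta = 0, L = 0.2, R = 0.6,
                    Z = matrix(0, 1, 1))
  e <- truncph:::estep_expectations(0, c(0.05, 1), pr)[[1]]
  expect_equal(e$e, c(0, 1 / (1 - exp(-1))), tolerance = 1e-9)
  expect_equal(e$e[2], 1.581977, tolerance = 1e-6)

  # two support points sharing the mass; the window total is at least one
  pr <- manual_prep(grid = c(0.2, 0.4, 0.6), A = 0, delta = 0, L = 0.2,
                    R = 0.6, Z = matrix(0, 1, 1))
  e <- truncph:::estep_expectations(0, c(0.3, 0.5, 0.5), pr)[[1]]
  expect_equal(e$e[2:3], rep(0.5 / (1 - exp(-1)), 2), tolerance = 1e-9)
  expect_equal(e$e[2], 0.790989, tolerance = 1e-6)
  expect_gte(sum(e$e), 1)

  # Monte Carlo oracle on windows of one to three points
  for (mu in list(1, c(0.5, 0.5), c(0.2, 0.7, 0.4))) {
    K <- length(mu)
    grid <- seq(0.2, by = 0.2, length.out = K + 1)
    pr <- manual_prep(grid = grid, A = 0, delta = 0, L = 0.2,
                      R = max(grid), Z = matrix(0, 1, 1))
    e <- truncph:::estep_expectations(0, c(0.1, mu), pr)[[1]]
    expect_equal(e$e[-1], mc_poisson_condmean(mu, 1e6, seed = K),
                 tolerance = 0.01)
  }
})

test_that("jump update solves its own score equation", {
  # hand example: one event and one censored subject at the same time,
  # everyone at risk -> the classical events/at-risk ratio
  pr <- manual_prep(grid = 1, A = c(0, 0), delta = c(1, 0),
                    T = c(1, NA), L = c(NA, 1), R = c(NA, Inf),
                    Z = matrix(0, 2, 1))
  co <- truncph:::estep_coefs(0, 0.3, pr)
  upd <- truncph:::update_lambda(co, 0, 0.3, pr, pairwise = TRUE)
  expect_equal(upd$lam, 0.5, tolerance = 1e-12)
  # equal entries: the pairwise denominator term is exactly zero
  upd2 <- truncph:::update_lambda(co, 0, 0.3, pr, pairwise = FALSE)
  expect_equal(upd$lam, upd2$lam, tolerance = 1e-14)

  # at a tightly converged fit, U_lambda_k = 0 at every supported jump
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 20,
                       seed = 3)
  fit <- fit_df(d, tol = 1e-9, max_iter = 50000)
  expect_true(fit$converged)
  pr <- prep_of(d)
  E <- truncph:::estep_expectations(coef(fit), fit$lambda, pr)
  ee <- exp(drop(pr$Z %*% coef(fit)))
  pt <- naive_pair_terms(coef(fit), fit$lambda, pr$grid, d)
  n <- 20
  for (k in seq_len(pr$K)) {
    if (fit$lambda[k] <= 1e-9) next
    s <- 0
    for (i in seq_len(n)) {
      r <- E[[i]]
      if (k %in% r$k)
        s <- s + r$e[r$k == k] / fit$lambda[k] - ee[i]
    }
    U <- s / n - pt$P[k] / (n * (n - 1))
    ## the fixed-point residual num_k - lam_k * den_k = lam_k * U_k; for
    ## very small jumps the raw score is ill-scaled, so assert the residual
    expect_lt(abs(fit$lambda[k] * U), 1e-9)
    if (fit$lambda[k] > 1e-4) expect_lt(abs(U), 1e-6)
  }
})

test_that("beta score and Jacobian match finite differences of the surrogate", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 8,
                       seed = 6)
  pr <- prep_of(d)
  beta <- c(0.3, -0.4)
  set.seed(6)
  lam <- runif(pr$K, 0.005, 0.08)
  co <- truncph:::estep_coefs(beta, lam, pr)
  Efix <- truncph:::estep_expectations(beta, lam, pr)
  h <- 1e-4
  for (pw in c(TRUE, FALSE)) {
    U <- truncph:::score_beta(co, beta, lam, pr, pw)
    for (q in 1:2) {
      bp <- bm <- beta; bp[q] <- bp[q] + h; bm[q] <- bm[q] - h
      lEp <- naive_lE(bp, lam, pr$grid, d, Efix)
      lEm <- naive_lE(bm, lam, pr$grid, d, Efix)
      if (!pw) {  # strip the pairwise part from the surrogate
        lEp <- lEp - naive_pairwise_loglik(bp, lam, pr$grid, d) / (8 * 7)
        lEm <- lEm - naive_pairwise_loglik(bm, lam, pr$grid, d) / (8 * 7)
      }
      expect_lt(abs(U[q] - (lEp - lEm) / (2 * h)), 1e-6)
    }
    # analytic Jacobian against central differences of the score
    J <- truncph:::jacobian_beta(co, beta, lam, pr, pw)
    for (q in 1:2) {
      bp <- bm <- beta; bp[q] <- bp[q] + h; bm[q] <- bm[q] - h
      fd <- (truncph:::score_beta(co, bp, lam, pr, pw) -
               truncph:::score_beta(co, bm, lam, pr, pw)) / (2 * h)
      expect_lt(max(abs(J[, q] - fd)), 1e-6)
    }
  }
  # a covariate identically zero contributes a zero score component
  d0 <- d; d0$Z1 <- 0; d0$Z2 <- 0
  pr0 <- prep_of(d0)
  co0 <- truncph:::estep_coefs(beta, lam, pr0)
  expect_equal(truncph:::score_beta(co0, beta, lam, pr0, TRUE), c(0, 0),
               ignore_attr = TRUE)
})

test_that("one-step Newton is stationary at the fixed point and guards a singular system", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 25,
                       seed = 10)
  fit <- fit_df(d, tol = 1e-10, max_iter = 50000)
  expect_true(fit$converged)
  pr <- prep_of(d)
  co <- truncph:::estep_coefs(coef(fit), fit$lambda, pr)
  st <- truncph:::newton_step_beta(co, coef(fit), fit$lambda, pr, TRUE)
  expect_lt(sum(abs(st$beta - coef(fit))), 1e-6)
  expect_false(st$fallback)
  # all-zero covariates make the system singular; the damped step is flagged
  d0 <- d; d0$Z1 <- 0; d0$Z2 <- 0
  pr0 <- prep_of(d0)
  co0 <- truncph:::estep_coefs(c(0, 0), fit$lambda, pr0)
  st0 <- truncph:::newton_step_beta(co0, c(0, 0), fit$lambda, pr0, TRUE)
  expect_true(st0$fallback)
  expect_equal(st0$beta, c(0, 0), ignore_attr = TRUE)
})

test_that("compiled engine reproduces the reference R iteration exactly", {
  d <- simulate_ltdata(sim_design("partly-interval", "exponential"), n = 40,
                       seed = 14)
  pr <- prep_of(d)
  ctrl <- truncph_control(trace_objective = FALSE)
  for (pw in c(TRUE, FALSE)) {
    beta <- c(0, 0); lam <- rep(1 / pr$K, pr$K)
    for (it in 1:3) {
      ref <- truncph:::em_iterate_r(beta, lam, pr, pw, ctrl)
      eng <- truncph:::em_engine(beta, lam, pr, pw, ctrl, 1L)
      expect_equal(eng$beta, ref$beta, tolerance = 1e-13,
                   ignore_attr = TRUE)
      expect_equal(eng$lambda, ref$lambda, tolerance = 1e-13)
      expect_equal(eng$delta, ref$delta, tolerance = 1e-10)
      beta <- ref$beta; lam <- ref$lambda
    }
  }
})

test_that("estimator variants reduce to one another as the entry times collapse", {
  # no truncation: the pairwise term vanishes and all three variants agree
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 60,
                       seed = 21)
  d$A <- 0
  f_pw <- fit_df(d, "pairwise")
  f_cl <- fit_df(d, "conditional")
  f_ig <- fit_df(d, "ignore-truncation")
  expect_lt(max(abs(coef(f_pw) - coef(f_cl))), 1e-8)
  expect_lt(max(abs(f_pw$lambda - f_cl$lambda)), 1e-8)
  # ignoring truncation is, by construction, the conditional fit on zeroed
  # entry times
  expect_identical(coef(f_ig), coef(f_cl))
  expect_identical(f_ig$lambda, f_cl$lambda)
  d2 <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 60,
                        seed = 22)
  f_ig2 <- fit_df(d2, "ignore-truncation")
  d2z <- d2; d2z$A <- 0
  f_cl2 <- fit_df(d2z, "conditional")
  expect_identical(coef(f_ig2), coef(f_cl2))
})

test_that("EM limit solves the profiled score equation (bisection oracle)", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 10,
                       seed = 2)
  d$Z2 <- NULL   # single covariate
  pr <- prep_of(d)
  profiled_score <- function(beta) {
    lam <- rep(1 / pr$K, pr$K)
    for (it in 1:20000) {
      co <- truncph:::estep_coefs(beta, lam, pr)
      upd <- truncph:::update_lambda(co, beta, lam, pr, pairwise = TRUE)
      if (sum(abs(upd$lam - lam)) < 1e-11) { lam <- upd$lam; break }
      lam <- upd$lam
    }
    co <- truncph:::estep_coefs(beta, lam, pr)
    truncph:::score_beta(co, beta, lam, pr, TRUE)
  }
  root <- uniroot(profiled_score, c(-1, 3), tol = 1e-9)$root
  fit <- fit_df(d, tol = 1e-9, max_iter = 100000)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit) - root), 1e-4)
})

test_that("untruncated right-censored fits match the Cox partial likelihood", {
  des <- sim_design("right", "uniform")
  d <- simulate_ltdata(des, n = 150, seed = 33)
  d$A <- 0
  fit <- fit_df(d, "conditional", tol = 1e-8, max_iter = 50000)
  x <- ifelse(d$delta == 1, d$T, d$L)
  cx <- survival::coxph(survival::Surv(x, d$delta) ~ Z1 + Z2, data = d,
                        ties = "breslow")
  expect_lt(max(abs(coef(fit) - coef(cx))), 1e-3)
  # Breslow baseline agrees too
  bh <- survival::basehaz(cx, centered = FALSE)
  at <- c(0.3, 0.6)
  expect_equal(truncph:::step_cumhaz(fit$lambda, fit$times, at),
               approx(bh$time, bh$hazard, xout = at, method = "constant",
                      rule = 2)$y,
               tolerance = 1e-3)
})

test_that("composite objective is monotone along the EM path", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 50,
                       seed = 27)
  fit <- fit_df(d, trace_objective = TRUE)
  expect_gt(length(fit$objective), 10)
  expect_gt(min(diff(fit$objective)), -1e-6)
})

test_that("iteration cap returns a flagged, not failed, fit", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 30,
                       seed = 4)
  fit <- fit_df(d, max_iter = 3)
  expect_false(fit$converged)
  expect_identical(fit$n_iter, 3L)
})

test_that("fitted coefficients recover the truth at large n", {
  d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 1000,
                       seed = 51)
  fit <- fit_df(d)
  expect_true(fit$converged)
  expect_lt(abs(coef(fit)[1] - 1), 0.15)
  expect_lt(abs(coef(fit)[2] - 1), 0.25)
})
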