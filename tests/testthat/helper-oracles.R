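# Independent reference implementations used as oracles. These are written
# as plain loops from the model formulas and never call the package's fast
# paths.

# Build an internal prep structure from a data frame in the standard layout.
prep_of <- function(d) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  truncph:::lt_prep(d$A, d$delta, d$T, d$L, d$R, Z)
}

fit_df <- function(d, method = "pairwise", ...) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  args <- list(...)
  if (is.null(args$trace_objective)) args$trace_objective <- FALSE
  truncph::truncph_fit(d$A, d$delta, d$T, d$L, d$R, Z, method = method,
                       control = do.call(truncph::truncph_control, args))
}

# Conditional log-likelihood from survival-function differences, loops only.
naive_cond_loglik <- function(beta, lam, grid, d) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  Lam <- function(t) sum(lam[grid <= t])
  ll <- 0
  for (i in seq_len(nrow(d))) {
    ee <- exp(sum(Z[i, ] * beta))
    sum_in <- function(lo, hi) {  # sum over lo <= t_k <= hi
      s <- 0
      for (k in seq_along(grid))
        if (grid[k] >= lo && grid[k] <= hi) s <- s + lam[k]
      s
    }
    if (d$delta[i] == 1) {
      k <- which(grid == d$T[i])
      ll <- ll + log(lam[k]) + log(ee) - sum_in(d$A[i], d$T[i]) * ee
    } else {
      t1 <- exp(-sum_in(d$A[i], d$L[i]) * ee)
      t2 <- if (is.finite(d$R[i])) exp(-sum_in(d$A[i], d$R[i]) * ee) else 0
      ll <- ll + log(t1 - t2)
    }
  }
  ll
}

# Pairwise log-likelihood by double loop over ordered pairs, from the
# indicator-sum definition of R_ij.
naive_pairwise_loglik <- function(beta, lam, grid, d) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  n <- nrow(d)
  ee <- exp(drop(Z %*% beta))
  out <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    x <- sum((as.numeric(grid <= d$A[i]) - as.numeric(grid <= d$A[j])) *
               lam * (ee[i] - ee[j]))
    out <- out - log(1 + exp(x))
  }
  out
}

# Brute-force pairwise terms of the two score equations.
naive_pair_terms <- function(beta, lam, grid, d) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  n <- nrow(d); p <- ncol(Z); K <- length(grid)
  ee <- exp(drop(Z %*% beta))
  Rij <- function(i, j)
    exp(sum((as.numeric(grid <= d$A[i]) - as.numeric(grid <= d$A[j])) *
              lam * (ee[i] - ee[j])))
  P <- numeric(K)
  Tp <- numeric(p)
  for (i in seq_len(n)) for (j in seq_len(n)) if (i != j) {
    w <- 1 / (1 + 1 / Rij(i, j))
    dk <- as.numeric(grid <= d$A[i]) - as.numeric(grid <= d$A[j])
    P <- P + w * (ee[i] - ee[j]) * dk
    Tp <- Tp + w * sum(lam * dk) * (Z[i, ] * ee[i] - Z[j, ] * ee[j])
  }
  list(P = P, score = Tp)
}

# E-step surrogate l_E(theta) with the expectations held fixed, loops only.
naive_lE <- function(beta, lam, grid, d, Efix) {
  Z <- as.matrix(d[, grep("^Z", names(d)), drop = FALSE])
  n <- nrow(d)
  ee <- exp(drop(Z %*% beta))
  out <- 0
  for (i in seq_len(n)) {
    r <- Efix[[i]]
    for (q in seq_along(r$k)) {
      k <- r$k[q]
      out <- out + (r$e[q] * log(lam[k] * ee[i]) - lam[k] * ee[i]) / n
    }
  }
  out + naive_pairwise_loglik(beta, lam, grid, d) / (n * (n - 1))
}

# Monte Carlo conditional means of independent Poisson counts given a
# positive sum.
mc_poisson_condmean <- function(mu, ndraw = 1e6, seed = 1) {
  set.seed(seed)
  W <- matrix(rpois(ndraw * length(mu), rep(mu, each = ndraw)), nrow = ndraw)
  keep <- rowSums(W) > 0
  colMeans(W[keep, , drop = FALSE])
}

# A tiny deterministic mixed-censoring dataset exercising all subject types.
toy_data <- function() {
  data.frame(id = 1:6,
             A = c(0.20, 0.10, 0.00, 0.30, 0.05, 0.15),
             delta = c(1, 0, 0, 1, 0, 0),
             T = c(0.50, NA, NA, 0.90, NA, NA),
             L = c(NA, 0.30, 0.40, NA, 0.05, 0.60),
             R = c(NA, 0.70, Inf, NA, 0.45, 1.10),
             Z1 = c(1, 0, 1, 0, 1, 0),
             Z2 = c(0.2, -0.3, 0.1, 0.4, -0.1, 0.25))
}
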