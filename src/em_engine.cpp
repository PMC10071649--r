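#include <Rcpp.h>
using namespace Rcpp;

// Fast path for the EM loop. Mirrors the R reference implementation
// (estep_coefs / update_lambda / score_beta / jacobian_beta /
// newton_step_beta) step for step; tests assert the two paths agree.

static inline double log1pexp_c(double x) {
  if (x > 0) return x + std::log1p(std::exp(-x));
  return std::log1p(std::exp(x));
}

// Solve J s = U by Gaussian elimination with partial pivoting.
// Returns false when J is singular or the solution is not finite.
static bool solve_small(std::vector<double> J, std::vector<double> U,
                        std::vector<double> &s, int p) {
  for (int c = 0; c < p; ++c) {
    int piv = c;
    for (int r = c + 1; r < p; ++r)
      if (std::fabs(J[r + c * p]) > std::fabs(J[piv + c * p])) piv = r;
    if (std::fabs(J[piv + c * p]) < 1e-300) return false;
    if (piv != c) {
      for (int cc = 0; cc < p; ++cc) std::swap(J[c + cc * p], J[piv + cc * p]);
      std::swap(U[c], U[piv]);
    }
    for (int r = c + 1; r < p; ++r) {
      double f = J[r + c * p] / J[c + c * p];
      for (int cc = c; cc < p; ++cc) J[r + cc * p] -= f * J[c + cc * p];
      U[r] -= f * U[c];
    }
  }
  for (int r = p - 1; r >= 0; --r) {
    double acc = U[r];
    for (int cc = r + 1; cc < p; ++cc) acc -= J[r + cc * p] * s[cc];
    s[r] = acc / J[r + r * p];
    if (!std::isfinite(s[r])) return false;
  }
  return true;
}

// One or more EM iterations from (beta, lam). Indices are the 1-based
// counts produced by lt_prep. Returns the updated parameters, the last
// sum-of-absolute-differences, and bookkeeping counts.
// [[Rcpp::export]]
List em_run(NumericMatrix Z, IntegerVector type, IntegerVector iAlt,
            IntegerVector iAle, IntegerVector iT, IntegerVector iL,
            IntegerVector iR, IntegerVector iRstar, int K,
            NumericVector beta0, NumericVector lam0, bool pairwise,
            double tol, int maxit, double lam_floor, double damping) {
  const int n = Z.nrow(), p = Z.ncol();
  std::vector<double> beta(beta0.begin(), beta0.end());
  std::vector<double> lam(lam0.begin(), lam0.end());
  std::vector<double> ee(n), cs0(K + 1), LamA(n), cI(n), Wi(n);
  std::vector<double> Nk(K), dvec(K + 1), rvec(K), den(K);
  std::vector<double> U(p), Jm(p * p), step(p), beta_new(p);
  std::vector<double> lam_new(K), cs0n(K + 1);
  int nfloor = 0, nfallback = 0, it = 0;
  bool converged = false;
  double delta = NA_REAL;

  while (it < maxit) {
    ++it;
    // linear predictor and cumulative jumps
    for (int i = 0; i < n; ++i) {
      double e = 0.0;
      for (int a = 0; a < p; ++a) e += Z(i, a) * beta[a];
      ee[i] = std::exp(e);
    }
    cs0[0] = 0.0;
    for (int k = 0; k < K; ++k) cs0[k + 1] = cs0[k] + lam[k];

    // E-step
    for (int i = 0; i < n; ++i) {
      cI[i] = 0.0;
      if (type[i] == 1) { Wi[i] = 1.0; continue; }
      Wi[i] = 0.0;
      if (type[i] == 2) {
        double csd = cs0[iR[i]] - cs0[iL[i]];
        double mu = ee[i] * csd;
        double c1 = 0.0;
        if (mu < 1e-300) c1 = csd > 0 ? 1.0 / csd : 0.0;
        else c1 = ee[i] / (-std::expm1(-mu));
        cI[i] = c1;
        Wi[i] = c1 * csd;
      }
    }

    // jump-update numerator and at-risk denominator
    std::fill(Nk.begin(), Nk.end(), 0.0);
    std::fill(dvec.begin(), dvec.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      if (type[i] == 1) Nk[iT[i] - 1] += 1.0;
      else if (type[i] == 2 && cI[i] > 0) {
        dvec[iL[i]] += cI[i];
        dvec[iR[i]] -= cI[i];
      }
    }
    double acc = 0.0;
    for (int k = 0; k < K; ++k) { acc += dvec[k]; Nk[k] += lam[k] * acc; }
    std::fill(dvec.begin(), dvec.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      dvec[iAlt[i]] += ee[i];
      dvec[iRstar[i]] -= ee[i];
    }
    acc = 0.0;
    for (int k = 0; k < K; ++k) { acc += dvec[k]; rvec[k] = acc; }
    for (int k = 0; k < K; ++k) den[k] = rvec[k] / n;

    // pairwise denominator term at the pre-update parameters
    if (pairwise && n > 1) {
      for (int i = 0; i < n; ++i) LamA[i] = cs0[iAle[i]];
      std::fill(dvec.begin(), dvec.end(), 0.0);
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          if (iAle[i] == iAle[j]) continue;
          double x = (LamA[i] - LamA[j]) * (ee[i] - ee[j]);
          if (x > 700.0) x = 700.0;
          if (x < -700.0) x = -700.0;
          double R = std::exp(x);
          double w = 2.0 * R / (1.0 + R);
          int hi = iAle[i] > iAle[j] ? i : j;
          int lo = hi == i ? j : i;
          double v = w * (ee[hi] - ee[lo]);
          dvec[iAle[lo]] += v;
          dvec[iAle[hi]] -= v;
        }
      }
      acc = 0.0;
      double nn1 = (double)n * (n - 1);
      for (int k = 0; k < K; ++k) { acc += dvec[k]; den[k] += acc / nn1; }
    }
    for (int k = 0; k < K; ++k) {
      double num = Nk[k] / n;
      if (num > 0.0 && den[k] == 0.0)
        stop("zero at-risk denominator with positive mass at grid point %d",
             k + 1);
      double l = num > 0.0 ? num / den[k] : 0.0;
      if (l < 0.0) { l = lam_floor; ++nfloor; }
      lam_new[k] = l;
    }

    // composite score and Jacobian at (beta, lam_new), E(W) fixed
    cs0n[0] = 0.0;
    for (int k = 0; k < K; ++k) cs0n[k + 1] = cs0n[k] + lam_new[k];
    std::fill(U.begin(), U.end(), 0.0);
    std::fill(Jm.begin(), Jm.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double Lwin = cs0n[iRstar[i]] - cs0n[iAlt[i]];
      double r1 = Wi[i] - ee[i] * Lwin;
      double r2 = ee[i] * Lwin;
      for (int a = 0; a < p; ++a) {
        U[a] += Z(i, a) * r1 / n;
        for (int b = 0; b < p; ++b)
          Jm[a + b * p] -= Z(i, a) * Z(i, b) * r2 / n;
      }
    }
    if (pairwise && n > 1) {
      double nn1 = (double)n * (n - 1);
      for (int i = 0; i < n; ++i) LamA[i] = cs0n[iAle[i]];
      for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double D = LamA[i] - LamA[j];
          double x = D * (ee[i] - ee[j]);
          if (x > 700.0) x = 700.0;
          if (x < -700.0) x = -700.0;
          double R = std::exp(x);
          double w = 2.0 * R / (1.0 + R);
          double c1 = 2.0 * R / ((1.0 + R) * (1.0 + R)) * D * D;
          for (int a = 0; a < p; ++a) {
            double q1a = Z(i, a) * ee[i] - Z(j, a) * ee[j];
            U[a] -= w * D * q1a / nn1;
            for (int b = 0; b < p; ++b) {
              double q1b = Z(i, b) * ee[i] - Z(j, b) * ee[j];
              Jm[a + b * p] -=
                (c1 * q1a * q1b +
                 w * D * (Z(i, a) * Z(i, b) * ee[i] -
                          Z(j, a) * Z(j, b) * ee[j])) / nn1;
            }
          }
        }
      }
    }
    bool ok = solve_small(Jm, U, step, p);
    if (ok) {
      for (int a = 0; a < p; ++a) beta_new[a] = beta[a] - step[a];
    } else {
      ++nfallback;
      for (int a = 0; a < p; ++a) beta_new[a] = beta[a] + damping * U[a];
    }

    delta = 0.0;
    for (int a = 0; a < p; ++a) delta += std::fabs(beta_new[a] - beta[a]);
    for (int k = 0; k < K; ++k) delta += std::fabs(lam_new[k] - lam[k]);
    beta = beta_new;
    lam = lam_new;
    if (delta < tol) { converged = true; break; }
  }
  return List::create(_["beta"] = NumericVector(beta.begin(), beta.end()),
                      _["lambda"] = NumericVector(lam.begin(), lam.end()),
                      _["n_iter"] = it, _["converged"] = converged,
                      _["delta"] = delta, _["nfloor"] = nfloor,
                      _["nfallback"] = nfallback);
}
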