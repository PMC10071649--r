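---
title: "Pairwise pseudo-likelihood estimation for left-truncated, censored survival data"
author: "truncph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise pseudo-likelihood estimation for left-truncated, censored survival data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(truncph)
```

## The problem

In prevalent-cohort and cross-sectional follow-up studies a subject is
observed only if the event of interest has not yet happened at study entry.
Writing $T^*$ for the underlying failure time, $A^*$ for the underlying
entry (truncation) time and $Z^*$ for covariates, the sample consists of
draws from $(T, A, Z) \sim (T^*, A^*, Z^*) \mid T^* \ge A^*$ — a
left-truncated sample in which long survivors are over-represented. On top
of truncation, the failure time is rarely observed exactly: periodic
examinations bracket it into an interval $(L, R]$, with $L = A$ (left
censoring) when the event precedes the first examination after entry and
$R = \infty$ (right censoring) when it outlives the last one. A mixture of
exact and bracketed observations is *partly interval-censored* data.

`truncph` fits the Cox proportional hazards model
$$\Lambda(t \mid Z) = \Lambda(t)\, e^{Z^\top \beta}$$
to such data, where $\Lambda$ is an unspecified baseline cumulative hazard.

## Estimators

The observed-data likelihood factorises into a *conditional* part — the
likelihood of the event data given entry times and covariates — and a
*marginal* part, the likelihood of the entry times themselves, which
involves the unknown entry-time density $h$. Three estimators are provided:

* **`pairwise`** (default): maximises the conditional likelihood augmented
  with the *pairwise pseudo-likelihood* of the entry times. For a pair
  $(i, j)$, conditioning on the observed pair of entry values but not on
  which subject carries which gives the contribution $1/(1 + R_{ij})$ with
  $$R_{ij} = \frac{S(A_i \mid Z_j)\, S(A_j \mid Z_i)}
                  {S(A_i \mid Z_i)\, S(A_j \mid Z_j)}
           = \exp\!\big[\{\Lambda(A_i) - \Lambda(A_j)\}
                        \{e^{Z_i^\top\beta} - e^{Z_j^\top\beta}\}\big].$$
  The density $h$ cancels within each pair, yet the pair retains information
  about $(\beta, \Lambda)$ carried by the entry times. Note that $R_{ij}$ is
  *symmetric* in $(i,j)$ — both factors of the exponent change sign
  together — so the product over ordered pairs counts every unordered pair
  twice.
* **`conditional`**: the conditional likelihood alone. Consistent, but it
  discards the entry-time information and is therefore less efficient.
* **`ignore-truncation`**: sets every $A_i$ to zero and fits the plain
  NPMLE. Biased under truncation; provided as the standard of comparison.

The two likelihood parts are combined on a common scale as
$$\ell(\theta) = \frac{1}{n} \log L^{C}(\theta)
  \;+\; \frac{1}{n(n-1)} \sum_{i \ne j} -\log\{1 + R_{ij}(\theta)\}.$$

## Nonparametric maximum likelihood and the EM algorithm

$\Lambda$ is estimated as a right-continuous step function. Its jump
support is the set of exact event times and finite censoring-interval
endpoints $t_1 < \dots < t_K$; entry times influence the fit only through
the step function's value $\Lambda(A_i)$. (Admitting jumps *at* entry times
was examined and rejected: an entry time near zero sits in a nearly empty
risk set, and the NPMLE then occasionally places a large jump there,
roughly doubling the Monte Carlo spread of $\hat\Lambda$ at small $t$
without any compensating gain. See "Numerical choices" below.)

Maximisation uses an EM algorithm built on Poisson data augmentation: for
subject $i$ and grid point $t_k$ in the window $A_i \le t_k \le R^*_i$
(with $R^*_i$ the event time, the finite interval endpoint, or the last
examination), a latent count $W_{ik} \sim \text{Poisson}(\lambda_k
e^{Z_i^\top\beta})$ is introduced, and the censored-data contributions
become constrained products of Poisson masses. The E-step means are closed
form: zero on $[A_i, L_i]$ and
$\lambda_k e^{Z_i^\top\beta} / \{1 - e^{-\mu_i}\}$ on $(L_i, R_i]$, with
$\mu_i$ the subject's window mass, for interval-censored subjects
(left censoring is the degenerate case $L_i = A_i$); an exact event is the
point mass $W_{ik} = 1$ at $t_k = T_i$; a right-censored subject's window
is all zeros.

Each iteration then performs

1. **E-step** at the current $(\beta, \lambda)$;
2. **jump update**: each $\lambda_k$ has a closed-form self-consistent
   solution of its own score equation — expected events at $t_k$ over the
   at-risk mass plus a pairwise correction term weighted by
   $1/(1 + R_{ij}^{-1})$;
3. **one-step Newton–Raphson** for $\beta$ on the composite score
   $U_\beta$, evaluated at the freshly updated jumps (a Gauss–Seidel
   ordering; the algorithm statement leaves the choice open and either
   reading converges to the same fixed point, which tests verify against a
   profiled bisection oracle).

Convergence is declared when the sum of absolute differences of *all*
parameters between successive iterations falls below `tol`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `tol` | 0.001 | sum-of-absolute-differences stopping rule over $(\beta, \lambda_1 \dots \lambda_K)$ (dimensionless; event times set the time unit) |
| `max_iter` | 10000 | iteration cap; the closed-form EM takes many cheap iterations (roughly 100–2000 at the default `tol`), so the cap is set well above typical needs — 1000 would misclassify many clean fits as non-converged |
| `init_beta` | 0 | starting coefficients |
| `init_lambda` | $1/K$ each | starting jumps; the fit is insensitive to this choice |
| `lam_floor` | 1e-10 | replacement value when a jump update turns negative (possible in principle because the pairwise correction enters the denominator); activations are counted and reported in `$warnings` — none occur in the simulation designs below |
| `trace_objective` | TRUE | record the composite objective each iteration (adds an $O(n^2)$ pass; the Monte Carlo drivers disable it) |

Bootstrap refits warm-start from the original fit (a resample's jump grid
is a subset of the original grid), which changes only the starting point of
a convergent iteration, not the estimator.

## Implementation notes

The per-iteration work is one $O(n + K)$ sweep for the E-step and jump
numerators plus two $O(n^2)$ passes over subject pairs for the pairwise
terms (one at the pre-update parameters for the jump denominators, one at
the post-update jumps for the Newton step). The pair passes and the EM loop
run in compiled code; an equivalent pure-R reference implementation of each
step ships in the package and the test suite asserts the two paths agree to
near machine precision, with the pair sums additionally checked against
brute-force double loops.

Numerical guards: the pairwise exponent is clamped at $\pm 700$ before
exponentiation; $\log(1 + e^x)$ uses the stable branch; a censored
subject's window mass that underflows ($\mu_i < 10^{-300}$) falls back to
the $\mu \to 0$ limit $\lambda_k / \sum \lambda_k$ so the M-step stays
defined; a singular Newton system falls back to a damped ascent step along
the score (counted in `$warnings`).

One-step Newton (rather than an inner maximisation) means the composite
objective is not mathematically guaranteed to increase every iteration;
empirically the trace is monotone to well below $10^{-6}$ per iteration,
and the test suite asserts exactly that on a moderate fit.

## The simulator

`simulate_ltdata()` emulates a truncated periodic-examination follow-up
study: $\Lambda(t) = t^2$ (Weibull, shape 2), $Z_1 \sim \text{Bernoulli}(0.5)$,
$Z_2 \sim U(-0.5, 0.5)$ (widened to $U(-1, 1)$ in the right-censoring
design), $\beta = (1, 1)$, and entry times Uniform$(0, \tau)$ or
Exponential$(\theta)$ with the parameter calibrated by Monte Carlo
bisection (100{,}000 draws, tolerance 0.005, cached per design) so that
half the population is truncated away. Accepted subjects are examined from
entry onwards with gaps $0.05 + U(0, 0.5)$ until calendar time 1.5 — read
as an absolute study length from the time origin, so late entrants get few
examinations; a subject whose entry itself exceeds 1.5 is right-censored at
that single examination. The event is bracketed by adjacent examinations;
in the partly-interval scheme a bracket shorter than 0.2 is replaced by the
exact time. The right-censoring scheme instead draws $C \sim U(0, C_{max})$
and censors at calendar time $A + C$ (censoring measured from entry, so
every subject has positive potential follow-up; measuring from the origin
would require redrawing $C > A$ and is the one reading the data cannot
distinguish), with $C_{max}$ calibrated to a 30% censoring rate.

Under these defaults the realised censoring mix (exact 4–26%, left 16–37%,
right 7–33%, interval 24–58%) and the truncation and censoring rates match
the reference operating ranges; the test suite checks all of them.

What the simulator does *not* emulate: informative examination schedules,
covariate-dependent entry, ties in continuous times, or measurement error.
Passing tests on simulated data therefore demonstrate correctness of the
estimator under independent censoring and entry — not robustness to
violations of those assumptions.

## Monte Carlo scales used by the tests

The acceptance-style tests rerun the reference simulation designs at
desk scale: 250 replicates at $n = 100$ (partly-interval and
right-censored designs), 50 replicates at $n = 300$ (interval design) and
$n = 500$, with tolerances of three Monte Carlo standard errors computed
from the reference spread at the replicate count actually used. Coverage
and average-bootstrap-standard-error summaries, which need a bootstrap
inside every replicate, run at 50 replicates with $B = 25$ in
`scripts/acceptance.R`.

## Known limitations

* The pairwise pass makes one fit $O(n^2)$ per iteration; fits at
  $n = 500$ take seconds, and bootstrap inference at much larger $n$ is
  computationally heavy (the bootstrap is the only variance estimator
  provided — no profile-likelihood or EM-map variance).
* The estimator assumes entry times independent of covariates and
  non-informative censoring; neither is testable from the data alone.
* $\hat\Lambda$ is only weakly identified beyond the last finite
  observation time; predictions there are extrapolations of a constant.
* Small samples with few exact events can show monotone-likelihood
  behaviour in $\beta$ (the pairwise MLE drifting to infinity), flagged by
  non-convergence at the iteration cap.
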