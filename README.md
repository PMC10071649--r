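# truncph

Cox proportional hazards regression for **left-truncated** failure time
data under **right, interval, left, or partly interval censoring**, using a
pairwise pseudo-likelihood NPMLE fitted by an EM algorithm with Poisson
data augmentation.

## The problem and who this is for

In prevalent-cohort and cross-sectional follow-up studies (dementia
survival cohorts, ageing panels such as the Massachusetts Health Care
Panel Study, registry-based epidemiology), a subject enters the sample
only if the event has not yet occurred at enrolment. With $T^*$ the
failure time, $A^*$ the entry time, and $Z^*$ covariates, one observes
draws from $(T^*, A^*, Z^*) \mid T^* \ge A^*$: a left-truncated, biased
sample. Between periodic examinations the event time is additionally only
known to lie in an interval $(L, R]$, possibly with $L = A$ (left
censoring) or $R = \infty$ (right censoring), and some events may be timed
exactly.

The package estimates $\beta$ and the baseline cumulative hazard
$\Lambda$ in

$$\Lambda(t \mid Z) = \Lambda(t)\, e^{Z^\top \beta},$$

treating $\Lambda$ as a step function with jumps $\lambda_k$ at the
observed event times and censoring-interval endpoints. The default
estimator augments the conditional likelihood of the event data with the
**pairwise pseudo-likelihood** of the entry times,

$$\prod_{i \ne j} \{1 + R_{ij}(\theta)\}^{-1},
\qquad
R_{ij} = \exp\!\big[\{\Lambda(A_i)-\Lambda(A_j)\}
\{e^{Z_i^\top\beta}-e^{Z_j^\top\beta}\}\big],$$

which cancels the unknown entry-time density within each subject pair
while keeping the information the entry times carry about $(\beta,
\Lambda)$. A conditional-likelihood estimator and a naive
truncation-ignoring NPMLE are included for comparison. Standard errors
come from the nonparametric bootstrap; confidence intervals for
$\Lambda(t)$ use the log-transformed delta-method form. A simulator for
truncated periodic-examination studies and a Monte Carlo harness round out
the package. See the methods vignette
(`vignettes/pairwise-pseudolikelihood.Rmd`) for the model, the EM
updates, and all numerical choices.

## Worked example

```r
library(truncph)

d <- simulate_ltdata(sim_design("partly-interval", "uniform"), n = 200, seed = 42)
fit <- truncph(TruncSurv(A, delta, T, L, R) ~ Z1 + Z2, data = d,
               control = truncph_control(trace_objective = FALSE))
bt <- truncph_boot(fit, B = 100, eval_times = c(0.4, 0.8, 1.2), seed = 1)
summary(fit, boot = bt)
```

```
Left-truncated PH fit (pairwise), n = 200

      Est    Std     z  p-value    
Z1 1.3322 0.1791 7.439 1.01e-13 ***
Z2 1.3666 0.2910 4.697 2.65e-06 ***

Baseline cumulative hazard:
    time cumhaz     se  lower  upper
0.4  0.4 0.1176 0.0730 0.0349 0.3970
0.8  0.8 0.4705 0.1069 0.3014 0.7344
1.2  1.2 1.1673 0.1967 0.8390 1.6241

Bootstrap: B = 100 (0 resample(s) failed)
```

The data were generated with true $\beta = (1, 1)$ and $\Lambda(t) = t^2$,
under ~50% truncation and a mixture of exact, left-, interval- and
right-censored observations. Both covariate effects are recovered within
sampling error (the bootstrap SEs are 0.18 and 0.29), and the estimated
cumulative hazard tracks $t^2$ at the three evaluation times (true values
0.16, 0.64, 1.44). `predict()`, `plot()`, `coef()` and `logLik()` methods
are available on the fit; `wald_test()` and `cumhaz_ci()` expose the
inferential pieces directly. Datasets travel as plain CSV via
`read_ltdata()` / `write_ltdata()`, and `inst/cli/truncph-cli.R` wraps
fitting, simulation and Monte Carlo studies for shell use.

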