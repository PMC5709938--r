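# pksse

Stochastic simulation and estimation (SSE) for population pharmacokinetics
with very few subjects.

Early preclinical and clinical PK studies often have six or so subjects.
At that size, the choice of estimation method for a nonlinear mixed-effects
model — classical first-order conditional estimation with interaction
(FOCE-I) versus Markov-chain Monte Carlo Bayesian estimation — visibly
changes the estimated population means and, above all, the
inter-individual-variability (IIV) variances. `pksse` is a self-contained
workbench for studying that question: it simulates replicate small-N
studies from a known truth, refits every dataset with four method
configurations, and summarises estimator bias and precision.

Everything is implemented in R from first principles: the closed-form
one-compartment oral model, a FOCE-I maximiser (conditional modes by damped
Gauss–Newton with analytic sensitivities, linearised marginal −2·log
likelihood, quasi-Newton outer search, Hessian-based covariance step), and
a Metropolis-within-Gibbs sampler with conjugate variance updates, adaptive
proposals, an interweaving recentering move, and a trend-test burn-in.

## Model

One-compartment, first-order absorption and elimination, single oral dose:

    C(t) = D·ka / (V·(ka − ke)) · (exp(−ke·t) − exp(−ka·t)),   ke = CL/V

with lognormal subject effects `V_i = θ_V·exp(η_V)`,
`CL_i = θ_CL·exp(η_CL)`, `η ~ N(0, ω²)`, and proportional residual error
`y = C_pred·(1 + ε)`, `ε ~ N(0, σ²)`. IIV is reported as
`CV% = 100·√(exp(ω²) − 1)`.

The four estimation configurations compared:

| label    | description                                    |
|----------|------------------------------------------------|
| FOCE-I   | maximum likelihood, FOCE with interaction      |
| BAYES    | MCMC, all parameters free, initialised at truth|
| BAYES(F) | MCMC with ω² fixed at the true values          |
| BAYES(C) | FOCE-I first, its estimates seeding the chain  |

Performance is summarised by the relative estimation error
`REE = 100·(P_est − P_true)/P_true` (median = bias, spread = precision) and
the relative root-mean-squared error
`rRMSE = √(mean(((P_est − P_true)/P_true)²))`.

## Worked example

```r
library(pksse)

truth <- pop_params(ka = 2, v_f = 40, cl_f = 10,
                    omega2_v = cv_to_omega2(30),
                    omega2_cl = cv_to_omega2(30), sigma2 = 0.01)

d <- simulate_pk_dataset(study_design(), truth, seed = 42)
fit <- fit_foce(d, truth)
fit
#> <pk_fit: FOCE-I>
#>        ka       v_f      cl_f  omega2_v omega2_cl    sigma2
#>   1.83900  43.81000  14.08000   0.04449   0.06316   0.01358
#> OFV: -129.9997
#> minimization: TRUE; covariance: TRUE
```

One simulated 6-subject study: the fixed effects land within ~10–40 % of
the truth (ka 1.84 vs 2, V/F 43.8 vs 40, CL/F 14.1 vs 10 — six subjects at
30 % IIV carry little information), and the IIV variances are shrunk below
the generative 0.0862, the typical small-sample behaviour the package is
built to quantify. `tidy(fit)` and `glance(fit)` give broom-style views;
Bayesian fits add posterior spread and the stored chain.

A miniature method-comparison sweep:

```r
cfg <- sse_config(
  design = study_design(iiv_levels = c(10, 50), n_replicates = 10),
  methods = c("FOCE-I", "BAYES"),
  mcmc_settings = mcmc_settings(n_burn_max = 1000, n_stationary = 2000),
  master_seed = 1
)
tab <- run_sse(cfg)          # long table: level x replicate x method x parameter
summarize_sse(tab)           # rRMSE, median REE, quartiles per group
success_rates(tab)           # minimisation / covariance bookkeeping
autoplot(summarize_sse(tab)) # rRMSE vs IIV level, one panel per parameter
autoplot(tab)                # REE box plots
```

`run_case_study()` runs the same pipeline with the theophylline
parameterisation (CL/F = 2.88 L/h, V/F = 33.01 L, ka = 1.46 /h, IIV on all
three parameters).

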