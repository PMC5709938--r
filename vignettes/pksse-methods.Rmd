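---
title: "Methods: simulation and estimation for small-sample population PK"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and estimation for small-sample population PK}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Exploratory pharmacokinetic studies often enrol very few subjects — six is
typical of a first-in-class preclinical or early clinical cohort. With so
little data, the choice of estimation method for a nonlinear mixed-effects
(population) model can materially change both the population means and,
especially, the inter-individual variability (IIV) estimates. `pksse`
implements a complete stochastic-simulation-and-estimation (SSE) workbench
for studying this question: it simulates replicate small-N studies from a
known truth, re-estimates each one with a classical likelihood method
(FOCE-I) and with Markov-chain Monte Carlo Bayesian estimation (three
variants), and summarises estimator bias and precision.

## Model

The structural model is a one-compartment system with first-order
absorption and elimination,

$$\frac{dA_d}{dt} = -k_a A_d, \qquad
  \frac{dA_c}{dt} = k_a A_d - \frac{CL/F}{V_d/F} A_c,$$

whose closed-form concentration after a single oral dose $D$ at $t=0$ is

$$C(t) = \frac{D\,k_a}{V (k_a - k_e)}\left(e^{-k_e t} - e^{-k_a t}\right),
  \qquad k_e = \frac{CL}{V},$$

with the L'Hôpital limit $C(t) = (D k_a t / V)\,e^{-k_a t}$ at the
flip-flop point $k_a = k_e$. The branch switches when
$|k_a - k_e| < 10^{-8} k_a$; continuity across the switch is part of the
test suite. Concentrations are amounts over volume (mg/L) and the dose
enters the depot as a bolus, mirroring a NONMEM `EVID = 1` record.

Between-subject variability is lognormal on $V_d/F$ and $CL/F$:
$V_i = \theta_V e^{\eta_{V,i}}$, $CL_i = \theta_{CL} e^{\eta_{CL,i}}$ with
$\eta \sim N(0, \omega^2)$, and the residual model is proportional,
$y_{ij} = C_{pred,ij}(1 + \varepsilon_{ij})$,
$\varepsilon \sim N(0, \sigma^2)$, so $\mathrm{Var}(y_{ij}) =
C_{pred,ij}^2 \sigma^2$. IIV is reported as a coefficient of variation,
$CV = \sqrt{e^{\omega^2} - 1}$, and `cv_to_omega2()` /
`omega2_to_cv()` convert exactly in both directions.

## Study conditions

The generator's defaults are the conditions of the simulation study the
package reproduces:

* 6 subjects, 8 samples per subject within 24 h, single oral dose;
* $\theta = (k_a, V_d/F, CL/F) = (2\ \mathrm{h}^{-1}, 40\ \mathrm{L},
  10\ \mathrm{L/h})$ — the printed unit "L/h" for $k_a$ is treated as a
  typographical slip, a first-order rate constant being $\mathrm{h}^{-1}$;
* IIV levels 5, 10, 20, 30, 50, 80 CV%, applied equally to $V_d/F$ and
  $CL/F$; 100 replicate datasets per level (600 in total).

Three design quantities are not printed anywhere and were fixed once, a
priori, at values a pharmacokineticist would consider routine; they are
recorded in every dataset's metadata and are all configurable:

* dose **320 mg** (the theophylline case study's oral dose);
* sampling at **0.25, 0.5, 1, 2, 4, 8, 12, 24 h** — an absorption-weighted
  log-like schedule spanning the stated 24 h window;
* proportional residual CV **10 %** ($\sigma^2 = 0.01$).

Simulated concentrations are *not* truncated at zero: a proportional
normal error can produce negative observations at late, low
concentrations, and truncation would change the generative model the
estimators assume. Datasets are written and read in NONMEM-style CSV
(`ID,TIME,AMT,EVID,MDV,DV`, with an optional `REP` column for the
long dialect).

The theophylline case study re-parameterises the generator from the
printed final-model estimates ($CL/F = 2.88$ L/h, $V_d/F = 33.01$ L,
$k_a = 1.46\ \mathrm{h}^{-1}$; IIV 25.69 %, 13.48 %, 65.39 %). Those three
IIV values are listed "respectively" after $CL/F$, $V_d/F$ and $k_a$, which
implies a random effect on $k_a$ in that model only; the estimators
therefore support an optional $\eta_{k_a}$, activated whenever
`omega2_ka > 0`. The true sampling schedule of that dataset is not printed;
an 11-point schedule ending at 24.3 h is used.

## FOCE-I

`fit_foce()` maximises the first-order-conditional-estimation-with-
interaction approximation to the marginal likelihood. For each subject the
conditional mode (empirical Bayes estimate) solves

$$\hat\eta_i = \arg\min_\eta \sum_j \left[\log(\sigma^2 f_{ij}(\eta)^2) +
  \frac{(y_{ij} - f_{ij}(\eta))^2}{\sigma^2 f_{ij}(\eta)^2}\right] +
  \eta' \Omega^{-1} \eta,$$

where the residual variance is evaluated at the current $\eta$ — the
$\eta$–$\varepsilon$ interaction. The marginal objective, up to the
constant $n \log 2\pi$ (omitted, following the NONMEM reporting
convention), is

$$\mathrm{OFV} = \sum_i \log\det C_i + r_i' C_i^{-1} r_i, \qquad
  C_i = G_i \Omega G_i' + \mathrm{diag}(\sigma^2 f_{ij}(\hat\eta_i)^2),$$

with $G_i = \partial f_i/\partial\eta$ at $\hat\eta_i$ and
$r_i = y_i - f_i(\hat\eta_i) + G_i \hat\eta_i$. Correctness is anchored to
an adaptive Gauss–Hermite quadrature oracle in the test suite (OFV
differences within 2 % on two-subject models), not to any external
implementation.

Numerical choices:

* **Inner problem.** A damped Gauss–Newton iteration with analytic
  sensitivities $\partial f/\partial\eta$ (exact for the closed-form
  model; central finite differences only in the measure-zero flip-flop
  neighbourhood), warm-started from the previous outer iterate, with a
  BFGS fallback if the gradient norm tolerance ($10^{-6}$ by default) is
  not met. The analytic $G_i$ doubles as the linearisation matrix of the
  objective.
* **Outer problem.** Quasi-Newton (`nlminb`) over
  $\log\theta, \log\omega^2, \log\sigma^2$ — the log transform enforces
  positivity and makes the problem smooth and unconstrained.
* **Convergence.** NONMEM's `SIG = 3` test is proprietary; the proxy used
  here is the optimiser's own relative-convergence report, backed by a
  central-difference gradient check scaled to the objective
  ($\max_k |g_k| < 0.5\times10^{-3}(1 + |\mathrm{OFV}|)$).
* **Covariance step.** A finite-difference Hessian of the OFV at the
  optimum (log scale); success means positive definite and finite — the
  R-matrix analogue of a covariance-step pass. Near-boundary IIV estimates
  ($\hat\omega^2 \to 0$) flatten the Hessian and fail this check, which is
  the same qualitative behaviour reported for low-IIV scenarios.
* Degenerate inputs (non-positive predicted concentrations under extreme
  $\eta$, overflowing parameters) are met with penalty values and
  backtracking rather than exceptions; an unrecoverable fit is returned
  with `minimization_success = FALSE`, never thrown.

## Bayesian estimation

`fit_bayes()` is a Metropolis-within-Gibbs sampler for the joint posterior
of $(\theta, \omega^2, \sigma^2, \{\eta_i\})$. The priors are not stated in
the source study (NONMEM defaults were used there); this implementation
uses a flat improper prior on $\log\theta$ and conjugate
$\mathrm{IG}(0.01, 0.01)$ priors on each $\omega^2$ and on $\sigma^2$ —
weakly informative, configurable, and recorded in the fit's settings.
Per iteration:

1. each subject's $\eta_i$ is updated by random-walk Metropolis, all
   subjects in parallel, with per-subject proposal scales adapted during
   burn-in toward ~30 % acceptance;
2. each $\omega^2_k$ is drawn from its conjugate inverse-gamma conditional
   $\mathrm{IG}(a_0 + n/2,\; b_0 + \tfrac12\sum_i \eta_{ik}^2)$ (skipped
   when $\omega^2$ is fixed — the BAYES(F) variant);
3. each $\log\theta_k$ is updated by componentwise random-walk Metropolis,
   followed by an exact *recentering* Gibbs draw for every component that
   carries a random effect: holding the subject-level sums
   $c_i = \log\theta + \eta_i$ fixed (the likelihood is untouched),
   $\log\theta \mid c, \omega^2 \sim N(\bar c, \omega^2/n)$. This
   ancillarity–sufficiency interweaving step removes the slow random-walk
   coupling between $\theta$ and the $\eta$ field that otherwise dominates
   the chain's autocorrelation time;
4. $\sigma^2$ is drawn from
   $\mathrm{IG}(a_0 + N/2,\; b_0 + \tfrac12\sum (y-f)^2/f^2)$.

Burn-in runs at most `n_burn_max` iterations (4000 by default) and ends
early when the stationarity test passes: every `test_interval` iterations
the most recent half of the burn-in is tested for a linear trend in the
log-posterior, each $\theta$, each $\omega^2$ and $\sigma^2$. Because raw
draws are autocorrelated, the slope's standard error uses the long-run
variance of the detrended series (Geyer's initial-positive-sequence
estimator) with effective-sample-size degrees of freedom; a series passes
when the slope is not significant at $\alpha = 0.01$. The stationary phase
stores all `n_stationary` draws (no thinning; 10,000 by default), and the
reported estimate is the posterior mean, with medians also stored. The
burn-in convergence flag doubles as `minimization_success`;
`covariance_success` is always true for the Bayesian fits, the posterior
spread being available by construction. `SIGL = 8` has no direct analogue
in this sampler and is recorded for provenance only.

The composite method (`fit_bayes_composite()`, label BAYES(C)) runs FOCE-I
first and starts the chain from its estimates, falling back to the user's
initials (flagged) if the FOCE-I stage fails hard. BAYES(F) fixes
$\omega^2$ at the initial (true) values.

## The SSE engine and metrics

`run_sse()` drives the full experiment: for each (IIV level, replicate)
cell one dataset is simulated and *shared by all methods* — the standard
SSE practice, which makes method comparisons paired; whether the source
study shared datasets across methods is not stated, and sharing is this
package's documented choice. All fits are initialised at the generative
truth, matching the study's initialisation policy. Every random stream
(simulation and chain) is derived by hashing
`(master_seed, level, replicate, method)`, so any subset of the sweep is
reproducible in isolation and results are independent of execution order.
Failures are data: a failed fit becomes a row with
`minimization_success = FALSE`, and `success_rates()` tabulates
minimisation and covariance rates per method and level.

Performance metrics follow the study's two summaries. The relative
estimation error is the signed percentage
$\mathrm{REE} = 100\,(P_{est} - P_{true})/P_{true}$; the square root that
appears in the source's REE formula would be undefined for the negative
biases reported there and is treated as a typographical error. The
relative root-mean-squared error is reported in its conventional form
$\mathrm{rRMSE} = \sqrt{n^{-1}\sum ((P_{est}-P_{true})/P_{true})^2}$; the
printed variant (which divides the squared error by $P_{true}$, not
$P_{true}^2$, and by $n^2$) is dimensionally inconsistent but is computed
alongside as `rrmse_variant_printed` for transparency. All comparisons use
the conventional form. Group summaries (`summarize_sse()`) use type-7
quantiles, include only replicates whose minimisation succeeded (with
`n_used` reported — the source does not state its handling of failures),
and keep empty groups visible as missing rows.

## Desk-scale problem sizes

The package's checks re-run the experiment at sizes chosen to keep a
complete verification run on a single core while preserving the
qualitative comparisons: the FOCE-I bias sweep uses 50 replicates per IIV
level (300 fits); the four-method comparison uses 30 replicates at the
10 %, 50 % and 80 % levels with chains of 1000 burn-in / 2000 stationary
iterations and a 250-iteration test interval (the full-scale defaults of
4000/10,000/500 remain the function defaults); large-sample checks use
100–150 subjects. These sizes are the package's documented choices for its
own verification, not limits of the methods.

## What the simulation does and does not show

The generator emulates the designed conditions exactly: lognormal IIV,
proportional error, a fixed common schedule, and a single bolus dose. Real
datasets differ in ways the simulation deliberately omits — irregular
sampling, dropouts and BLQ censoring, covariate effects, inter-occasion
variability, model misspecification. Passing the package's checks
therefore demonstrates correctness of the estimators *under the assumed
model*, and the method ranking it reproduces (FOCE-I more reliable than
the Bayesian variants for this simple model at small N and high IIV)
should not be extrapolated to complex models or rich data, where the
opposite ranking has been reported.

One empirical caveat the package's own runs make visible: with six
subjects, the maximum-likelihood estimate of an IIV variance is strongly
right-skewed downward — the median of an ML variance estimate over five
effective degrees of freedom sits near $-27\%$ relative error even when
each subject's parameters are observed perfectly, and the package's FOCE-I
medians across levels land in the $-20\%$ to $-50\%$ range. The source
study reports medians no lower than $-17\%$; that figure is consistent
with summaries restricted to replicates passing the covariance step
(which preferentially removes near-boundary, strongly negative
$\hat\omega^2$ fits — at 5 % IIV roughly half of them) but is not
reproduced by the unfiltered median of a faithful ML estimator under
these conditions. The package reports the unfiltered summaries, with
`n_used` alongside.

## Limitations

Single-dose, one-compartment, diagonal $\Omega$, proportional error only;
no BLQ likelihood; no FO/Laplace variants; single-chain MCMC without
cross-chain diagnostics (matching the single-chain design it mirrors).
The Bayesian point estimate is the posterior mean, which for skewed
small-N posteriors (notably $\omega^2$) sits above the mode — part of the
positive bias the method comparison measures rather than an artefact.
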