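---
title: "Residual dynamic SEM for momentary assessment data: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual dynamic SEM for momentary assessment data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific setting

Ecological momentary assessment (EMA) delivers short smartphone surveys many
times a day, yielding per-person time series of momentary stress ratings and
momentary symptom ratings.  The question this package is built around is
directional: do momentary feelings of stress drive subsequent (or same-hour)
symptom experiences, do symptoms drive stress, or both?  Because prompts are
pseudo-random and adherence is incomplete, the raw series are irregular;
because people differ in their typical levels, within-person dynamics must be
separated from stable between-person differences.

## The model

Observations are first aligned to a uniform grid of 24 hourly slots per day,
common midnight origin, with missing values inserted in empty slots (most
slots are structurally empty: at most 8 of 24 daily slots can be observed
under the default design).  For person $i$ and slot $t$, with $K$ observed
variables $y_{it}$ (momentary stress first, symptom composite(s) after):

$$ y_{it} = \mu_i + d_{it}, \qquad
   M_0\, d_{it} = M_1\, d_{i,t-1} + e_{it}, \qquad e_{it} \sim N(0, \Psi), $$

a random-intercept cross-lagged panel structure: $\mu_i \sim N(\nu,
\Sigma_B)$ carries the stable between-person differences, and the VAR(1) on
the within-person deviations $d_{it}$ carries the dynamics.  $M_1$ holds the
autoregressive and cross-lagged (lag-1) paths.  The contemporaneous (lag-0)
association — effects acting within one hour, faster than the grid can
resolve — is wired in one of three ways through $M_0 = I - B_0$ and $\Psi$:

* **covariance** (model A): $B_0 = 0$, $\Psi$ a free $2 \times 2$ covariance
  (undirected);
* **stress → symptom** (model B): a directed lag-0 path from stress onto the
  symptom composite, $\Psi$ diagonal;
* **symptom → stress** (model C): the opposite directed path.

Because the dynamics act on deviations from the person mean ("latent
centering"), this is the residual-DSEM convention: identical to a DSEM with
autoregression on residuals when there are no within-level covariates.

**A caution on comparing the three wirings.** With fixed coefficients the
three variants are bijective reparameterizations of the same conditional
Gaussian family (the free covariance and the two triangular factorizations
span the identical transition/innovation set), so they fit any dataset
equally well up to prior effects; information criteria order them by
Monte-Carlo noise rather than substance.  `compare_lag0_models()` therefore
reports DIC together with a parsimony count and plausibility flags and leaves
the final selection to the analyst; the `selection_record()` flags the
disagreement whenever the DIC winner is not the most parsimonious model.
The wirings do become distinguishable once person-level random slopes are
attached to specific paths.

Extensions estimated in the same framework: person-level random slopes on
chosen paths (slope $\beta_{ij} \sim N(g_{0j} + x_i^\top g_j, \tau_j^2)$,
with moderators $x_i$ z-scored internally), person-level log-normal residual
variances ($\log \sigma^2_{ik} \sim N(\lambda_k, \omega^2_k)$), and
trivariate symptom-split models with two symptom composites and two directed
lag-0 paths onto stress.

## Estimation

`rdsem_fit()` runs a blocked Gibbs sampler (compiled core):

1. **Missing-slot imputation.** Every missing scalar is drawn from its
   Gaussian full conditional given its slot neighbours, the same-slot other
   variables, and the current parameters (single-site updates).  A missing
   first slot uses the stationary prior $d_{i1} \sim N(0, V)$, $V$ solved
   from the discrete Lyapunov equation by a doubling iteration.
2. **Coefficients.** Conjugate normal updates per equation (directed modes)
   or a matrix-normal update with inverse-Wishart residual covariance
   (covariance mode).
3. **Random slopes and hyperparameters.** Conjugate person-wise normal
   updates, then normal/inverse-gamma updates of the slope means, moderator
   coefficients and slope variances.
4. **Residual variances.** Inverse-gamma (homogeneous) or a random-walk
   Metropolis step on each person's log residual variance (step SD 0.3,
   accepting around 0.3–0.5 in practice), with conjugate updates of
   $\lambda_k, \omega^2_k$.
5. **Intercepts and between-level.** Conjugate normal updates of $\mu_i$ and
   $\nu$; inverse-Wishart update of $\Sigma_B$.

Parameter updates use the likelihood conditional on the first grid slot; the
stationary term enters only through imputation.  All randomness flows
through R's RNG, so a seed makes a fit bit-reproducible (chains run
sequentially with per-chain seeds and saved RNG states).

**Priors.** Diffuse proper defaults in the spirit of common Bayesian SEM
software: $N(0, 10^{10})$ for coefficients and means,
inverse-gamma(0.001, 0.001) for variances, inverse-Wishart(I, $K+1$) for
covariance matrices.  All are arguments of `rdsem_priors()` so sensitivity
analyses are one call away.

**Convergence.** At least 2000 iterations per chain (the package default,
matching standard practice for these models); thereafter the potential scale
reduction — the between/within variance ratio over the second half of each
of at least two chains — is checked every 100 iterations until every stored
parameter is below 1.05 or the iteration cap is reached, in which case the
fit is flagged rather than discarded.  Posterior summaries use the second
half of each chain.

**Standardization.** Within-level coefficients are standardized per draw by
the ratio of model-implied within-person stationary SDs of predictor and
outcome (per person, then averaged over persons, when random effects make
the implied moments person-specific); the lag-0 covariance is reported as a
residual correlation and the between-level covariance as a correlation.
Two-tailed significance follows the reporting convention of flagging
one-tailed posterior sign probabilities below 0.025.

**DIC.** The deviance is $-2$ times the observed-data log-likelihood
conditional on the person-level parameters and the dynamic parameters, with
missing slots marginalized analytically by a Kalman filter over the slotted
state space; $p_D = \overline{D} - D(\hat\theta)$ at posterior means.  This
conditioning is one of several DIC variants; it is logged with every
pipeline run, and the comparability caveat above applies with force.

**Moderation.** Moderators are estimated inside the hierarchy (regressed on
the random slope within the MCMC, not post hoc).  The joint Wald test uses
the posterior mean vector and posterior covariance of the moderator
coefficients, referred to $\chi^2_{q}$.

## The synthetic-data generator

`simulate_ema_dataset()` emulates the study design: 7 days × 8 prompts
pseudo-randomly placed between 08:00 and 22:00 with ≥ 25 minutes spacing
(exact uniform sampling over the constrained region via the gap
construction), optional one-time postponement of each prompt by 5/10/15
minutes (independent Bernoulli, default rate 0.1 — protocols offer the
option but usage rates are rarely recorded, so a modest rate was chosen
once), and per-person adherence drawn from a beta distribution with mean
69.24% and SD 24.65% (compliance moments typical of clinical EMA cohorts; a
scalar rate is available for controlled experiments).  Person covariates
use plausible marginals (age uniform over 11–36 years, sex
Bernoulli(0.506)) and
plausible bounded integer distributions for the interview severities
(binomial(5, 0.4) and binomial(14, 0.35)), which were chosen once as
realistic mid-range severities for a clinical-high-risk cohort.

Generating coefficients are interpreted on the standardized scale: residual
variances are calibrated so every within-person stationary variance is 1
(a linear solve for the directed wirings, a fixed-point iteration for the
covariance wiring), making raw and standardized generating values coincide.
The default magnitudes (autoregressions 0.45/0.60, lag-0 0.28, between
correlation 0.34) are typical of momentary stress–symptom analyses and are
configuration values, not truth claims.  Initial states are drawn from the
exact stationary distribution rather than by burn-in.

The 21 symptom items are continuous linear-Gaussian functions of the latent
momentary symptom level (default loading 1, noise SD 0.5, optional rounding
to the 0–6 scale); the analysis consumes composite means only, so
composite-level fidelity is the contract.  The default item catalog (14
basic-symptom + 7 attenuated-psychotic items; 6 perceptive / 15
nonperceptive) is a synthetic default — the study-specific perceptive
mapping is not in the published tables — and is user-overridable.

**What the generator does not emulate:** informative (symptom-dependent)
missingness, ordinal measurement with thresholds, time-of-day periodicity,
reactivity, or item-order effects.  Passing tests on generated data
therefore demonstrate estimator correctness under the model's assumptions,
not robustness to these real-data features.

**Matched-DGP calibration.** The package's recovery and calibration
experiments (conjugate and imputation oracles, study-scale recovery,
interval coverage, Wald null calibration) generate items with zero
measurement noise so the composite equals the latent level and the fitted
model coincides with the generating process.  With the default item noise
the composite is an error-laden proxy and the collinear pair $(m_t,
m_{t-1})$ in the stress equation acquires a small errors-in-variables bias —
a genuine robustness phenomenon, but one that would confound a test of the
estimator itself.

## Problem sizes used by the test-suite experiments

Chosen as the smallest sizes at which the checked asymptotics are reliable:
oracles use one person (200 complete slots; 8 slots with 3 missing);
recovery and misspecification use 20 replications of 60 persons × 7 days at
adherence 0.69 with 2 chains × 2000 iterations; calibration uses 100
replications of 30 persons × 3 days at adherence 0.8 with 800 iterations.

## Numerical and design choices

* Grid covers the full 24-hour day; overnight slots are structurally
  missing, letting effects decay across gaps via the VAR propagation.
* Slot binning is floor-based (left-closed hourly bins); boundary times go
  to the later slot.  Two observations in one slot keep the earlier one,
  with a warning (the reference software's tie rule is not documented).
* Persons with fewer than two observations are excluded with a warning, as
  are persons with missing moderator values in moderation fits.
* The credible-interval-overlap rule for contrasting the two split lag-0
  effects is retained for comparability, and the posterior distribution of
  the difference is always co-reported (labelled), since CI overlap is a
  conservative criterion.
* "Significant path" means the one-tailed posterior sign probability is
  below 0.025 (the two-tailed reporting convention), both for flagging and
  for choosing which paths receive random slopes in
  `add_random_effects()`.
* Pipeline stage seeds derive deterministically from the master seed
  (`seed + 1000 × stage index`) so stages are individually reproducible.

## Known limitations

Lags beyond 1, within-level covariates, ordinal measurement models, and
variational/HMC estimation are out of scope.  The DIC variant implemented
here need not match other software numerically, and — as emphasized above —
DIC should not be the sole arbiter among the three lag-0 wirings.
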