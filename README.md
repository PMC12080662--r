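# emadsem

Bayesian analysis of bidirectional stress–symptom dynamics in ecological
momentary assessment (EMA) time series, for researchers studying momentary
experiences in clinical high-risk and related populations.

Smartphone-based EMA delivers a handful of pseudo-randomly timed prompts per
day; each prompt records a momentary stress rating and ratings of 21
momentary symptom items (14 basic symptoms, 7 attenuated/brief psychotic
symptoms).  The substantive question is directional: does momentary stress
drive symptom experiences, do symptoms drive stress, or both — within the
hour, and from one hour to the next?

## The model

Observations are aligned to a uniform hourly grid (24 slots/day, missing
values in empty slots).  For person *i* and slot *t*, with observed
variables *y* (stress and symptom composite):

    y_it = mu_i + d_it
    M0 d_it = M1 d_i,t-1 + e_it,   e_it ~ N(0, Psi),   mu_i ~ N(nu, Sigma_B)

a two-level random-intercept cross-lagged panel model: `M1` holds the
autoregressive and cross-lagged paths; the contemporaneous (lag-0)
association is wired either as an undirected residual covariance (model A),
a directed stress→symptom path (model B), or a directed symptom→stress path
(model C) through `M0 = I − B0`.  Estimation is by Gibbs sampling with
within-sampler imputation of every missing grid slot, PSR convergence
monitoring, within-person standardization, and an observed-data DIC
(missing slots marginalized by a Kalman filter).  Random slopes, random
residual variances, person-level moderation with a joint Wald test, and
trivariate symptom-split models are fitted in the same framework.  A
synthetic-data generator reproduces the study design (7 days × 8 prompts in
08:00–22:00, ≥ 25 min spacing, postponement, ~69% adherence) so every stage
is testable end to end.

See the methods vignette (`vignettes/rdsem-methods.Rmd`) for the estimation
details, priors, design choices, and an important caveat on comparing the
three lag-0 wirings by DIC.

## Worked example

```r
library(emadsem)
pop <- population_params()          # symptom->stress lag-0 wiring, defaults
ds  <- simulate_ema_dataset(pop, n_persons = 20, seed = 42)
g   <- grid_ema_dataset(ds$long, ds$grid, ds$catalog)
fit <- rdsem_fit(g, rdsem_model("C"), mcmc = mcmc_settings(seed = 1))
print(fit)
writeLines(format_results_table(render_results_table(summary(fit))))
```

```
Residual-DSEM fit: 2 variables ( stress, mchr ), lag0 = y_to_x 
  20 persons, 2 chains x 2000 iterations (converged)
  max PSR = 1.040, DIC = 3877.09 (pD = 41.2)
path                                  est        p      LCI      UCI    
------------------------------------------------------------------------
stress[t-1] → stress[t]           0.436    0.000    0.357    0.518   *
stress[t-1] → mchr[t]             0.020    0.323   -0.078    0.111    
mchr[t-1] → stress[t]             0.078    0.088   -0.033    0.184    
mchr[t-1] → mchr[t]               0.485    0.000    0.386    0.569   *
mchr[t] → stress[t]               0.239    0.000    0.161    0.317   *
stress ←→ mchr (between)        0.229    0.157   -0.241    0.631    
DIC = 3877.095 (pD = 41.2), 2000 iterations
```

Reading the table: rows are standardized paths (`A → B` means B regressed
on A; `←→` an undirected association).  Here the generating values were
autoregressions 0.45/0.60, a directed lag-0 symptom→stress effect of 0.28
and zero cross-lags: the fit recovers strong autoregression for both
series, a clearly positive contemporaneous symptom→stress path (0.239, CI
[0.161, 0.317], starred as significant at the two-tailed 0.025 convention)
and no significant cross-lagged effects — the generating structure.  `p` is
the one-tailed posterior probability of the minority sign; the footer shows
the DIC with its effective parameter count and the iteration count.

Model comparison, random-effects augmentation, moderation and symptom-split
contrasts follow the same pattern via `compare_lag0_models()`,
`add_random_effects()`, `fit_moderation()` and `fit_split_symptoms()`, or
end to end via `run_pipeline(run_config(...))`, which writes comparison
tables, a selection record, moderation and contrast reports, and a log of
all active design-decision flags into an output directory.

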