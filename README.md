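# spmjoint

Shared-parameter joint models for longitudinal outcomes with informative
dropout, plus the GEE / mixed-model comparators that together make a
missing-data sensitivity analysis.

## Who this is for

Epidemiologists and biostatisticians analysing long-running cohort
studies in which an outcome-related event truncates follow-up — the
canonical case being cognitive decline measured over ~20 years, where
participants stop contributing assessments once dementia is diagnosed.
Because the unmeasured outcomes of those participants are likely worse
than the measured outcomes of those who remain, estimates from standard
methods depend on their missingness assumptions:

| model | assumption | consistent when dropout depends on |
|---|---|---|
| GEE (sandwich SEs) | MCAR | nothing related to the data |
| linear mixed model (ML) | MAR | observed data only |
| shared-parameter model (SPM) | extended MAR (XMAR) | observed data *and* the subject's latent random effects |

## The model

The SPM couples two sub-models through shared subject-level random
effects `b_i ~ MVN(0, tau)`:

* longitudinal: `Y_ij = X_ij beta + Z_ij b_i + e_ij`, `e_ij ~ N(0, sigma^2)`,
  with random intercept (+ slope);
* event (per cause k, e.g. dementia and optionally death):
  `h_ik(t) = h0k(t) exp(X*_i alpha_k + rho_k . b_i)`.

The loading factors `rho_k` measure how strongly the latent trajectory
drives the censoring event; `rho = 0` collapses the SPM to the ordinary
mixed model (an identity the tests verify).  The likelihood integrates
the random effects out by adaptive Gauss–Hermite quadrature, vectorized
across subjects.  Estimation is maximum likelihood with two-stage
initialization from the separate mixed-model and proportional-hazards
fits; SEs come from the observed information, and derived quantities
(marginalized declines over a horizon, effect attenuation, hazard ratios
per SD of random effect) get delta-method intervals.

A calibrated synthetic cohort generator (`simulate_cohort()`) emulates a
brain-aging cohort — 1840 subjects, visits at 0/6/15/18/20 years, 34%
exposure prevalence, standardized cognitive z-scores, 61% lost to
follow-up, dropout driven by a dementia-like hazard with negative
loadings — so the entire workflow is reproducible with no external data.
See the vignette (`vignettes/shared-parameter-models.Rmd`) for the full
model account, numerical choices and calibration rationale.

## Worked example

```r
library(spmjoint)
spec <- spm_spec("atrophy", adjustors = "age")
sim  <- simulate_cohort(sim_config(n = 500, seed = 7))
summarize_cohort(sim$data, group = "atrophy")
compare_models(sim$data, spec)
```

Output (exactly as printed):

```
Cohort: N = 500; completers 203 (41%); lost to follow-up 297 (59%)
  scheduled waves (years): 0, 6, 15, 18, 20
  loss by group:
 group   n n_lost pct_lost
     0 325    185       57
     1 175    112       64

Model comparison (20-year marginalized declines)

      model         decline without            decline with
 SPM (XMAR) -0.929 (-1.296, -0.561) -1.311 (-1.849, -0.772)
 GLMM (MAR) -0.888 (-1.247, -0.529) -1.218 (-1.737, -0.698)
 GEE (MCAR) -0.672 (-1.062, -0.283) -0.951 (-1.515, -0.387)
                     additional attenuation    AIC    BIC
 -0.382 (-1.017, 0.253) p=0.238       -ref- 6380.9 6456.7
 -0.329 (-0.960, 0.301) p=0.306         14% 4718.1 4756.1
 -0.279 (-0.964, 0.406) p=0.425         27%      –      –

Loading factors (hazard ratio per SD of random effect):
 model cause    effect    hr lower upper    direction
   SPM     1 intercept 2.016 1.626 2.500 per SD lower
   SPM     1     slope 1.132 0.918 1.395 per SD lower
```

Reading it: 59% of this simulated cohort misses at least one scheduled
wave, more among the exposed (64% vs 57%).  Each model row gives the
estimated absolute 20-year cognitive decline (z-score units) without and
with the exposure, marginalized over the adjustors, and the additional
decline attributable to exposure with its Wald CI and p-value.  Moving
up the missingness spectrum the exposure effect strengthens: the GEE
(MCAR) estimate is attenuated 27% and the mixed model (MAR) 14% relative
to the SPM (XMAR) reference — the signature of informative, event-driven
dropout.  AIC/BIC are each model's own criteria (the SPM's covers the
joint longitudinal+event likelihood; none are defined for GEE).  The
loading rows translate the coupling into hazard ratios: a one-SD lower
latent baseline cognition doubles the dementia-censoring hazard
(HR 2.02, 95% CI 1.63–2.50).

`fit_spm()`, `fit_lmm()`, `fit_gee()` and `fit_ph()` are also available
individually, with `summary`, `coef`, `vcov`, `logLik`/`AIC`/`BIC`,
`predict`, `residuals`, `plot` and `simulate` methods;
`fit_spm_competing()` adds a second cause-specific hazard (death)
sharing the same random effects.  A thin command-line front end lives at
`inst/cli/spmjoint.R` (subcommands `simulate`, `fit-lmm`, `fit-gee`,
`fit-spm`, `compare`, `predict`).

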