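---
title: "Estimating long-term antifracture efficacy without a control arm: methods"
author: "fracturetwin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating long-term antifracture efficacy without a control arm: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Long-term extension studies of osteoporosis treatments typically move every
participant onto active drug, so after the randomized core period there is
no concurrent control arm.  The question "how many fractures did ten years
of treatment prevent?" then has no direct comparator.  `fracturetwin`
implements two complementary answers for a trial with a 3-year
placebo-controlled core and a 7-year single-arm extension:

1. **Virtual twins.**  For every treated participant who completed all ten
   years, construct a hypothetical untreated duplicate with identical
   baseline characteristics, and predict the twin's fracture experience from
   models calibrated on the *placebo (crossover) arm's core-period data* —
   the only untreated data the trial produced.  The mean predicted 10-year
   cumulative incidence over all twins is the counterfactual placebo
   incidence.
2. **External 10-year probabilities.**  Compare the observed incidence with
   the mean 10-year fracture probability predicted at baseline by an
   external risk calculator (FRAX-style).  The calculator itself is a black
   box; the package consumes its per-subject outputs and handles
   missing-risk-factor imputation.

Both are compared against the observed Kaplan–Meier cumulative incidence of
major osteoporotic fracture (MOF: clinical vertebral, hip, forearm, or
humerus) and of hip fracture alone, read out at ten years.

## The virtual-twin model

### Placebo-calibrated fracture-rate model

Fracture counts in the placebo arm's core period follow a log-linear
Poisson model with a person-time offset:

$$\log E[N_i] = \beta_0 + \beta^\top x_i + \log t_i,$$

where $N_i$ is the number of MOF events subject $i$ experienced during
core follow-up $t_i \le 3$ years (recurrent events counted — this is a
count model, not a time-to-first-event model), and $x_i$ contains baseline
age, BMI, prior vertebral and prior nonvertebral fracture history, total-hip
T-score, and ever-smoker status.  `fit_placebo_poisson()` obtains the MLE by
iteratively reweighted least squares (tolerance $10^{-12}$, at most 100
iterations) and the covariance as the inverse observed information.  A
quasi-Poisson dispersion is reported as a diagnostic only.

Two modelling choices deserve comment.  *Which T-score?*  The twin
procedure later simulates the **total-hip** T-score at the end of the core
period, so the rate model uses the total-hip T-score as its predictor by
default; a femoral-neck option exists for sensitivity analyses of the fit
itself but cannot feed the twin update.  *One history indicator or two?*
Prior vertebral and prior nonvertebral fracture enter as two separate
indicators by default (`prior_history = "composite"` collapses them).

### Building a twin

For each long-term completer (exactly 3 core + 7 extension years of
follow-up), `build_twins()` composes:

1. **Core period.**  Expected untreated count
   $\mu_{\text{core}} = \exp(\hat\beta^\top x) \cdot 3$ at the subject's own
   baseline covariates.
2. **History update.**  With probability $1 - e^{-\mu_{\text{core}}}$ (the
   Poisson probability of at least one event) the twin acquires a new prior
   fracture, assigned to the vertebral slot with the placebo arm's
   empirical core-period vertebral share, else to the nonvertebral slot.
   The default is a Bernoulli draw; an expectation-weighted variant
   (`history_update = "expected"`) mixes the three history states by their
   probabilities instead.
3. **T-score update.**  The untreated end-of-core total-hip T-score is
   simulated as a normal variable around the mean of a linear model (OLS of
   end-of-core T-score on baseline age, total-hip T-score and BMI, fitted on
   crossover subjects; `fit_tscore_model()`), with the model's residual SD
   as the noise scale.  A numerically perfect fit is rejected: a zero
   residual SD cannot supply the simulation noise.
4. **Extension period.**  Age advances by 3 years; BMI and smoking status
   carry forward unchanged (treatment is not assumed to affect them);
   history and T-score take their updated values; the expected count is
   $\mu_{\text{ext}} = \exp(\hat\beta^\top x') \cdot 7$.
5. **Composition.**  The two expected counts are summed as a cumulative
   hazard and converted to a probability,
   $1 - \exp(-(\mu_{\text{core}} + \mu_{\text{ext}}))$.  This is
   self-consistent with the Poisson model and bounded in $[0, 1]$; an
   uncapped count-scale alternative (`composition = "count"`) exists for
   sensitivity analysis.

The counterfactual placebo incidence is the mean composed incidence over
all twins (`twin_cohort_incidence()`).

### Rate ratio

Treatment efficacy is summarized as the ratio of 10-year cumulative hazards,
$-\log(1 - \text{observed}) \,/\, -\log(1 - \text{twin})$
(`rate_ratio()`).  The raw incidence quotient is reported alongside; the
hazard-scale definition is the natural one for a Poisson rate model and is
the package's headline "rate ratio".

### Bootstrap

`run_twin_analysis()` wraps the whole pipeline in a subject-level
percentile bootstrap: subjects are resampled with replacement *within each
arm*, both placebo models are refitted on the resampled crossover subjects,
and twins are rebuilt — with fresh T-score and history draws — for the
resampled long-term completers.  One twin realization per subject per
resample means the twin-simulation Monte-Carlo noise is absorbed into the
bootstrap CI rather than averaged away.  The 95% CI is the 2.5th/97.5th
percentile of the draws; because observed and twin quantities are recomputed
jointly in every draw, the rate-ratio CI is internally consistent.  The
default is 5000 resamples; the package's own tests use 50–200 for speed.
BCa intervals were considered and not implemented: the percentile interval
is the simplest defensible reading of "bootstrap 95% CI", and the statistics
involved are smooth means.

### Low-event guard

When the placebo arm contributed fewer than 20 core-period events of the
requested type set (the default threshold; hip fractures alone typically
fall under it), the twin pipeline refuses to run: rate models calibrated on
a handful of events produce unreliable counterfactuals.  The refusal is a
typed outcome carried into reports — never a zero — and can be overridden
explicitly, in which case the override is recorded.

## The synthetic trial generator

Patient-level data from the emulating trial are not publicly available, so
`generate_cohort()` produces cohorts with the same design and known ground
truth; every estimator in the package is validated against it.  Defaults
are fixed once and describe the 10-year completer population of the
emulated study:

| Parameter | Default | Source/rationale |
|---|---|---|
| age | 70.8 (SD 4.6), truncated to [60, 90] | completer baseline table; eligibility ages |
| BMI | 25.8 (SD 4.0) kg/m² | completer baseline table |
| femoral-neck T-score | −2.1 (SD 0.7) | completer baseline table |
| prior fracture (either site) | 51% | completer baseline table |
| ever smoker | 7% | completer baseline table |
| parental hip fracture / alcohol ≥3 units | 10% / 2% | completer baseline table (imputation harness only) |
| total-hip T-score | femoral neck + N(0.1, 0.3) | invented linkage, configurable |
| rate model | intercept −7.0; slopes: age 0.04, BMI −0.02, prior vertebral 0.5, prior nonvertebral 0.3, total-hip T-score −0.3, smoker 0.2 | order-of-magnitude plausible gradients, intercept set so the untreated 10-year MOF incidence is ≈23% and the treated ≈11%, the scale of the emulated study |
| treatment rate ratio | 0.5 | emulated effect size |
| hip fraction of MOF events | 0.10 | reproduces the ≈1% observed / ≈6% predicted hip scale |
| T-score 3-year drift | +0.5 treated, −0.1 placebo, noise SD 0.25 | plausible BMD trajectories; configurable, ground truth carries whatever is set |
| dropout | 0.065/yr core, 0.10/yr extension | ≈40% of randomized subjects complete 10 years, as in long-term osteoporosis trials |

The event process is Poisson with a rate that is **piecewise constant over
the core and extension periods**: the extension rate is recomputed from the
same log-linear model with extension-baseline covariates (age + 3, realized
end-of-core T-score, fracture history updated by core events).  This is
exactly the model family the twin engine assumes, which makes parameter
recovery a clean test: the twin estimator should be unbiased here, and the
tests verify that it is (mean absolute bias ≲ 0.005 at trial scale).  A
`weibull_shape` option bends the within-period time scale
(cumulative intensity $r \cdot t^{\text{shape}}$) as a
hazard-misspecification stress; it defaults to 1 (off).

Ground truth records each subject's realized untreated core and extension
rates; `true_counterfactual_incidence()` is the closed-form mean of
$1 - e^{-\Lambda_i(h)}$ over subjects — the oracle for recovery tests.

The generator also fills `frax_mof_prob` / `frax_hip_prob` with **synthetic
stand-ins** for externally computed probabilities: each subject's true
untreated 10-year cumulative hazard, scaled by a configurable bias factor
(defaults 0.65 for MOF, 2.4 for hip — chosen once so the cohort means land
near the 15.6% / 5.6% means of the emulated completer table) and jittered
with mean-one lognormal noise (SD 0.45, matching the ≈10-point SD of the
table).  These columns exercise the comparison harness; they are *not* an
implementation of any published risk calculator.

What the generator deliberately does **not** emulate: mortality as a
competing risk, secular trends within a period, country-specific risk
heterogeneity, dosing compliance, and covariate drift other than the
T-score (BMI and smoking are carried forward, as the twin model assumes).
Passing tests therefore show the estimators are correct *under the model
they assume*, plus the Weibull stress option; they cannot show robustness
to, say, informative dropout, which real extension data might exhibit.

## Missing-risk-factor imputation

External calculators need complete risk-factor profiles.  `impute_missing()`
fills gaps by single stochastic draws from conditional models fitted on the
profiles' own complete cases: linear models (plus Gaussian residual) among
the continuous factors, then logistic models of each binary factor on age,
BMI and femoral-neck T-score.  The reference approach fitted such
associations on large external development cohorts; those are not
available, so the package fits them on the analysis cohort itself — a
documented substitution that preserves the mechanism (conditional-model
single imputation) if not the calibration source.  Observed values are
never altered; glucocorticoid use and rheumatoid arthritis are fixed "no"
(trial exclusion criteria); a repetition count supports sensitivity checks.

## Numerical and design details

- **Time origin.**  Fractional years from core-trial baseline; core is
  $[0, 3)$, extension $[3, 10)$, so a boundary event is never counted in
  both periods.  Events are stored recurrently; Kaplan–Meier uses first
  events only.
- **Kaplan–Meier.**  `km_fit()` delegates to `survival::survfit`.  The 95%
  CI uses the complementary log-log transform by default (kept inside
  $[0,1]$; switchable to the plain Greenwood interval).  Events precede
  censorings at tied times.  The horizon read-out is the right-continuous
  step value at the largest event time ≤ horizon.  Zero events yield
  incidence 0 with the exact binomial upper bound $1 - 0.025^{1/n}$.
- **Missing values** are empty CSV cells, never sentinel numbers; numerics
  serialize at 17 significant digits so write→read is the identity.
- **Randomness.**  One master seed per entry point; derived sub-seeds with
  fixed offsets (the point-estimate twin draws use `seed`, the bootstrap
  stream `seed + 1`), so each stage reproduces in isolation.  The
  generator, the twin draws, the bootstrap and the imputation are all
  deterministic given their seed, to the byte on serialized output.
- **Degenerate inputs.**  Rank-deficient designs name the collinear
  columns; non-converged rate fits refuse downstream prediction; a
  perfect T-score fit is refused; a zero twin incidence refuses the rate
  ratio.

## Test conditions

Recovery tests run at the emulated trial scale ($n = 1278$ per arm, the
completer count of the emulated study) with 100 replicates, bootstrap
coverage with 200 replicates of 200 resamples, and parameter recovery for
the rate model at $n = 5000$ per arm across 100 seeds.  Two recovery
settings set the treated T-score drift equal to the placebo drift: with
different drifts the treated arm also benefits through BMD, so the
configured rate ratio would not be the true composite hazard ratio — the
equal-drift configuration is the one in which "true rate ratio 0.5" (or a
true null) is exactly what the generator produces.

One caveat the tests make explicit: at trial scale the *point* rate ratio
is an honest but noisy estimate.  With ~90–100 placebo core events the
log-rate-ratio standard error is ≈0.14 (the emulated study's own reported
CI implies the same), so individual replicates scatter widely around the
true 0.5 even though the estimator is unbiased and its bootstrap CI covers
the truth at the nominal rate.  Single-trial rate ratios should be read
with their CIs, not as point values.

## Limitations

- The twin method inherits the core-period placebo model; it extrapolates
  untreated behaviour seven years beyond any untreated observation, and
  updates fracture history only once, at the extension baseline.
- Completer-only analysis sets are standard here but condition on
  post-randomization behaviour; the package reports what the design
  permits, not an intent-to-treat effect.
- Hip-only counterfactuals are refused at the default guard threshold for
  exactly the reason the guard exists: too few placebo hip events to
  calibrate a rate model.
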