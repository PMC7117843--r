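# fracturetwin

Quantifying the long-term antifracture efficacy of a treatment when the
extension phase of the trial has no control arm.

Osteoporosis trials typically randomize against placebo for a few years and
then move everyone onto active drug for an open-label extension.  After ten
years there is no concurrent untreated group to compare against, so the
question "how many fractures did treatment prevent?" needs a counterfactual.
`fracturetwin` implements two estimates of the 10-year untreated fracture
incidence for a 3-year core + 7-year extension design, and compares both with
the observed Kaplan–Meier incidence:

1. **Virtual twins.**  For each treated 10-year completer, a hypothetical
   untreated duplicate with identical baseline covariates.  The twin's
   fracture experience comes from a Poisson rate model with a log
   person-time offset,

   log E[N] = β₀ + β·x + log t,

   calibrated on the placebo (crossover) arm's core-period counts, with
   x = (age, BMI, prior vertebral fx, prior nonvertebral fx, total-hip
   T-score, ever-smoker).  Extension-period predictions update age (+3 y),
   the fracture history (a Bernoulli draw with probability 1 − e^(−μ_core)),
   and the total-hip T-score (simulated from a placebo-calibrated linear
   model).  Expected counts compose on the cumulative-hazard scale,
   P(10-y fracture) = 1 − exp(−(μ_core + μ_ext)), and efficacy is the
   hazard-scale rate ratio −log(1 − observed) / −log(1 − twin).  CIs come
   from a subject-level percentile bootstrap that refits the whole pipeline
   on every resample.
2. **External 10-year probabilities** (FRAX-style), supplied as per-subject
   input columns and summarized as mean ± 1.96·SD/√n, with conditional-model
   imputation of missing risk factors.

Because the motivating trial's patient-level data are not public, the
package ships a synthetic trial generator (`generate_cohort()`) with known
ground truth — baseline covariates matching the published completer
population, log-linear fracture rates, a treatment rate multiplier,
arm-specific T-score drift, and dropout — so every estimator is testable
end to end.

## Worked example

```r
library(fracturetwin)

cfg <- sim_config(n_per_arm = 1278, seed = 42)   # emulated study scale
sim <- generate_cohort(cfg)
sim$cohort
#> <fracture_cohort> 2556 subjects, 288 fracture events
#>   arms: placebo_crossover = 1278, denosumab_longterm = 1278
#>   10-year completers: 1066
#>   provenance: simulated seed=42 n_per_arm=1278

res <- run_twin_analysis(sim$cohort, seed = 7, n_boot = 1000)
res
#> <twin_analysis> event set: clinical_vertebral/hip/forearm/humerus, horizon 10 y
#> <event_guard> PASS: 100 placebo core-period events (>= 20): twin analysis allowed
#>   observed KM incidence: 0.1266 (95% CI 0.1017 to 0.1570)
#>   twin incidence:        0.2763 (95% CI 0.2270 to 0.3219)
#> <rate_ratio> 0.4184 (95% CI 0.3076 to 0.5656, 1000 resamples); raw incidence quotient 0.4580
```

Read: among treated completers, 12.7% had a major osteoporotic fracture by
year 10, while their virtual placebo twins accrued 27.6% — a hazard-scale
rate ratio of 0.42, i.e. roughly a halving of the fracture rate.  (This
cohort was simulated with a true rate ratio of 0.5 and a true counterfactual
incidence of 23.2%, `true_counterfactual_incidence(sim$truth, 10)`; the
estimates scatter around those truths with the CIs shown.)

The externally predicted mean probability sits between the two, as in the
study this emulates:

```r
frax_summary(sim$cohort, "mof")
#> <frax_summary> mof: mean 10-year probability 0.1577 (95% CI 0.1541 to 0.1613; SD 0.0930, n = 2556)
```

Hip fractures alone are too sparse in the placebo core period to calibrate
a rate model, and the pipeline says so instead of guessing:

```r
run_twin_analysis(sim$cohort, event_set = "hip", seed = 8)$guard
#> <event_guard> REFUSE: only 12 placebo core-period events (< 20): the low
#>   number of events would lead to unreliable twin estimates; analysis
#>   refused (use override to force)
```

`build_report()` / `write_report()` assemble the observed / predicted /
twin comparison (refusals rendered as refusals, never zeros) as JSON and a
three-bar plot.  A thin command-line front end with `simulate`, `km`,
`fit-poisson`, `twin` and `report` subcommands lives at
`inst/cli/fracturetwin.R`.

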