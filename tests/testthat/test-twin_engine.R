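# Placebo cohort with a controllable end-of-core T-score relationship.
toy_tscore_cohort <- function(n = 40, seed = 41, noise_sd = 0.2,
                              drift = -0.1, slope_th = 1) {
  set.seed(seed)
  age <- rnorm(n, 70, 4)
  th0 <- rnorm(n, -2, 0.6)
  bmi <- rnorm(n, 26, 3)
  end <- drift + slope_th * th0 + rnorm(n, 0, noise_sd)
  fracture_cohort(subj_row(sprintf("t%d", seq_len(n)),
                           arm = "placebo_crossover", age = age, bmi = bmi,
                           th0 = th0, th_end = end, ext = 0))
}

test_that("the T-score model solves the normal equations", {
  cohort <- toy_tscore_cohort(n = 12)
  fit <- fit_tscore_model(cohort)
  s <- cohort$subjects
  X <- cbind(1, s$age_years, s$total_hip_tscore_baseline, s$bmi)
  y <- s$total_hip_tscore_end_core
  beta_ne <- solve(crossprod(X), crossprod(X, y))  # independent route
  expect_equal(unname(fit$coefficients), as.numeric(beta_ne),
               tolerance = 1e-9)
  rss <- sum((y - X %*% beta_ne)^2)
  expect_equal(fit$residual_sd, sqrt(rss / (12 - 4)), tolerance = 1e-9)
})

test_that("a perfect (noise-free) T-score fit is rejected as degenerate", {
  cohort <- toy_tscore_cohort(n = 20, noise_sd = 0)
  expect_error(fit_tscore_model(cohort), "degenerate")
  expect_error(fit_tscore_model(toy_tscore_cohort(n = 4)), "at least 5")
})

test_that("the placebo T-score drift is recovered from simulated data", {
  cfg <- sim_config(n_per_arm = 4000, seed = 42)
  g <- generate_cohort(cfg)
  fit <- fit_tscore_model(g$cohort)
  # data-generating model: end = drift + 1 * baseline + noise
  expect_lt(abs(fit$coefficients[["total_hip_tscore_baseline"]] - 1), 0.05)
  expect_lt(abs(fit$coefficients[["age_years"]]), 0.01)
  expect_lt(abs(fit$coefficients[["bmi"]]), 0.01)
  # the drift is identified by the fitted mean change at the covariate
  # centre (the raw intercept extrapolates far outside the data)
  s <- g$cohort$subjects[g$cohort$subjects$arm == "placebo_crossover" &
                           !is.na(g$cohort$subjects$total_hip_tscore_end_core), ]
  pred_centre <- fit$coefficients[[1]] +
    fit$coefficients[[2]] * mean(s$age_years) +
    fit$coefficients[[3]] * mean(s$total_hip_tscore_baseline) +
    fit$coefficients[[4]] * mean(s$bmi)
  drift_hat <- pred_centre - mean(s$total_hip_tscore_baseline)
  expect_lt(abs(drift_hat - cfg$tscore_drift_placebo), 0.03)
  expect_lt(abs(fit$residual_sd - cfg$tscore_noise_sd), 0.02)
})

test_that("twins of a vanishing-rate model have ~zero incidence and no history update", {
  cohort <- small_twoarm_cohort(seed = 43, n_per_arm = 200)
  pfit <- fit_placebo_poisson(cohort)
  pfit$coefficients[] <- 0
  pfit$coefficients["(Intercept)"] <- -20   # vanishing rate
  tfit <- fit_tscore_model(cohort)
  tw <- build_twins(cohort, pfit, tfit, seed = 1)
  expect_true(all(tw$ten_year_incidence < 1e-6))
  expect_true(all(tw$core_predicted_fx_vertebral == 0))
  expect_true(all(tw$core_predicted_fx_nonvertebral == 0))
})

test_that("extension predictions age the twin by the core duration", {
  cohort <- small_twoarm_cohort(seed = 44, n_per_arm = 400)
  pfit <- fit_placebo_poisson(cohort, predictors = "age_years")
  tfit <- fit_tscore_model(cohort)
  id <- completers(subset_arm(cohort, "denosumab_longterm"))$
    subjects$subject_id[1]
  tw <- make_virtual_twin(cohort, id, pfit, tfit, seed = 2)
  age0 <- cohort$subjects$age_years[cohort$subjects$subject_id == id]
  b <- pfit$coefficients
  expect_equal(tw$core_expected_count,
               exp(b[[1]] + b[[2]] * age0) * 3, tolerance = 1e-12)
  expect_equal(tw$ext_expected_count,
               exp(b[[1]] + b[[2]] * (age0 + 3)) * 7, tolerance = 1e-12)
  expect_equal(tw$ten_year_incidence,
               1 - exp(-(tw$core_expected_count + tw$ext_expected_count)),
               tolerance = 1e-15)
})

test_that("twin draws follow the documented RNG order and are reproducible", {
  cohort <- small_twoarm_cohort(seed = 45, n_per_arm = 300)
  pfit <- fit_placebo_poisson(cohort)
  tfit <- fit_tscore_model(cohort)
  tw1 <- build_twins(cohort, pfit, tfit, seed = 7)
  tw2 <- build_twins(cohort, pfit, tfit, seed = 7)
  expect_identical(tw1, tw2)
  # recompute the simulated T-score from the recorded draw order:
  # history uniforms, slot uniforms, then standard normals
  n <- nrow(tw1)
  set.seed(7)
  runif(n); runif(n)
  z <- rnorm(n)
  s <- completers(subset_arm(cohort, "denosumab_longterm"))$subjects
  mean_ts <- tfit$coefficients[[1]] +
    tfit$coefficients[[2]] * s$age_years +
    tfit$coefficients[[3]] * s$total_hip_tscore_baseline +
    tfit$coefficients[[4]] * s$bmi
  expect_equal(tw1$ext_tscore_simulated, mean_ts + z * tfit$residual_sd,
               tolerance = 1e-12)
})

test_that("composed incidence is bounded by the summed expected counts", {
  for (seed in c(46, 47)) {
    cohort <- small_twoarm_cohort(seed = seed, n_per_arm = 300)
    pfit <- fit_placebo_poisson(cohort)
    tfit <- fit_tscore_model(cohort)
    tw <- build_twins(cohort, pfit, tfit, seed = seed)
    expect_true(all(tw$ten_year_incidence <=
                      tw$core_expected_count + tw$ext_expected_count))
    expect_true(all(tw$ten_year_incidence >= 0 &
                      tw$ten_year_incidence <= 1))
  }
})

test_that("the expectation-weighted history variant mixes the three states", {
  cohort <- small_twoarm_cohort(seed = 48, n_per_arm = 300)
  pfit <- fit_placebo_poisson(cohort)
  tfit <- fit_tscore_model(cohort)
  vs <- vertebral_split(cohort)
  tw <- build_twins(cohort, pfit, tfit, seed = 3,
                    history_update = "expected")
  s <- completers(subset_arm(cohort, "denosumab_longterm"))$subjects
  i <- 5L
  p_ev <- 1 - exp(-tw$core_expected_count[i])
  expect_equal(tw$core_predicted_fx_vertebral[i], p_ev * vs,
               tolerance = 1e-12)
  base <- data.frame(age_years = s$age_years[i] + 3, bmi = s$bmi[i],
                     prior_vertebral_fx = s$prior_vertebral_fx[i],
                     prior_nonvertebral_fx = s$prior_nonvertebral_fx[i],
                     tscore = tw$ext_tscore_simulated[i],
                     ever_smoker = s$ever_smoker[i])
  mix <- function(v, nv) {
    d <- base
    d$prior_vertebral_fx <- pmax(as.numeric(d$prior_vertebral_fx), v)
    d$prior_nonvertebral_fx <- pmax(as.numeric(d$prior_nonvertebral_fx), nv)
    expected_count(pfit, d, 7)
  }
  manual <- (1 - p_ev) * mix(0, 0) + p_ev * (vs * mix(1, 0) +
                                               (1 - vs) * mix(0, 1))
  expect_equal(tw$ext_expected_count[i], manual, tolerance = 1e-10)
})

test_that("non-completers are refused as twin inputs", {
  cohort <- small_twoarm_cohort(seed = 49, n_per_arm = 300)
  pfit <- fit_placebo_poisson(cohort)
  tfit <- fit_tscore_model(cohort)
  s <- cohort$subjects
  non_comp <- s$subject_id[s$arm == "denosumab_longterm" &
                             s$extension_followup_years < 7][1]
  expect_error(make_virtual_twin(cohort, non_comp, pfit, tfit, seed = 1),
               "completer")
  crossover <- s$subject_id[s$arm == "placebo_crossover"][1]
  expect_error(make_virtual_twin(cohort, crossover, pfit, tfit, seed = 1),
               "completer")
})

test_that("a large homogeneous cohort converges to the closed-form incidence", {
  beta <- c(intercept = log(0.024), age_years = 0, bmi = 0,
            prior_vertebral_fx = 0, prior_nonvertebral_fx = 0,
            total_hip_tscore = 0, ever_smoker = 0)
  g <- generate_cohort(sim_config(n_per_arm = 5000, seed = 50,
                                  rate_coefficients = beta))
  pfit <- fit_placebo_poisson(g$cohort)
  tfit <- fit_tscore_model(g$cohort)
  est <- twin_cohort_incidence(g$cohort, pfit, tfit, seed = 4)
  expect_lt(abs(as.numeric(est) - (1 - exp(-0.24))), 0.01)
})

test_that("twin_cohort_incidence of a single completer equals its twin", {
  cohort <- small_twoarm_cohort(seed = 51, n_per_arm = 300)
  pfit <- fit_placebo_poisson(cohort)
  tfit <- fit_tscore_model(cohort)
  id <- completers(subset_arm(cohort, "denosumab_longterm"))$
    subjects$subject_id[1]
  keep <- c(cohort$subjects$subject_id[
    cohort$subjects$arm == "placebo_crossover"], id)
  sub <- subset_cohort(cohort, keep)
  est <- twin_cohort_incidence(sub, pfit, tfit, seed = 8)
  tw <- make_virtual_twin(sub, id, pfit, tfit, seed = 8)
  expect_equal(as.numeric(est), tw$ten_year_incidence)
})

test_that("the low-event guard refuses sparse endpoints and honours overrides", {
  cohort <- small_twoarm_cohort(seed = 52, n_per_arm = 400)
  hip <- low_event_guard(cohort, "hip", min_events = 20)
  expect_false(hip$pass)
  expect_match(hip$message, "refused")
  mof <- low_event_guard(cohort, mof_event_types, min_events = 20)
  expect_true(mof$pass)
  expect_false(mof$override_used)
  forced <- low_event_guard(cohort, "hip", min_events = 20, override = TRUE)
  expect_true(forced$pass)
  expect_true(forced$override_used)
  expect_match(forced$message, "override")
})
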