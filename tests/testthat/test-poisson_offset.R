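# A tiny placebo cohort with a chosen count/exposure pattern.  Counts are
# realized as repeated forearm events inside the core period.
toy_poisson_cohort <- function(counts, exposures, pvf) {
  n <- length(counts)
  ids <- sprintf("p%d", seq_len(n))
  subjects <- subj_row(ids, arm = "placebo_crossover", pvf = pvf,
                       core = exposures, ext = 0)
  ev <- NULL
  for (i in seq_len(n)) {
    if (counts[i] > 0) {
      times <- seq(0.1, exposures[i] * 0.9, length.out = counts[i])
      ev <- rbind(ev, event_row(ids[i], "forearm", times))
    }
  }
  fracture_cohort(subjects, ev)
}

test_that("the intercept-only MLE is log(total events / total person-years)", {
  cohort <- toy_poisson_cohort(counts = c(0, 1, 0, 2, 1, 3),
                               exposures = c(2, 3, 2.5, 3, 2, 3),
                               pvf = rep(FALSE, 6))
  fit <- fit_placebo_poisson(cohort, predictors = character(0))
  expect_equal(unname(fit$coefficients), log(7 / 15.5), tolerance = 1e-10)
  expect_equal(fit$total_events, 7)
  expect_equal(fit$total_person_years, 15.5)
})

test_that("the two-parameter MLE matches a brute-force likelihood grid", {
  counts <- c(0, 1, 0, 2, 1, 3)
  exposures <- c(2, 3, 2.5, 3, 2, 3)
  x <- c(0, 0, 0, 1, 1, 1)
  cohort <- toy_poisson_cohort(counts, exposures, pvf = as.logical(x))
  fit <- fit_placebo_poisson(cohort, predictors = "prior_vertebral_fx")

  loglik <- function(b0, b1) {
    mu <- exp(b0 + b1 * x) * exposures
    sum(counts * log(mu) - mu)
  }
  # two-stage grid search, refined to 1e-4
  grid_max <- function(b0s, b1s) {
    best <- c(-Inf, NA, NA)
    for (b0 in b0s) for (b1 in b1s) {
      ll <- loglik(b0, b1)
      if (ll > best[1]) best <- c(ll, b0, b1)
    }
    best[2:3]
  }
  coarse <- grid_max(seq(-5, 0, by = 0.02), seq(-1, 3, by = 0.02))
  fine <- grid_max(seq(coarse[1] - 0.02, coarse[1] + 0.02, by = 1e-4),
                   seq(coarse[2] - 0.02, coarse[2] + 0.02, by = 1e-4))
  expect_equal(unname(fit$coefficients[1]), fine[1], tolerance = 2e-4)
  expect_equal(unname(fit$coefficients[2]), fine[2], tolerance = 2e-4)
  # this toy also has a closed form: arm-wise event/person-time ratios
  expect_equal(unname(fit$coefficients[1]), log(1 / 7.5), tolerance = 1e-8)
  expect_equal(unname(fit$coefficients[2]), log((6 / 8) / (1 / 7.5)),
               tolerance = 1e-8)
})

test_that("score equations vanish at every fitted MLE", {
  for (seed in c(31, 32)) {
    cohort <- small_twoarm_cohort(seed = seed, n_per_arm = 600)
    fit <- fit_placebo_poisson(cohort)
    d <- placebo_core_counts(cohort)
    X <- cbind(1, as.matrix(d[, c("age_years", "bmi", "prior_vertebral_fx",
                                  "prior_nonvertebral_fx", "tscore",
                                  "ever_smoker")]))
    mu <- exp(as.numeric(X %*% fit$coefficients)) * d$exposure
    score <- as.numeric(crossprod(X, d$count - mu))
    expect_lt(max(abs(score)), 1e-6)
  }
})

test_that("shifting age changes only the intercept, not the fitted means", {
  cohort <- small_twoarm_cohort(seed = 33, n_per_arm = 500)
  fit1 <- fit_placebo_poisson(cohort)
  shifted <- cohort
  shifted$subjects$age_years <- shifted$subjects$age_years + 10
  fit2 <- fit_placebo_poisson(shifted)
  d1 <- placebo_core_counts(cohort)
  d2 <- placebo_core_counts(shifted)
  expect_equal(expected_count(fit2, d2, d2$exposure),
               expected_count(fit1, d1, d1$exposure), tolerance = 1e-8)
  # slopes other than age (and the intercept) are unchanged
  keep <- c("bmi", "prior_vertebral_fx", "prior_nonvertebral_fx",
            "tscore", "ever_smoker")
  expect_equal(fit2$coefficients[keep], fit1$coefficients[keep],
               tolerance = 1e-6)
  expect_equal(unname(fit2$coefficients["(Intercept)"]),
               unname(fit1$coefficients["(Intercept)"] -
                        10 * fit1$coefficients["age_years"]),
               tolerance = 1e-6)
})

test_that("reported standard errors match a finite-difference Hessian", {
  counts <- c(0, 1, 0, 2, 1, 3, 0, 2)
  exposures <- c(2, 3, 2.5, 3, 2, 3, 1.5, 2.5)
  x <- c(0, 0, 0, 1, 1, 1, 0, 1)
  cohort <- toy_poisson_cohort(counts, exposures, pvf = as.logical(x))
  fit <- fit_placebo_poisson(cohort, predictors = "prior_vertebral_fx")
  loglik <- function(b) {
    mu <- exp(b[1] + b[2] * x) * exposures
    sum(counts * log(mu) - mu)
  }
  h <- 1e-5
  b <- unname(fit$coefficients)
  H <- matrix(0, 2, 2)
  for (i in 1:2) for (j in 1:2) {
    ei <- ej <- c(0, 0); ei[i] <- h; ej[j] <- h
    H[i, j] <- (loglik(b + ei + ej) - loglik(b + ei - ej) -
                  loglik(b - ei + ej) + loglik(b - ei - ej)) / (4 * h^2)
  }
  se_fd <- sqrt(diag(solve(-H)))
  expect_equal(unname(sqrt(diag(fit$covariance))), se_fd, tolerance = 0.01)
})

test_that("known coefficients are recovered from a simulated placebo arm", {
  cfg <- sim_config(n_per_arm = 5000, seed = 34)
  g <- generate_cohort(cfg)
  fit <- fit_placebo_poisson(g$cohort)
  truth <- cfg$rate_coefficients
  names(truth)[names(truth) == "intercept"] <- "(Intercept)"
  names(truth)[names(truth) == "total_hip_tscore"] <- "tscore"
  se <- sqrt(diag(fit$covariance))
  z <- abs(fit$coefficients - truth[names(fit$coefficients)]) / se
  expect_true(all(z < 3))
  expect_true(fit$converged)
})

test_that("expected_count is the exponentiated linear predictor times exposure", {
  cohort <- small_twoarm_cohort(seed = 35, n_per_arm = 400)
  fit <- fit_placebo_poisson(cohort)
  x <- data.frame(age_years = 72, bmi = 24, prior_vertebral_fx = 1,
                  prior_nonvertebral_fx = 0, tscore = -2.4, ever_smoker = 0)
  manual <- exp(sum(fit$coefficients *
                      c(1, 72, 24, 1, 0, -2.4, 0))) * 3
  expect_equal(expected_count(fit, x, 3), manual, tolerance = 1e-12)
  # all-zero coefficients: expected count equals the exposure
  fit0 <- fit
  fit0$coefficients[] <- 0
  expect_equal(expected_count(fit0, x, 1), 1)
  # intercept log(0.02), zero slopes, 3 person-years -> 0.06
  fit0$coefficients["(Intercept)"] <- log(0.02)
  expect_equal(expected_count(fit0, x, 3), 0.06, tolerance = 1e-12)
})

test_that("rank-deficient designs are refused with the collinear column named", {
  cohort <- toy_poisson_cohort(counts = c(0, 1, 2, 1, 0, 1),
                               exposures = rep(3, 6), pvf = rep(FALSE, 6))
  expect_error(fit_placebo_poisson(cohort,
                                   predictors = "prior_vertebral_fx"),
               "prior_vertebral_fx")
})

test_that("the composite prior-fracture option collapses the two indicators", {
  cohort <- small_twoarm_cohort(seed = 36, n_per_arm = 500)
  fit <- fit_placebo_poisson(cohort, prior_history = "composite")
  expect_true("prior_any_fx" %in% fit$predictor_names)
  expect_length(fit$coefficients, 6L)
})

test_that("poisson fits round-trip through JSON losslessly", {
  cohort <- small_twoarm_cohort(seed = 37, n_per_arm = 400)
  fit <- fit_placebo_poisson(cohort)
  path <- withr::local_tempfile(fileext = ".json")
  write_poisson_fit(fit, path)
  back <- read_poisson_fit(path)
  expect_equal(back$coefficients, fit$coefficients)
  expect_equal(back$covariance, fit$covariance)
  expect_equal(back$total_events, fit$total_events)
})
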