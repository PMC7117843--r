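# End-to-end virtual-twin analysis: guard, placebo model fits, twins,
# observed Kaplan-Meier incidence, and the joint subject-level bootstrap in
# which the whole pipeline (Poisson refit, T-score refit, twin rebuild,
# observed incidence) is recomputed on every resample so that the rate-ratio
# CI is internally consistent.
#
# The bootstrap inner loop works on a precomputed subject-level "analysis
# frame" (design matrices, core-period counts, first-event indicators), so
# a draw costs two glm.fit/lm.fit calls plus vector arithmetic.

.analysis_frame <- function(cohort, event_set, horizon) {
  s <- cohort$subjects
  pc <- placebo_core_counts(cohort, event_set)  # validates placebo arm
  count <- setNames(pc$count, pc$subject_id)
  core_count <- rep(0L, nrow(s))
  core_count[match(pc$subject_id, s$subject_id)] <- pc$count
  # vertebral share of placebo core events, per subject (for refits)
  e <- cohort$events
  e <- e[e$event_type %in% event_set, , drop = FALSE]
  core_fu <- setNames(s$core_followup_years, s$subject_id)
  core_ev <- e[e$time_years < core_fu[e$subject_id], , drop = FALSE]
  vert_count <- integer(nrow(s))
  if (nrow(core_ev)) {
    tv <- table(factor(core_ev$subject_id[
      core_ev$event_type == "clinical_vertebral"], levels = s$subject_id))
    vert_count <- as.integer(tv)
  }
  fe <- first_event_times(cohort, event_set)
  data.frame(
    subject_id = s$subject_id,
    arm = s$arm,
    age_years = s$age_years,
    bmi = s$bmi,
    prior_vertebral_fx = as.numeric(s$prior_vertebral_fx),
    prior_nonvertebral_fx = as.numeric(s$prior_nonvertebral_fx),
    tscore = s$total_hip_tscore_baseline,
    total_hip_tscore_baseline = s$total_hip_tscore_baseline,
    total_hip_tscore_end_core = s$total_hip_tscore_end_core,
    ever_smoker = as.numeric(s$ever_smoker),
    exposure = s$core_followup_years,
    core_count = core_count,
    core_vert_count = vert_count,
    completer = .is_completer(s),
    event_by_horizon = fe$observed & fe$time_years <= horizon,
    stringsAsFactors = FALSE
  )
}

# One pipeline evaluation on index subsets of the analysis frame (a plain
# list of column vectors, so resampled subsetting stays cheap inside the
# bootstrap loop).  Returns c(twin, observed, twin count-scale Lambda).
# Consumes the RNG stream via the twin draws.
.pipeline_eval <- function(frl, i_pl, i_tr, history_update) {
  i_pl <- i_pl[frl$exposure[i_pl] > 0]
  Xp <- cbind(1, frl$age_years[i_pl], frl$bmi[i_pl],
              frl$prior_vertebral_fx[i_pl], frl$prior_nonvertebral_fx[i_pl],
              frl$tscore[i_pl], frl$ever_smoker[i_pl])
  # warnings about numerically-zero fitted rates in extreme resamples are
  # benign; convergence and rank are checked explicitly below
  pfit_raw <- suppressWarnings(
    glm.fit(Xp, frl$core_count[i_pl], family = poisson(),
            offset = log(frl$exposure[i_pl]),
            control = glm.control(epsilon = 1e-12, maxit = 100)))
  if (!isTRUE(pfit_raw$converged)) stop("Poisson refit did not converge")
  beta <- pfit_raw$coefficients
  if (anyNA(beta)) stop("Poisson refit is rank deficient")
  pfit <- structure(list(
    coefficients = setNames(beta, c("(Intercept)", .poisson_predictors)),
    predictor_names = c("(Intercept)", .poisson_predictors),
    converged = TRUE, tscore = "total_hip"
  ), class = "poisson_fit")

  end_th <- frl$total_hip_tscore_end_core[i_pl]
  i_t <- i_pl[!is.na(end_th)]
  if (length(i_t) < 5L) stop("too few end-of-core T-scores in resample")
  Xt <- cbind(1, frl$age_years[i_t], frl$total_hip_tscore_baseline[i_t],
              frl$bmi[i_t])
  tfit_raw <- lm.fit(Xt, frl$total_hip_tscore_end_core[i_t])
  if (anyNA(tfit_raw$coefficients)) stop("T-score refit is rank deficient")
  rsd <- sqrt(sum(tfit_raw$residuals^2) / (length(i_t) - 4L))
  tfit <- structure(list(
    coefficients = setNames(tfit_raw$coefficients,
                            c("(Intercept)", "age_years",
                              "total_hip_tscore_baseline", "bmi")),
    residual_sd = rsd, n = length(i_t)
  ), class = "tscore_fit")

  tot_count <- sum(frl$core_count[i_pl])
  vs <- if (tot_count > 0) sum(frl$core_vert_count[i_pl]) / tot_count else 0.5

  i_c <- i_tr[frl$completer[i_tr]]
  if (length(i_c) == 0L) stop("no long-term completers in resample")
  tr <- list(subject_id = frl$subject_id[i_c],
             age_years = frl$age_years[i_c],
             bmi = frl$bmi[i_c],
             prior_vertebral_fx = frl$prior_vertebral_fx[i_c],
             prior_nonvertebral_fx = frl$prior_nonvertebral_fx[i_c],
             total_hip_tscore_baseline = frl$total_hip_tscore_baseline[i_c],
             ever_smoker = frl$ever_smoker[i_c])
  tw <- .twins(tr, pfit, tfit, vs, history_update = history_update)
  c(twin = mean(tw$ten_year_incidence),
    observed = mean(frl$event_by_horizon[i_c]),
    twin_lambda = mean(tw$core_expected_count + tw$ext_expected_count))
}

#' Run the full virtual-twin efficacy analysis
#'
#' The complete pipeline for one event set: (1) the low-event guard on the
#' placebo arm; (2) placebo-calibrated Poisson rate and end-of-core T-score
#' fits; (3) virtual twins for the long-term 10-year completers and their
#' mean counterfactual 10-year incidence; (4) the observed Kaplan-Meier
#' incidence of the same completers; (5) a joint subject-level bootstrap
#' (resampling within arms, refitting both models, rebuilding twins with
#' fresh T-score and history draws in every resample) giving percentile CIs
#' for the twin incidence, the observed incidence, and the
#' cumulative-hazard-scale rate ratio.
#'
#' Randomness is governed by `seed`: the point-estimate twin draws use
#' `seed`, the bootstrap stream `seed + 1`, so each stage is reproducible in
#' isolation.
#'
#' @param cohort A `fracture_cohort` containing both arms.
#' @param event_set Non-empty subset of [mof_event_types].
#' @param horizon Read-out horizon in years (default 10).
#' @param n_boot Bootstrap resamples; 5000 matches the design this package
#'   emulates (tests use fewer).  `0` skips the bootstrap (point estimates
#'   only).
#' @param seed Master integer seed.
#' @param min_events,override Passed to [low_event_guard()].
#' @param history_update Twin history mechanism, see [build_twins()].
#' @return An object of class `twin_analysis`: `guard`, and unless refused
#'   `pfit`, `tfit`, `km_observed` (a `km_estimate`), `twin` (list
#'   `estimate`, `ci_low`, `ci_high`), `observed` (the same for the KM
#'   read-out), `rr` (a [rate_ratio()]), `boot` (a `bootstrap_result` with
#'   draw columns `twin`, `observed`, `twin_lambda`), `twins` (the twin
#'   table), `n_completers`, `seed`.  When the guard refuses, only `guard`
#'   and `km_observed` are filled and `twin`/`rr` are [refusal()] markers.
#' @export
run_twin_analysis <- function(cohort, event_set = mof_event_types,
                              horizon = 10, n_boot = 5000L, seed = 1L,
                              min_events = 20L, override = FALSE,
                              history_update = c("draw", "expected")) {
  history_update <- match.arg(history_update)
  validate_cohort(cohort)
  seed <- as.integer(seed)
  guard <- low_event_guard(cohort, event_set, min_events, override)
  km_obs <- km_fit(completers(subset_arm(cohort, "denosumab_longterm")),
                   event_set, horizon)
  out <- list(guard = guard, km_observed = km_obs, seed = seed,
              event_set = event_set, horizon = horizon)
  if (!guard$pass) {
    out$twin <- refusal(guard$message)
    out$rr <- refusal(guard$message)
    class(out) <- "twin_analysis"
    return(out)
  }

  fr <- .analysis_frame(cohort, event_set, horizon)
  frl <- as.list(fr)
  pfit <- fit_placebo_poisson(cohort, event_set)
  tfit <- fit_tscore_model(cohort)
  set.seed(seed)
  i_pl <- which(fr$arm == "placebo_crossover")
  i_tr <- which(fr$arm == "denosumab_longterm")
  point <- .pipeline_eval(frl, i_pl, i_tr, history_update)
  twins <- build_twins(cohort, pfit, tfit, seed = seed,
                       history_update = history_update)

  boot <- NULL
  twin_ci <- obs_ci <- c(NA_real_, NA_real_)
  if (n_boot >= 1L) {
    set.seed(seed + 1L)
    draws <- matrix(NA_real_, n_boot, 3L,
                    dimnames = list(NULL, names(point)))
    for (b in seq_len(n_boot)) {
      bi_pl <- i_pl[sample.int(length(i_pl), replace = TRUE)]
      bi_tr <- i_tr[sample.int(length(i_tr), replace = TRUE)]
      draws[b, ] <- tryCatch(
        .pipeline_eval(frl, bi_pl, bi_tr, history_update),
        error = function(e) rep(NA_real_, 3L))
    }
    n_failed <- sum(apply(draws, 1L, anyNA))
    if (n_failed > 0.01 * n_boot) {
      stop(sprintf("bootstrap: %d of %d draws failed (> 1%%)",
                   n_failed, n_boot), call. = FALSE)
    }
    boot <- new_bootstrap_result(point, draws, n_boot, seed + 1L, n_failed)
    twin_ci <- c(boot$ci_low[["twin"]], boot$ci_high[["twin"]])
    obs_ci <- c(boot$ci_low[["observed"]], boot$ci_high[["observed"]])
  }
  out$pfit <- pfit
  out$tfit <- tfit
  out$twins <- twins
  out$n_completers <- sum(fr$completer & fr$arm == "denosumab_longterm")
  out$twin <- list(estimate = unname(point["twin"]),
                   ci_low = twin_ci[1L], ci_high = twin_ci[2L])
  out$observed <- list(estimate = unname(point["observed"]),
                       ci_low = obs_ci[1L], ci_high = obs_ci[2L])
  out$boot <- boot
  out$rr <- rate_ratio(km_obs, out$twin$estimate, boot)
  class(out) <- "twin_analysis"
  out
}

#' @export
print.twin_analysis <- function(x, ...) {
  cat("<twin_analysis> event set: ", paste(x$event_set, collapse = "/"),
      ", horizon ", x$horizon, " y\n", sep = "")
  print(x$guard)
  ro <- x$km_observed$horizon_readout
  cat(sprintf("  observed KM incidence: %.4f (95%% CI %.4f to %.4f)\n",
              ro$incidence, ro$ci_low, ro$ci_high))
  if (inherits(x$twin, "ft_refusal")) {
    cat("  twin estimate: refused\n")
  } else {
    cat(sprintf("  twin incidence:        %.4f (95%% CI %.4f to %.4f)\n",
                x$twin$estimate, x$twin$ci_low, x$twin$ci_high))
    print(x$rr)
  }
  invisible(x)
}
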