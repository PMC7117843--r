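# Virtual-twin engine: for each long-term treated 10-year completer, build
# a counterfactual placebo twin with identical baseline characteristics and
# compose its expected 10-year fracture incidence from the placebo-
# calibrated Poisson rate model.
#
# Composition rule: expected core-period (3 y) and extension-period (7 y)
# counts are summed as a cumulative hazard and converted to a probability by
# 1 - exp(-Lambda), which is self-consistent with the Poisson model and
# bounded in [0, 1].  A count-scale alternative (Lambda itself, uncapped) is
# available via `composition = "count"` for sensitivity analysis.

#' Linear model for the end-of-core total-hip T-score
#'
#' Ordinary least squares of the total-hip T-score at the end of the core
#' period on baseline age, baseline total-hip T-score and BMI, fitted on
#' placebo-crossover subjects with a non-missing end-of-core measurement
#' (their core-period change represents untreated behaviour).  The residual
#' SD (denominator `n - 4`) is the noise scale used when simulating twin
#' T-scores.
#'
#' @param cohort A `fracture_cohort`.
#' @param min_n Minimum number of usable subjects (default 5).
#' @return An object of class `tscore_fit`: `coefficients` (intercept, age,
#'   baseline T-score, BMI), `residual_sd`, `n`.
#' @export
fit_tscore_model <- function(cohort, min_n = 5L) {
  s <- cohort$subjects
  s <- s[s$arm == "placebo_crossover" &
           !is.na(s$total_hip_tscore_end_core), , drop = FALSE]
  if (nrow(s) < min_n) {
    stop("need at least ", min_n, " placebo subjects with an end-of-core ",
         "T-score; got ", nrow(s), call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1, age_years = s$age_years,
             total_hip_tscore_baseline = s$total_hip_tscore_baseline,
             bmi = s$bmi)
  if (qr(X)$rank < 4L) {
    stop("T-score design matrix is collinear", call. = FALSE)
  }
  fit <- lm.fit(X, s$total_hip_tscore_end_core)
  rss <- sum(fit$residuals^2)
  residual_sd <- sqrt(rss / (nrow(s) - 4L))
  if (!is.finite(residual_sd) || residual_sd <= 1e-8) {
    stop("degenerate T-score fit: residual SD is (numerically) zero; ",
         "a perfect fit cannot supply the simulation noise scale",
         call. = FALSE)
  }
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(X)),
    residual_sd = residual_sd,
    n = nrow(s)
  ), class = "tscore_fit")
}

#' @export
print.tscore_fit <- function(x, ...) {
  cat("<tscore_fit> n = ", x$n, ", residual SD = ",
      sprintf("%.4f", x$residual_sd), "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

.predict_tscore <- function(tfit, subj) {
  b <- tfit$coefficients
  b[[1L]] + b[[2L]] * subj$age_years +
    b[[3L]] * subj$total_hip_tscore_baseline + b[[4L]] * subj$bmi
}

#' Empirical vertebral share of placebo core-period fractures
#'
#' Proportion of placebo-arm core-period events of `event_set` that are
#' clinical vertebral fractures; used to assign a twin's predicted in-core
#' fracture to the vertebral vs. nonvertebral history slot.  Returns
#' `default` when the placebo arm has no qualifying events.
#'
#' @inheritParams placebo_core_counts
#' @param default Value returned with zero events (default 0.5).
#' @return A probability in \[0, 1\].
#' @export
vertebral_split <- function(cohort, event_set = mof_event_types,
                            default = 0.5) {
  event_set <- .check_event_set(event_set)
  s <- cohort$subjects
  pl <- s[s$arm == "placebo_crossover", , drop = FALSE]
  e <- cohort$events
  e <- e[e$subject_id %in% pl$subject_id & e$event_type %in% event_set, ,
         drop = FALSE]
  core_fu <- setNames(pl$core_followup_years, pl$subject_id)
  e <- e[e$time_years < core_fu[e$subject_id], , drop = FALSE]
  if (nrow(e) == 0L) return(default)
  mean(e$event_type == "clinical_vertebral")
}

# Core twin computation on a subjects data frame (already restricted to
# long-term completers).  Consumes the ambient RNG stream in a fixed order:
# (1) history uniforms, (2) vertebral/nonvertebral slot uniforms,
# (3) standard-normal T-score draws.
.twins <- function(subj, pfit, tfit, vert_split,
                   history_update = c("draw", "expected"),
                   composition = c("hazard", "count"),
                   core_years = 3, ext_years = 7) {
  history_update <- match.arg(history_update)
  composition <- match.arg(composition)
  n <- length(subj$subject_id)
  base <- data.frame(
    age_years = subj$age_years,
    bmi = subj$bmi,
    prior_vertebral_fx = as.numeric(subj$prior_vertebral_fx),
    prior_nonvertebral_fx = as.numeric(subj$prior_nonvertebral_fx),
    tscore = subj$total_hip_tscore_baseline,
    ever_smoker = as.numeric(subj$ever_smoker)
  )
  base$prior_any_fx <- as.numeric(base$prior_vertebral_fx > 0 |
                                    base$prior_nonvertebral_fx > 0)
  mu_core <- expected_count(pfit, base, core_years)
  p_ev <- 1 - exp(-mu_core)

  u_hist <- runif(n)
  u_slot <- runif(n)
  z <- rnorm(n)
  ts_ext <- .predict_tscore(tfit, subj) + z * tfit$residual_sd

  ext_frame <- function(new_vert, new_nonvert) {
    d <- base
    d$age_years <- base$age_years + core_years
    d$tscore <- ts_ext
    d$prior_vertebral_fx <- pmax(base$prior_vertebral_fx,
                                 as.numeric(new_vert))
    d$prior_nonvertebral_fx <- pmax(base$prior_nonvertebral_fx,
                                    as.numeric(new_nonvert))
    d$prior_any_fx <- as.numeric(d$prior_vertebral_fx > 0 |
                                   d$prior_nonvertebral_fx > 0)
    d
  }

  if (history_update == "draw") {
    drawn <- u_hist < p_ev
    new_vert <- drawn & (u_slot < vert_split)
    new_nonvert <- drawn & !new_vert
    mu_ext <- expected_count(pfit, ext_frame(new_vert, new_nonvert),
                             ext_years)
    pred_vert <- as.numeric(new_vert)
    pred_nonvert <- as.numeric(new_nonvert)
  } else {
    # expectation over the history Bernoulli instead of a draw
    mu_none <- expected_count(pfit, ext_frame(FALSE, FALSE), ext_years)
    mu_vert <- expected_count(pfit, ext_frame(TRUE, FALSE), ext_years)
    mu_nv <- expected_count(pfit, ext_frame(FALSE, TRUE), ext_years)
    mu_ext <- (1 - p_ev) * mu_none +
      p_ev * (vert_split * mu_vert + (1 - vert_split) * mu_nv)
    pred_vert <- p_ev * vert_split
    pred_nonvert <- p_ev * (1 - vert_split)
  }
  lambda <- mu_core + mu_ext
  data.frame(
    subject_id = subj$subject_id,
    core_expected_count = mu_core,
    core_predicted_fx_vertebral = pred_vert,
    core_predicted_fx_nonvertebral = pred_nonvert,
    ext_tscore_simulated = ts_ext,
    ext_expected_count = mu_ext,
    ten_year_incidence = if (composition == "hazard") 1 - exp(-lambda)
                         else lambda,
    stringsAsFactors = FALSE
  )
}

.twin_subjects <- function(cohort, subject_ids = NULL) {
  s <- cohort$subjects
  ok <- s$arm == "denosumab_longterm" & .is_completer(s)
  if (is.null(subject_ids)) {
    subj <- s[ok, , drop = FALSE]
    if (nrow(subj) == 0L) {
      stop("no long-term 10-year completers in the cohort", call. = FALSE)
    }
  } else {
    idx <- match(subject_ids, s$subject_id)
    if (anyNA(idx)) {
      stop("unknown subject_id: ", subject_ids[which(is.na(idx))[1L]],
           call. = FALSE)
    }
    bad <- which(!ok[idx])
    if (length(bad)) {
      stop("subject '", subject_ids[bad[1L]], "' is not a long-term ",
           "10-year completer; the virtual-twin analysis set is completers ",
           "only", call. = FALSE)
    }
    subj <- s[idx, , drop = FALSE]
  }
  subj
}

#' Build virtual placebo twins for the long-term completers
#'
#' For every long-term treated 10-year completer (or the requested subset),
#' constructs the counterfactual twin record: expected core-period (3-year)
#' fracture count at the subject's own baseline covariates under the placebo
#' rate model; a stochastic in-core fracture-history update (Bernoulli with
#' probability `1 - exp(-mu_core)`, assigned to the vertebral slot with
#' probability `vert_split`); a simulated untreated end-of-core total-hip
#' T-score (normal around the [fit_tscore_model()] mean with its residual
#' SD); the expected extension-period (7-year) count at the updated
#' covariates (age + 3, same BMI and smoking status, updated history,
#' simulated T-score); and the composed 10-year incidence
#' `1 - exp(-(mu_core + mu_ext))`.
#'
#' @param cohort A `fracture_cohort`.
#' @param pfit A converged [fit_placebo_poisson()] fit using the total-hip
#'   T-score predictor.
#' @param tfit A [fit_tscore_model()] fit.
#' @param seed Optional integer; when supplied, `set.seed(seed)` is called
#'   first so the twin draws are reproducible in isolation.  When `NULL`
#'   the ambient RNG stream is used (as inside the bootstrap).
#' @param subject_ids Optional ids; each must be a long-term completer
#'   (anything else is an error).
#' @param history_update `"draw"` (default; stochastic Bernoulli history
#'   update) or `"expected"` (expectation-weighted variant).
#' @param vert_split Probability that a predicted in-core fracture updates
#'   the vertebral history slot; defaults to the placebo arm's empirical
#'   core-period vertebral share ([vertebral_split()]).
#' @param composition `"hazard"` (default, `1 - exp(-Lambda)`) or `"count"`
#'   (uncapped expected count, sensitivity only).
#' @return Data frame of twin records, one row per twin, with attribute
#'   `"vert_split"`.
#' @export
build_twins <- function(cohort, pfit, tfit, seed = NULL, subject_ids = NULL,
                        history_update = c("draw", "expected"),
                        vert_split = NULL,
                        composition = c("hazard", "count")) {
  stopifnot(inherits(pfit, "poisson_fit"), inherits(tfit, "tscore_fit"))
  if (!pfit$converged) {
    stop("poisson_fit did not converge; refusing to build twins",
         call. = FALSE)
  }
  if (pfit$tscore != "total_hip") {
    stop("twin construction requires a rate model fitted on the total-hip ",
         "T-score (the extension update simulates the total-hip T-score)",
         call. = FALSE)
  }
  subj <- .twin_subjects(cohort, subject_ids)
  if (is.null(vert_split)) vert_split <- vertebral_split(cohort, pfit$event_set)
  if (!is.null(seed)) set.seed(as.integer(seed))
  out <- .twins(subj, pfit, tfit, vert_split,
                history_update = match.arg(history_update),
                composition = match.arg(composition))
  attr(out, "vert_split") <- vert_split
  out
}

#' Build the virtual twin of a single subject
#'
#' Convenience wrapper around [build_twins()] for one long-term completer.
#'
#' @inheritParams build_twins
#' @param subject_id Id of a long-term 10-year completer.
#' @return A one-row twin-record data frame.
#' @export
make_virtual_twin <- function(cohort, subject_id, pfit, tfit, seed = NULL,
                              ...) {
  build_twins(cohort, pfit, tfit, seed = seed, subject_ids = subject_id, ...)
}

#' Virtual-twin estimate of the 10-year counterfactual incidence
#'
#' Mean composed 10-year incidence over the virtual twins (one twin per
#' long-term 10-year completer).
#'
#' @inheritParams build_twins
#' @return A probability in \[0, 1\], with the twin table attached as
#'   attribute `"twins"`.
#' @export
twin_cohort_incidence <- function(cohort, pfit, tfit, seed = NULL, ...) {
  tw <- build_twins(cohort, pfit, tfit, seed = seed, ...)
  structure(mean(tw$ten_year_incidence), twins = tw)
}

#' Minimum-event guard for the twin pipeline
#'
#' The counterfactual rate model is unreliable when the placebo arm
#' contributed too few core-period events of the requested type set (as with
#' hip fractures alone); the twin pipeline then refuses to run unless an
#' explicit override is given.  Refusal is a typed outcome, not an error.
#'
#' @inheritParams placebo_core_counts
#' @param min_events Minimum placebo core-period event count (default 20).
#' @param override Run anyway?  The override is recorded so reports can
#'   flag it.
#' @return An object of class `event_guard`: list with `pass`, `n_events`,
#'   `min_events`, `override_used`, `event_set`, `message`.
#' @export
low_event_guard <- function(cohort, event_set = mof_event_types,
                            min_events = 20L, override = FALSE) {
  d <- placebo_core_counts(cohort, event_set)
  n_ev <- sum(d$count)
  enough <- n_ev >= min_events
  msg <- if (enough) {
    sprintf("%d placebo core-period events (>= %d): twin analysis allowed",
            n_ev, min_events)
  } else if (override) {
    sprintf(paste0("only %d placebo core-period events (< %d); twin ",
                   "estimates are unreliable at this event count -- ",
                   "override requested, proceeding anyway"),
            n_ev, min_events)
  } else {
    sprintf(paste0("only %d placebo core-period events (< %d): the low ",
                   "number of events would lead to unreliable twin ",
                   "estimates; analysis refused (use override to force)"),
            n_ev, min_events)
  }
  structure(list(pass = enough || isTRUE(override),
                 n_events = n_ev, min_events = as.integer(min_events),
                 override_used = isTRUE(override) && !enough,
                 event_set = event_set, message = msg),
            class = "event_guard")
}

#' @export
print.event_guard <- function(x, ...) {
  cat("<event_guard> ", if (x$pass) "PASS" else "REFUSE", ": ", x$message,
      "\n", sep = "")
  invisible(x)
}
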