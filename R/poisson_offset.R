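# Poisson regression of core-period fracture counts with a log person-time
# offset, calibrated on the placebo (crossover) arm.  This is the rate model
# that powers the virtual-twin counterfactual.

.poisson_predictors <- c("age_years", "bmi", "prior_vertebral_fx",
                         "prior_nonvertebral_fx", "tscore", "ever_smoker")

#' Core-period fracture counts and predictors for the placebo arm
#'
#' Builds the modeling frame of [fit_placebo_poisson()]: one row per
#' placebo-crossover subject with positive core follow-up, the number of
#' fractures of `event_set` during that follow-up (recurrent events counted,
#' not just the first), the person-time exposure, and the baseline
#' predictors.  Exposed so tests and diagnostics can recompute the
#' likelihood independently.
#'
#' @param cohort A `fracture_cohort`.
#' @param event_set Non-empty subset of [mof_event_types].
#' @param tscore Which baseline T-score enters as the `tscore` predictor:
#'   `"total_hip"` (default; the twin procedure later updates the total-hip
#'   T-score) or `"femoral_neck"`.
#' @return Data frame with columns `subject_id`, `count`, `exposure`, and
#'   the predictors `age_years`, `bmi`, `prior_vertebral_fx`,
#'   `prior_nonvertebral_fx`, `tscore`, `ever_smoker` (indicators as 0/1).
#' @export
placebo_core_counts <- function(cohort, event_set = mof_event_types,
                                tscore = c("total_hip", "femoral_neck")) {
  tscore <- match.arg(tscore)
  event_set <- .check_event_set(event_set)
  s <- cohort$subjects
  s <- s[s$arm == "placebo_crossover" & s$core_followup_years > 0, ,
         drop = FALSE]
  if (nrow(s) == 0L) {
    stop("no placebo_crossover subjects with positive core follow-up",
         call. = FALSE)
  }
  e <- cohort$events
  e <- e[e$event_type %in% event_set & e$subject_id %in% s$subject_id, ,
         drop = FALSE]
  core_fu <- setNames(s$core_followup_years, s$subject_id)
  e <- e[e$time_years < core_fu[e$subject_id], , drop = FALSE]
  cnt <- table(factor(e$subject_id, levels = s$subject_id))
  data.frame(
    subject_id = s$subject_id,
    count = as.integer(cnt),
    exposure = s$core_followup_years,
    age_years = s$age_years,
    bmi = s$bmi,
    prior_vertebral_fx = as.numeric(s$prior_vertebral_fx),
    prior_nonvertebral_fx = as.numeric(s$prior_nonvertebral_fx),
    tscore = if (tscore == "total_hip") s$total_hip_tscore_baseline
             else s$femoral_neck_tscore,
    ever_smoker = as.numeric(s$ever_smoker),
    stringsAsFactors = FALSE
  )
}

#' Fit the placebo-calibrated Poisson fracture-rate model
#'
#' Maximum-likelihood Poisson regression of core-period fracture counts on
#' baseline predictors with `log(person-time)` offset:
#' `log E[count_i] = beta . x_i + log(t_i)`.  Fitting is iteratively
#' reweighted least squares to convergence tolerance 1e-12 (at most 100
#' iterations); the covariance is the inverse observed information.  A
#' quasi-Poisson dispersion (Pearson chi-square / df) is computed and
#' reported as a diagnostic only; the fit itself is plain Poisson.
#'
#' @inheritParams placebo_core_counts
#' @param predictors Character vector of predictors to include (default all
#'   six); `character(0)` fits the intercept-only model whose MLE is the
#'   closed form `log(total events / total person-years)`.
#' @param prior_history `"separate"` keeps prior vertebral and nonvertebral
#'   fracture history as two indicators (default); `"composite"` replaces
#'   them by their union.
#' @return An object of class `poisson_fit`: `coefficients`, `covariance`,
#'   `predictor_names`, `n_subjects`, `total_events`, `total_person_years`,
#'   `converged`, `dispersion`, `tscore`, `event_set`.
#' @export
fit_placebo_poisson <- function(cohort, event_set = mof_event_types,
                                tscore = c("total_hip", "femoral_neck"),
                                predictors = NULL,
                                prior_history = c("separate", "composite")) {
  tscore <- match.arg(tscore)
  prior_history <- match.arg(prior_history)
  d <- placebo_core_counts(cohort, event_set, tscore)
  if (prior_history == "composite") {
    d$prior_any_fx <- as.numeric(d$prior_vertebral_fx > 0 |
                                   d$prior_nonvertebral_fx > 0)
    d$prior_vertebral_fx <- d$prior_nonvertebral_fx <- NULL
    all_preds <- c("age_years", "bmi", "prior_any_fx", "tscore",
                   "ever_smoker")
  } else {
    all_preds <- .poisson_predictors
  }
  if (is.null(predictors)) predictors <- all_preds
  if (length(predictors) && !all(predictors %in% all_preds)) {
    stop("unknown predictor(s): ",
         paste(setdiff(predictors, all_preds), collapse = ", "),
         call. = FALSE)
  }
  X <- cbind("(Intercept)" = 1,
             as.matrix(d[, predictors, drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[seq.int(qx$rank + 1L, ncol(X))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- glm.fit(X, d$count, family = poisson(), offset = log(d$exposure),
                 control = glm.control(epsilon = 1e-12, maxit = 100))
  # observed-information covariance from the final IRLS weights
  XtWX <- crossprod(X * sqrt(fit$weights))
  covb <- chol2inv(chol(XtWX))
  dimnames(covb) <- list(colnames(X), colnames(X))
  mu <- fit$fitted.values
  p <- ncol(X)
  dispersion <- if (nrow(d) > p) {
    sum((d$count - mu)^2 / mu) / (nrow(d) - p)
  } else NA_real_
  structure(list(
    coefficients = setNames(fit$coefficients, colnames(X)),
    covariance = covb,
    predictor_names = colnames(X),
    n_subjects = nrow(d),
    total_events = sum(d$count),
    total_person_years = sum(d$exposure),
    converged = isTRUE(fit$converged),
    dispersion = dispersion,
    tscore = tscore,
    prior_history = prior_history,
    event_set = event_set
  ), class = "poisson_fit")
}

#' @export
print.poisson_fit <- function(x, ...) {
  cat("<poisson_fit> ", x$n_subjects, " placebo subjects, ",
      x$total_events, " events / ", format(x$total_person_years),
      " person-years", if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  se <- sqrt(diag(x$covariance))
  print(cbind(estimate = x$coefficients, std_error = se))
  cat(sprintf("  quasi-Poisson dispersion (diagnostic): %.3f\n",
              x$dispersion))
  invisible(x)
}

#' Expected fracture count under the fitted rate model
#'
#' Evaluates `exp(beta . x) * person_years` for new predictor values.
#'
#' @param fit A converged `poisson_fit`.
#' @param newdata Data frame containing the fit's predictor columns
#'   (`age_years`, `bmi`, `prior_vertebral_fx`, `prior_nonvertebral_fx`,
#'   `tscore`, `ever_smoker`; indicators as 0/1 or logical).
#' @param person_years Non-negative exposure, scalar or one per row.
#' @return Numeric vector of expected counts (>= 0), one per row.
#' @export
expected_count <- function(fit, newdata, person_years) {
  stopifnot(inherits(fit, "poisson_fit"))
  if (!fit$converged) {
    stop("refusing to predict from a non-converged poisson_fit",
         call. = FALSE)
  }
  if (any(person_years < 0)) stop("person_years must be >= 0", call. = FALSE)
  preds <- setdiff(fit$predictor_names, "(Intercept)")
  miss <- setdiff(preds, names(newdata))
  if (length(miss)) {
    stop("newdata is missing predictor(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  nd <- as.data.frame(newdata)
  X <- matrix(1, nrow(nd), length(preds) + 1L)
  for (j in seq_along(preds)) X[, j + 1L] <- as.numeric(nd[[preds[j]]])
  as.numeric(exp(X %*% fit$coefficients)) * person_years
}

#' Serialize / restore a Poisson rate fit as JSON
#'
#' Lossless round trip of a `poisson_fit` (full double precision).
#'
#' @param fit A `poisson_fit`.
#' @param path File path.
#' @return `write_poisson_fit`: `path` invisibly; `read_poisson_fit`: the
#'   restored `poisson_fit`.
#' @export
write_poisson_fit <- function(fit, path) {
  stopifnot(inherits(fit, "poisson_fit"))
  out <- unclass(fit)
  out$covariance <- as.data.frame(out$covariance)
  out$schema_version <- 1L
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_poisson_fit
#' @export
read_poisson_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  x$coefficients <- unlist(x$coefficients)
  x$covariance <- as.matrix(x$covariance)
  dimnames(x$covariance) <- list(x$predictor_names, x$predictor_names)
  names(x$coefficients) <- x$predictor_names
  structure(x, class = "poisson_fit")
}
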