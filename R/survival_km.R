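# Observed cumulative fracture incidence: product-limit estimation via
# survival::survfit, with Greenwood variance and a horizon read-out.

#' Kaplan-Meier cumulative fracture incidence with a horizon read-out
#'
#' Fits the product-limit estimator to per-subject time-to-first-event data
#' derived from the cohort (see [first_event_times()]): the first fracture
#' whose type lies in `event_set` is the event, total follow-up the
#' censoring time.  Events precede censorings at tied times (the standard
#' convention).  The 95% CI is formed on the complementary log-log scale by
#' default, keeping it inside \[0, 1\]; `conf_type = "linear"` gives the
#' plain Greenwood interval.  The horizon read-out takes the step function's
#' value at the largest event time at or before `horizon`
#' (right-continuous, no interpolation).
#'
#' With zero observed events the incidence is 0 and the CI upper bound is
#' the exact binomial bound `1 - 0.025^(1/n)` (the "rule of three" made
#' exact), with `n` the number of subjects.
#'
#' @param cohort A `fracture_cohort`; the caller chooses the analysis set
#'   (e.g. `completers(subset_arm(cohort, "denosumab_longterm"))`).
#' @param event_set Non-empty subset of [mof_event_types].
#' @param horizon Read-out horizon in years (> 0), default 10.
#' @param conf_type `"cloglog"` (default) or `"linear"`.
#' @return An object of class `km_estimate`: list with `event_times`,
#'   `survival`, `cumulative_incidence`, `greenwood_variance`, `n_at_risk`,
#'   `n_events`, and `horizon_readout` (list `horizon`, `incidence`,
#'   `ci_low`, `ci_high`), plus the underlying `survfit` object.
#' @export
km_fit <- function(cohort, event_set = mof_event_types, horizon = 10,
                   conf_type = c("cloglog", "linear")) {
  conf_type <- match.arg(conf_type)
  stopifnot(horizon > 0)
  fe <- first_event_times(cohort, event_set)
  if (nrow(fe) == 0L) stop("no subjects at risk at time 0", call. = FALSE)
  sf <- survival::survfit(
    survival::Surv(fe$time_years, fe$observed) ~ 1,
    conf.type = if (conf_type == "cloglog") "log-log" else "plain",
    conf.int = 0.95
  )
  keep <- sf$n.event > 0
  surv <- sf$surv[keep]
  est <- list(
    event_times = sf$time[keep],
    survival = surv,
    cumulative_incidence = 1 - surv,
    greenwood_variance = (surv * sf$std.err[keep])^2,
    n_at_risk = sf$n.risk[keep],
    n_events = sf$n.event[keep],
    n_subjects = nrow(fe),
    conf_type = conf_type,
    event_set = event_set,
    survfit = sf
  )
  idx <- which(est$event_times <= horizon + 1e-12)
  if (length(idx) == 0L) {
    n <- nrow(fe)
    ro <- list(horizon = horizon, incidence = 0, ci_low = 0,
               ci_high = 1 - 0.025^(1 / n))
  } else {
    i <- max(idx)
    at <- which(keep)[i]
    lo_s <- sf$lower[at]
    hi_s <- sf$upper[at]
    ro <- list(horizon = horizon,
               incidence = est$cumulative_incidence[i],
               ci_low = if (is.na(hi_s)) NA_real_ else 1 - hi_s,
               ci_high = if (is.na(lo_s)) NA_real_ else 1 - lo_s)
  }
  est$horizon_readout <- ro
  class(est) <- "km_estimate"
  est
}

#' @export
print.km_estimate <- function(x, ...) {
  ro <- x$horizon_readout
  cat("<km_estimate> ", x$n_subjects, " subjects, ",
      sum(x$n_events), " first events (",
      paste(x$event_set, collapse = "/"), ")\n", sep = "")
  cat(sprintf("  incidence at %g y: %.4f (95%% CI %.4f to %.4f, %s)\n",
              ro$horizon, ro$incidence, ro$ci_low, ro$ci_high, x$conf_type))
  invisible(x)
}

#' Compare an observed Kaplan-Meier incidence with a reference estimate
#'
#' Builds one structured comparison row (observed vs. an external reference
#' such as a FRAX mean probability or a virtual-twin estimate) for the
#' report module.
#'
#' @param km A `km_estimate`.
#' @param reference_incidence Reference probability in \[0, 1\].
#' @param reference_ci Optional length-2 numeric `(low, high)`, or `NULL`.
#' @param reference_label Label for the reference column.
#' @return A one-row data frame with columns `observed`, `observed_ci_low`,
#'   `observed_ci_high`, `reference`, `reference_ci_low`,
#'   `reference_ci_high`, `difference` (observed minus reference),
#'   `reference_label`.
#' @export
km_compare_report <- function(km, reference_incidence, reference_ci = NULL,
                              reference_label = "reference") {
  stopifnot(inherits(km, "km_estimate"),
            reference_incidence >= 0, reference_incidence <= 1)
  ro <- km$horizon_readout
  data.frame(
    observed = ro$incidence,
    observed_ci_low = ro$ci_low,
    observed_ci_high = ro$ci_high,
    reference = reference_incidence,
    reference_ci_low = if (is.null(reference_ci)) NA_real_ else reference_ci[1],
    reference_ci_high = if (is.null(reference_ci)) NA_real_ else reference_ci[2],
    difference = ro$incidence - reference_incidence,
    reference_label = reference_label,
    stringsAsFactors = FALSE
  )
}
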