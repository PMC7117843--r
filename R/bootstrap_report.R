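# Subject-level percentile bootstrap, observed-vs-twin rate ratio on the
# cumulative-hazard scale, and the final comparison report.

.percentile_ci <- function(draws, level = 0.95) {
  a <- (1 - level) / 2
  as.numeric(quantile(draws, c(a, 1 - a), na.rm = TRUE, names = FALSE))
}

new_bootstrap_result <- function(point, draws, n_boot, seed, n_failed = 0L,
                                 level = 0.95) {
  draws <- as.matrix(draws)
  if (is.null(colnames(draws)) && !is.null(names(point))) {
    colnames(draws) <- names(point)
  }
  ci <- apply(draws, 2L, .percentile_ci, level = level)
  structure(list(
    point_estimate = point,
    ci_low = setNames(ci[1L, ], colnames(draws)),
    ci_high = setNames(ci[2L, ], colnames(draws)),
    n_boot = as.integer(n_boot),
    n_failed = as.integer(n_failed),
    level = level,
    seed = seed,
    draws = draws
  ), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", x$n_boot, " resamples (seed ", x$seed, ")",
      if (x$n_failed) sprintf(", %d failed", x$n_failed), "\n", sep = "")
  tab <- cbind(estimate = x$point_estimate, ci_low = x$ci_low,
               ci_high = x$ci_high)
  print(tab)
  invisible(x)
}

# Resampling scheme (documented so independent implementations can
# reproduce it): set.seed(seed); then for each of the n_boot draws, and for
# each arm in the order placebo_crossover, denosumab_longterm (when
# stratified; otherwise the whole cohort at once), draw sample.int(n_arm,
# replace = TRUE).  The statistic is evaluated immediately after, on the
# resampled cohort, consuming the same RNG stream (so stochastic statistics
# such as twin draws are reproducible too).
.resample_indices <- function(arm, stratify) {
  if (stratify) {
    idx <- integer(length(arm))
    for (a in cohort_arms) {
      w <- which(arm == a)
      if (length(w)) idx[w] <- w[sample.int(length(w), replace = TRUE)]
    }
    idx[idx > 0L]
  } else {
    sample.int(length(arm), replace = TRUE)
  }
}

.resample_cohort <- function(cohort, idx, ev_split) {
  s <- cohort$subjects[idx, , drop = FALSE]
  new_id <- sprintf("B%06d", seq_along(idx))
  ev_rows <- ev_split[cohort$subjects$subject_id[idx]]
  n_ev <- vapply(ev_rows, NROW, integer(1L))
  e <- cohort$events[unlist(ev_rows, use.names = FALSE), , drop = FALSE]
  e$subject_id <- rep.int(new_id, n_ev)
  s$subject_id <- new_id
  rownames(s) <- rownames(e) <- NULL
  new_fracture_cohort(s, e, cohort$provenance)
}

#' Subject-level percentile bootstrap of an arbitrary cohort statistic
#'
#' Resamples subjects with replacement -- within each arm when
#' `stratify_by_arm = TRUE` (the default), so per-arm sample sizes are
#' preserved exactly in every draw -- rebuilds the cohort (subjects carry
#' their events), and recomputes `statistic` on each resample.  The CI is
#' the empirical 2.5th/97.5th percentile of the draws.  Deterministic given
#' `seed`.  A draw on which the statistic fails (e.g. a rank-deficient
#' refit) is recorded as `NA`; more than 1% failed draws is an error.
#'
#' @param cohort A `fracture_cohort`.
#' @param statistic Function of one argument (the resampled
#'   `fracture_cohort`) returning a numeric scalar or named vector.  It may
#'   consume the RNG stream (e.g. rebuild twins); that randomness is then
#'   absorbed into the bootstrap CI.
#' @param n_boot Number of resamples (>= 1); 5000 reproduces the design this
#'   pipeline emulates, smaller values are fine for testing.
#' @param seed Integer seed for the whole resampling process.
#' @param stratify_by_arm Resample within arms (default `TRUE`).
#' @param level Confidence level (default 0.95).
#' @return A `bootstrap_result`: `point_estimate` (statistic on the original
#'   cohort), `ci_low`, `ci_high`, `n_boot`, `n_failed`, `seed`, and the
#'   retained `draws` matrix (one row per resample).
#' @export
bootstrap_statistic <- function(cohort, statistic, n_boot, seed,
                                stratify_by_arm = TRUE, level = 0.95) {
  stopifnot(n_boot >= 1)
  validate_cohort(cohort)
  arm <- cohort$subjects$arm
  ev_split <- split(seq_len(nrow(cohort$events)), cohort$events$subject_id)
  ev_split <- lapply(ev_split, as.integer)
  missing_ids <- setdiff(cohort$subjects$subject_id, names(ev_split))
  ev_split[missing_ids] <- list(integer(0))

  set.seed(as.integer(seed))
  point <- statistic(cohort)
  k <- length(point)
  draws <- matrix(NA_real_, n_boot, k)
  colnames(draws) <- names(point)
  for (b in seq_len(n_boot)) {
    idx <- .resample_indices(arm, stratify_by_arm)
    res <- tryCatch(statistic(.resample_cohort(cohort, idx, ev_split)),
                    error = function(e) rep(NA_real_, k))
    draws[b, ] <- as.numeric(res)
  }
  n_failed <- sum(apply(draws, 1L, anyNA))
  if (n_failed > 0.01 * n_boot) {
    stop(sprintf("bootstrap: %d of %d draws failed (> 1%%)",
                 n_failed, n_boot), call. = FALSE)
  }
  new_bootstrap_result(point, draws, n_boot, seed, n_failed, level)
}

#' Refusal marker
#'
#' Typed outcome used when an analysis is declined (e.g. zero twin
#' incidence, or a failed [low_event_guard()]); refused analyses are shown
#' as refusals in reports, never as zeros.
#'
#' @param reason Human-readable explanation.
#' @return An object of class `ft_refusal`.
#' @export
refusal <- function(reason) {
  structure(list(refused = TRUE, reason = reason), class = "ft_refusal")
}

#' @export
print.ft_refusal <- function(x, ...) {
  cat("<refused> ", x$reason, "\n", sep = "")
  invisible(x)
}

#' Observed-vs-twin fracture rate ratio on the cumulative-hazard scale
#'
#' Point estimate `log(1 - observed) / log(1 - twin)` -- the ratio of
#' 10-year cumulative hazards, the Poisson-consistent reading of a "rate
#' ratio" -- with a percentile CI from paired bootstrap draws when `boot`
#' carries named columns `observed` and `twin` (the ratio is recomputed
#' within each draw).  The raw incidence quotient `observed / twin` is
#' reported alongside as `raw_quotient`.  A zero twin incidence yields a
#' [refusal()].
#'
#' @param observed A `km_estimate` (its horizon read-out is used) or a bare
#'   observed incidence in \[0, 1\].
#' @param twin_incidence Twin-estimated counterfactual incidence in (0, 1).
#' @param boot Optional `bootstrap_result` with draw columns `observed` and
#'   `twin`.
#' @return A list of class `rate_ratio` with `point_estimate`, `ci_low`,
#'   `ci_high` (NA without `boot`), `raw_quotient`, `n_boot`; or an
#'   `ft_refusal`.
#' @export
rate_ratio <- function(observed, twin_incidence, boot = NULL) {
  obs <- if (inherits(observed, "km_estimate")) {
    observed$horizon_readout$incidence
  } else observed
  stopifnot(obs >= 0, obs <= 1)
  if (!is.numeric(twin_incidence) || twin_incidence <= 0) {
    return(refusal("twin incidence is zero; rate ratio undefined"))
  }
  point <- log1p(-obs) / log1p(-twin_incidence)
  ci <- c(NA_real_, NA_real_)
  rdraws <- NULL
  if (!is.null(boot)) {
    stopifnot(inherits(boot, "bootstrap_result"))
    cols <- colnames(boot$draws)
    if (!all(c("observed", "twin") %in% cols)) {
      stop("boot draws must have columns 'observed' and 'twin'",
           call. = FALSE)
    }
    rdraws <- log1p(-boot$draws[, "observed"]) / log1p(-boot$draws[, "twin"])
    ci <- .percentile_ci(rdraws, boot$level)
  }
  structure(list(point_estimate = point, ci_low = ci[1L], ci_high = ci[2L],
                 raw_quotient = obs / twin_incidence,
                 n_boot = if (is.null(boot)) 0L else boot$n_boot,
                 draws = rdraws),
            class = "rate_ratio")
}

#' @export
print.rate_ratio <- function(x, ...) {
  cat(sprintf("<rate_ratio> %.4f", x$point_estimate))
  if (!is.na(x$ci_low)) {
    cat(sprintf(" (95%% CI %.4f to %.4f, %d resamples)",
                x$ci_low, x$ci_high, x$n_boot))
  }
  cat(sprintf("; raw incidence quotient %.4f\n", x$raw_quotient))
  invisible(x)
}

.report_row <- function(endpoint, quantity, estimate = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        status = "ok", note = "") {
  data.frame(endpoint = endpoint, quantity = quantity,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             status = status, note = note, stringsAsFactors = FALSE)
}

.ref_or_refused <- function(endpoint, quantity, x, extract) {
  if (is.null(x)) return(NULL)
  if (inherits(x, "ft_refusal")) {
    return(.report_row(endpoint, quantity, status = "refused",
                       note = x$reason))
  }
  v <- extract(x)
  .report_row(endpoint, quantity, v[1L], v[2L], v[3L])
}

#' Assemble the final observed / FRAX / virtual-twin comparison report
#'
#' One row per endpoint (MOF, hip) and quantity (observed Kaplan-Meier
#' incidence, mean externally predicted probability, twin estimate), plus
#' the rate ratio; refused analyses (e.g. the hip twin under the low-event
#' guard) appear as refusals with the guard's message, never as zeros.
#'
#' @param km_mof,km_hip `km_estimate` objects (hip optional).
#' @param frax_mof,frax_hip Outputs of [frax_summary()], or `NULL`.
#' @param twin_mof,twin_hip A list with `estimate`, `ci_low`, `ci_high`
#'   (e.g. from [run_twin_analysis()]), an `ft_refusal`, or `NULL`.
#' @param rr A `rate_ratio`, an `ft_refusal`, or `NULL`.
#' @param guards Named list of `event_guard` outcomes to record.
#' @param meta Named list of metadata (seeds, configuration hash, ...).
#' @return An object of class `comparison_report` with elements `rows`
#'   (data frame), `rate_ratio`, `guards`, `meta`.
#' @export
build_report <- function(km_mof, km_hip = NULL, frax_mof = NULL,
                         frax_hip = NULL, twin_mof = NULL, twin_hip = NULL,
                         rr = NULL, guards = list(), meta = list()) {
  stopifnot(inherits(km_mof, "km_estimate"))
  km_row <- function(endpoint, km) {
    ro <- km$horizon_readout
    .report_row(endpoint, "observed_km", ro$incidence, ro$ci_low, ro$ci_high)
  }
  rows <- list(km_row("mof", km_mof))
  if (!is.null(km_hip)) rows <- c(rows, list(km_row("hip", km_hip)))
  rows <- c(rows, list(
    .ref_or_refused("mof", "frax_mean", frax_mof,
                    function(x) c(x$mean_prob, x$ci_low, x$ci_high)),
    .ref_or_refused("hip", "frax_mean", frax_hip,
                    function(x) c(x$mean_prob, x$ci_low, x$ci_high)),
    .ref_or_refused("mof", "virtual_twin", twin_mof,
                    function(x) c(x$estimate, x$ci_low, x$ci_high)),
    .ref_or_refused("hip", "virtual_twin", twin_hip,
                    function(x) c(x$estimate, x$ci_low, x$ci_high))
  ))
  rows <- do.call(rbind, Filter(Negate(is.null), rows))
  rr_out <- if (is.null(rr)) {
    NULL
  } else if (inherits(rr, "ft_refusal")) {
    list(status = "refused", note = rr$reason)
  } else {
    list(status = "ok", estimate = rr$point_estimate, ci_low = rr$ci_low,
         ci_high = rr$ci_high, raw_quotient = rr$raw_quotient,
         n_boot = rr$n_boot)
  }
  structure(list(
    rows = rows,
    rate_ratio = rr_out,
    guards = lapply(guards, function(g) {
      if (inherits(g, "event_guard")) unclass(g) else g
    }),
    meta = meta
  ), class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>\n")
  print(x$rows, row.names = FALSE)
  if (!is.null(x$rate_ratio)) {
    rrr <- x$rate_ratio
    if (identical(rrr$status, "refused")) {
      cat("  rate ratio: refused --", rrr$note, "\n")
    } else {
      cat(sprintf("  rate ratio (hazard scale): %.4f [%.4f, %.4f]\n",
                  rrr$estimate, rrr$ci_low, rrr$ci_high))
    }
  }
  for (nm in names(x$guards)) {
    g <- x$guards[[nm]]
    cat("  guard [", nm, "]: ", g$message, "\n", sep = "")
  }
  invisible(x)
}

#' Three-bar comparison plot of a report
#'
#' Observed, externally predicted, and virtual-twin 10-year incidences per
#' endpoint, with 95% CI whiskers; refused analyses are annotated instead
#' of drawn.
#'
#' @param x A `comparison_report`.
#' @param endpoint `"mof"` or `"hip"`.
#' @param ... Unused.
#' @return Invisibly, the plotted data frame.
#' @export
plot.comparison_report <- function(x, endpoint = "mof", ...) {
  d <- x$rows[x$rows$endpoint == endpoint, , drop = FALSE]
  labels <- c(observed_km = "Observed (KM)", frax_mean = "Predicted (FRAX)",
              virtual_twin = "Virtual twin")
  ok <- d$status == "ok"
  heights <- ifelse(ok, d$estimate, 0) * 100
  bp <- graphics::barplot(heights, names.arg = labels[d$quantity],
                          ylab = "10-year cumulative incidence (%)",
                          main = toupper(endpoint),
                          ylim = c(0, max(c(d$ci_high * 100, heights),
                                          na.rm = TRUE) * 1.15))
  has_ci <- ok & !is.na(d$ci_low)
  if (any(has_ci)) {
    graphics::arrows(bp[has_ci], d$ci_low[has_ci] * 100,
                     bp[has_ci], d$ci_high[has_ci] * 100,
                     angle = 90, code = 3, length = 0.06)
  }
  if (any(!ok)) {
    graphics::text(bp[!ok], 0, "refused", srt = 90, adj = c(-0.2, 0.5))
  }
  invisible(d)
}

#' Serialize / restore a comparison report as JSON
#'
#' @param report A `comparison_report`.
#' @param path File path.
#' @return `write_report`: `path` invisibly; `read_report`: the restored
#'   `comparison_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "comparison_report"))
  out <- unclass(report)
  out$schema_version <- 1L
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$schema_version <- NULL
  x$rows <- as.data.frame(x$rows, stringsAsFactors = FALSE)
  for (col in c("estimate", "ci_low", "ci_high")) {
    x$rows[[col]] <- as.numeric(x$rows[[col]])
  }
  structure(x, class = "comparison_report")
}
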