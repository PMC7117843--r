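# Interface to externally computed 10-year fracture probabilities.  The
# probability algorithm itself (FRAX) is an external black box: its outputs
# arrive as per-subject input columns.  In scope here: conditional-model
# imputation of missing clinical risk factors and the predicted-vs-observed
# summary.

.profile_continuous <- c("age_years", "bmi", "femoral_neck_tscore")
.profile_binary <- c("prior_fracture", "parental_hip_fracture",
                     "alcohol_3_units", "current_smoker")
.profile_fixed_false <- c("glucocorticoid_use", "rheumatoid_arthritis")

#' Clinical risk-factor profiles from a cohort
#'
#' Maps a cohort to the risk-factor layout consumed by external 10-year
#' fracture-probability calculators: age, BMI, femoral-neck T-score, prior
#' fracture (union of the vertebral and nonvertebral history indicators),
#' parental hip fracture, daily alcohol >= 3 units, smoking status.
#' Glucocorticoid use and rheumatoid arthritis are fixed `FALSE` (trial
#' exclusion criteria).  Parental hip fracture and alcohol are taken from
#' the pass-through columns `parental_hip_fx` / `alcohol_3plus_units` when
#' present, else left missing for [impute_missing()].
#'
#' @param cohort A `fracture_cohort`.
#' @return Data frame of class `risk_profiles`, one row per subject.
#' @export
risk_factor_profiles <- function(cohort) {
  s <- cohort$subjects
  out <- data.frame(
    subject_id = s$subject_id,
    age_years = s$age_years,
    bmi = s$bmi,
    femoral_neck_tscore = s$femoral_neck_tscore,
    prior_fracture = s$prior_vertebral_fx | s$prior_nonvertebral_fx,
    parental_hip_fracture = if ("parental_hip_fx" %in% names(s)) {
      as.logical(s$parental_hip_fx)
    } else NA,
    alcohol_3_units = if ("alcohol_3plus_units" %in% names(s)) {
      as.logical(s$alcohol_3plus_units)
    } else NA,
    current_smoker = s$ever_smoker,
    glucocorticoid_use = FALSE,
    rheumatoid_arthritis = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("risk_profiles", "data.frame")
  out
}

#' Impute missing risk factors from conditional models
#'
#' Fills missing values by single stochastic draws from conditional models
#' fitted on the profiles' own complete cases: each missing continuous field
#' (age, BMI, femoral-neck T-score) is drawn from a linear model on the
#' other two continuous fields plus a Gaussian residual; each missing binary
#' field is then drawn from a logistic model on the three continuous fields.
#' (A missing model predictor is replaced by its complete-case mean.)
#' Observed values are never altered; `glucocorticoid_use` and
#' `rheumatoid_arthritis` stay `FALSE`.  Deterministic given `seed`.
#'
#' @param profiles A data frame with the columns of
#'   [risk_factor_profiles()] (binaries logical, possibly `NA`).
#' @param seed Integer seed.
#' @param min_complete Minimum complete cases required per imputed field
#'   (default 20); fewer is an error naming the field.
#' @param n_draws Number of independent single-draw repetitions to perform
#'   (default 1).  With `n_draws > 1` a list of imputed data frames is
#'   returned, a sensitivity-check convenience.
#' @return The imputed data frame (or list of them when `n_draws > 1`).
#' @export
impute_missing <- function(profiles, seed, min_complete = 20L,
                           n_draws = 1L) {
  p <- as.data.frame(profiles)
  need <- c(.profile_continuous, .profile_binary)
  miss_cols <- setdiff(need, names(p))
  if (length(miss_cols)) {
    stop("profiles are missing column(s): ",
         paste(miss_cols, collapse = ", "), call. = FALSE)
  }
  for (col in need) {
    if (anyNA(p[[col]]) && sum(!is.na(p[[col]])) < min_complete) {
      stop("field '", col, "' has fewer than ", min_complete,
           " complete cases; cannot fit its imputation model",
           call. = FALSE)
    }
  }
  set.seed(as.integer(seed))
  one_draw <- function() {
    d <- p
    cc_mean <- vapply(.profile_continuous,
                      function(col) mean(d[[col]], na.rm = TRUE), 0)
    # continuous fields: linear model on the other two
    for (col in .profile_continuous) {
      na_i <- which(is.na(d[[col]]))
      if (!length(na_i)) next
      others <- setdiff(.profile_continuous, col)
      cc <- which(stats::complete.cases(p[, .profile_continuous]))
      X <- cbind(1, as.matrix(p[cc, others]))
      fit <- lm.fit(X, p[cc, col])
      sigma <- sqrt(sum(fit$residuals^2) / (length(cc) - ncol(X)))
      Xn <- cbind(1, as.matrix(d[na_i, others, drop = FALSE]))
      for (j in seq_along(others)) {
        nas <- is.na(Xn[, j + 1L])
        Xn[nas, j + 1L] <- cc_mean[[others[j]]]
      }
      d[na_i, col] <- as.numeric(Xn %*% fit$coefficients) +
        rnorm(length(na_i), 0, sigma)
    }
    # binary fields: logistic model on the (now filled) continuous fields
    for (col in .profile_binary) {
      na_i <- which(is.na(d[[col]]))
      if (!length(na_i)) next
      cc <- which(!is.na(p[[col]]) &
                    stats::complete.cases(p[, .profile_continuous]))
      Xc <- as.matrix(p[cc, .profile_continuous])
      fit <- suppressWarnings(
        glm.fit(cbind(1, Xc), as.numeric(p[cc, col]), family = binomial())
      )
      Xn <- cbind(1, as.matrix(d[na_i, .profile_continuous, drop = FALSE]))
      prob <- plogis(as.numeric(Xn %*% fit$coefficients))
      d[na_i, col] <- runif(length(na_i)) < prob
    }
    for (col in intersect(.profile_fixed_false, names(d))) {
      d[[col]] <- FALSE
    }
    d
  }
  if (n_draws == 1L) one_draw() else replicate(n_draws, one_draw(),
                                               simplify = FALSE)
}

#' Mean externally predicted 10-year fracture probability
#'
#' Summarizes the per-subject externally computed probabilities
#' (`frax_mof_prob` / `frax_hip_prob`): their mean with the normal-
#' approximation 95% CI `mean +/- 1.96 * SD / sqrt(n)`.  Subjects with a
#' missing probability are excluded; all missing is an error.
#'
#' @param cohort A `fracture_cohort`.
#' @param endpoint `"mof"` or `"hip"`.
#' @return A list of class `frax_summary`: `mean_prob`, `ci_low`,
#'   `ci_high`, `sd`, `n`, `endpoint`.
#' @export
frax_summary <- function(cohort, endpoint = c("mof", "hip")) {
  endpoint <- match.arg(endpoint)
  col <- paste0("frax_", endpoint, "_prob")
  v <- cohort$subjects[[col]]
  v <- v[!is.na(v)]
  if (length(v) == 0L) {
    stop("no non-missing values in '", col, "'", call. = FALSE)
  }
  s <- if (length(v) > 1L) sd(v) else 0
  half <- 1.96 * s / sqrt(length(v))
  structure(list(mean_prob = mean(v),
                 ci_low = max(0, mean(v) - half),
                 ci_high = min(1, mean(v) + half),
                 sd = s, n = length(v), endpoint = endpoint),
            class = "frax_summary")
}

#' @export
print.frax_summary <- function(x, ...) {
  cat(sprintf(paste0("<frax_summary> %s: mean 10-year probability %.4f ",
                     "(95%% CI %.4f to %.4f; SD %.4f, n = %d)\n"),
              x$endpoint, x$mean_prob, x$ci_low, x$ci_high, x$sd, x$n))
  invisible(x)
}
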