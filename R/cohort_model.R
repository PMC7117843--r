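# Subject/event data model shared by all pipeline stages.
#
# Times are fractional years since core-trial baseline.  The core period is
# the half-open interval [0, 3), the extension [3, 10), so a boundary event
# is never counted twice.  Recurrent events are stored (the fracture-rate
# model is a count model); time-to-first-event is derived on demand for the
# Kaplan-Meier estimator.

#' Major osteoporotic fracture (MOF) component event types
#'
#' A MOF is any clinical vertebral, hip, forearm, or humerus fracture,
#' regardless of trauma severity.  All event-set arguments in the package
#' must be non-empty subsets of this vector.
#'
#' @format Character vector of length 4.
#' @export
mof_event_types <- c("clinical_vertebral", "hip", "forearm", "humerus")

#' Trial arms
#'
#' `placebo_crossover` subjects received placebo in the 3-year core trial and
#' active treatment in the 7-year extension; their core-period data represent
#' untreated behaviour and calibrate the counterfactual models.
#' `denosumab_longterm` subjects received active treatment throughout.
#'
#' @format Character vector of length 2.
#' @export
cohort_arms <- c("placebo_crossover", "denosumab_longterm")

.subject_required <- c(
  "subject_id", "arm", "age_years", "bmi", "femoral_neck_tscore",
  "total_hip_tscore_baseline", "total_hip_tscore_end_core",
  "prior_vertebral_fx", "prior_nonvertebral_fx", "ever_smoker",
  "core_followup_years", "extension_followup_years",
  "frax_mof_prob", "frax_hip_prob"
)
.subject_numeric <- c(
  "age_years", "bmi", "femoral_neck_tscore", "total_hip_tscore_baseline",
  "total_hip_tscore_end_core", "core_followup_years",
  "extension_followup_years", "frax_mof_prob", "frax_hip_prob"
)
.subject_logical <- c("prior_vertebral_fx", "prior_nonvertebral_fx",
                      "ever_smoker")
.event_required <- c("subject_id", "event_type", "time_years")

.empty_events <- function() {
  data.frame(subject_id = character(), event_type = character(),
             time_years = numeric(), stringsAsFactors = FALSE)
}

new_fracture_cohort <- function(subjects, events, provenance = "") {
  structure(list(subjects = subjects, events = events,
                 provenance = provenance),
            class = "fracture_cohort")
}

#' Construct a validated fracture cohort
#'
#' Bundles a subject table and a long-format event table into the container
#' consumed by every estimator in the package.  Events are sorted by subject
#' and time; all structural invariants (unique ids, event times within
#' follow-up, follow-up ranges) are enforced unless `validate = FALSE`.
#'
#' @param subjects Data frame with one row per subject.  Required columns:
#'   `subject_id`, `arm` (one of [cohort_arms]), `age_years`, `bmi`,
#'   `femoral_neck_tscore`, `total_hip_tscore_baseline`,
#'   `total_hip_tscore_end_core` (may be `NA`), `prior_vertebral_fx`,
#'   `prior_nonvertebral_fx`, `ever_smoker` (logical), `core_followup_years`
#'   in (0, 3], `extension_followup_years` in \[0, 7\], `frax_mof_prob` and
#'   `frax_hip_prob` in \[0, 1\] or `NA`.  Additional columns are carried
#'   through untouched.
#' @param events Data frame with columns `subject_id`, `event_type` (one of
#'   [mof_event_types]) and `time_years`, or `NULL` for no events.
#' @param provenance Free-text provenance string (file path, simulation
#'   seed/configuration) carried along for reporting.
#' @param validate Run [validate_cohort()]?  Internal callers that resample
#'   an already-valid cohort may skip it.
#' @return An object of class `fracture_cohort`: a list with elements
#'   `subjects`, `events`, `provenance`.
#' @seealso [read_cohort()], [write_cohort()], [generate_cohort()]
#' @export
fracture_cohort <- function(subjects, events = NULL, provenance = "",
                            validate = TRUE) {
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)
  rownames(subjects) <- NULL
  if (is.null(events) || nrow(as.data.frame(events)) == 0L) {
    events <- .empty_events()
  } else {
    events <- as.data.frame(events, stringsAsFactors = FALSE)
  }
  if (nrow(events)) {
    events <- events[order(match(events$subject_id, subjects$subject_id),
                           events$time_years), , drop = FALSE]
    rownames(events) <- NULL
  }
  x <- new_fracture_cohort(subjects, events, provenance)
  if (validate) validate_cohort(x)
  x
}

#' Validate a fracture cohort
#'
#' Checks every structural invariant of the data model and fails with a
#' message naming the offending column and row.  Returns the cohort
#' invisibly so it can be used in pipes.
#'
#' @param cohort A `fracture_cohort`.
#' @return `cohort`, invisibly.
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "fracture_cohort"))
  s <- cohort$subjects
  e <- cohort$events

  miss <- setdiff(.subject_required, names(s))
  if (length(miss)) {
    stop("subjects table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(s) < 1L) stop("cohort must contain at least one subject",
                         call. = FALSE)
  if (anyDuplicated(s$subject_id)) {
    dup <- s$subject_id[duplicated(s$subject_id)][1L]
    stop("duplicate subject_id: '", dup, "'", call. = FALSE)
  }
  bad_arm <- which(!s$arm %in% cohort_arms)
  if (length(bad_arm)) {
    stop(sprintf("column 'arm', row %d: invalid value '%s'",
                 bad_arm[1L], s$arm[bad_arm[1L]]), call. = FALSE)
  }
  for (col in .subject_numeric) {
    if (!is.numeric(s[[col]])) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
  }
  for (col in .subject_logical) {
    if (!is.logical(s[[col]]) || anyNA(s[[col]])) {
      stop("column '", col, "' must be logical with no missing values",
           call. = FALSE)
    }
  }
  .check_range <- function(col, lo, hi, na_ok = FALSE, lo_open = FALSE) {
    v <- s[[col]]
    bad <- if (lo_open) (v <= lo | v > hi) else (v < lo | v > hi)
    bad <- if (na_ok) which(!is.na(v) & bad) else which(is.na(v) | bad)
    if (length(bad)) {
      stop(sprintf("column '%s', row %d: value %s outside %s%g, %g]",
                   col, bad[1L], format(v[bad[1L]]),
                   if (lo_open) "(" else "[", lo, hi), call. = FALSE)
    }
  }
  .check_range("age_years", 0, Inf, lo_open = TRUE)
  .check_range("bmi", 0, Inf, lo_open = TRUE)
  .check_range("core_followup_years", 0, 3 + 1e-9, lo_open = TRUE)
  .check_range("extension_followup_years", 0, 7 + 1e-9)
  .check_range("frax_mof_prob", 0, 1, na_ok = TRUE)
  .check_range("frax_hip_prob", 0, 1, na_ok = TRUE)

  miss_e <- setdiff(.event_required, names(e))
  if (length(miss_e)) {
    stop("events table is missing column(s): ",
         paste(miss_e, collapse = ", "), call. = FALSE)
  }
  if (nrow(e)) {
    bad <- which(!e$event_type %in% mof_event_types)
    if (length(bad)) {
      stop(sprintf("events column 'event_type', row %d: invalid type '%s'",
                   bad[1L], e$event_type[bad[1L]]), call. = FALSE)
    }
    unknown <- which(!e$subject_id %in% s$subject_id)
    if (length(unknown)) {
      stop(sprintf("events row %d: unknown subject_id '%s'",
                   unknown[1L], e$subject_id[unknown[1L]]), call. = FALSE)
    }
    fu <- s$core_followup_years + s$extension_followup_years
    names(fu) <- s$subject_id
    bad_t <- which(is.na(e$time_years) | e$time_years < 0 |
                     e$time_years >= fu[e$subject_id])
    if (length(bad_t)) {
      i <- bad_t[1L]
      stop(sprintf(paste0("events row %d (subject '%s'): time_years %s not ",
                          "in [0, total follow-up %g)"),
                   i, e$subject_id[i], format(e$time_years[i]),
                   fu[e$subject_id[i]]), call. = FALSE)
    }
  }
  invisible(cohort)
}

#' @export
print.fracture_cohort <- function(x, ...) {
  s <- x$subjects
  cat("<fracture_cohort> ", nrow(s), " subjects, ", nrow(x$events),
      " fracture events\n", sep = "")
  tab <- table(factor(s$arm, levels = cohort_arms))
  cat("  arms: ", paste(sprintf("%s = %d", names(tab), tab),
                        collapse = ", "), "\n", sep = "")
  n_comp <- sum(.is_completer(s))
  cat("  10-year completers: ", n_comp, "\n", sep = "")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

.is_completer <- function(subjects, tol = 1e-9) {
  abs(subjects$core_followup_years - 3) <= tol &
    abs(subjects$extension_followup_years - 7) <= tol
}

#' Restrict a cohort to 10-year completers
#'
#' A completer has `core_followup_years == 3` and
#' `extension_followup_years == 7` within `tol` (the analysis set of the
#' virtual-twin method and of the observed 10-year incidence).
#'
#' @param cohort A `fracture_cohort`.
#' @param tol Numeric tolerance on the follow-up equalities.
#' @return A `fracture_cohort` containing only completers.
#' @export
completers <- function(cohort, tol = 1e-9) {
  keep <- cohort$subjects$subject_id[.is_completer(cohort$subjects, tol)]
  subset_cohort(cohort, keep)
}

#' Subset a cohort by arm
#'
#' @param cohort A `fracture_cohort`.
#' @param arm One of [cohort_arms].
#' @return A `fracture_cohort`.
#' @export
subset_arm <- function(cohort, arm) {
  arm <- match.arg(arm, cohort_arms)
  subset_cohort(cohort, cohort$subjects$subject_id[cohort$subjects$arm == arm])
}

#' Subset a cohort by subject id
#'
#' @param cohort A `fracture_cohort`.
#' @param subject_ids Character vector of ids to keep.
#' @return A `fracture_cohort` with the matching subjects and their events.
#' @export
subset_cohort <- function(cohort, subject_ids) {
  s <- cohort$subjects[cohort$subjects$subject_id %in% subject_ids, ,
                       drop = FALSE]
  e <- cohort$events[cohort$events$subject_id %in% subject_ids, ,
                     drop = FALSE]
  rownames(s) <- rownames(e) <- NULL
  new_fracture_cohort(s, e, cohort$provenance)
}

#' Time to first fracture of a given type set, per subject
#'
#' For each subject, returns the time of the first event whose type lies in
#' `event_set` (`observed = TRUE`), or the total follow-up time with
#' `observed = FALSE` if no such event occurred.  This is the input of the
#' product-limit estimator.
#'
#' @param cohort A `fracture_cohort`.
#' @param event_set Non-empty subset of [mof_event_types].
#' @return Data frame with columns `subject_id`, `time_years`, `observed`,
#'   one row per subject in the order of the subject table.
#' @export
first_event_times <- function(cohort, event_set = mof_event_types) {
  event_set <- .check_event_set(event_set)
  s <- cohort$subjects
  fu <- s$core_followup_years + s$extension_followup_years
  out <- data.frame(subject_id = s$subject_id, time_years = fu,
                    observed = FALSE, stringsAsFactors = FALSE)
  e <- cohort$events
  e <- e[e$event_type %in% event_set, , drop = FALSE]
  if (nrow(e)) {
    first <- tapply(e$time_years, e$subject_id, min)
    idx <- match(names(first), out$subject_id)
    out$time_years[idx] <- as.numeric(first)
    out$observed[idx] <- TRUE
  }
  out
}

.check_event_set <- function(event_set) {
  if (length(event_set) == 0L || !all(event_set %in% mof_event_types)) {
    stop("event_set must be a non-empty subset of: ",
         paste(mof_event_types, collapse = ", "), call. = FALSE)
  }
  unique(event_set)
}

# ---- CSV serialization -----------------------------------------------------
# Numerics are written with 17 significant digits so write -> read is the
# identity on doubles; booleans as "true"/"false"; missing values as empty
# cells (never sentinel numbers).

.fmt_field <- function(v) {
  if (is.numeric(v)) {
    out <- ifelse(is.na(v), "", sprintf("%.17g", v))
  } else if (is.logical(v)) {
    out <- ifelse(is.na(v), "", ifelse(v, "true", "false"))
  } else {
    out <- ifelse(is.na(v), "", as.character(v))
  }
  out
}

.write_csv_exact <- function(df, path) {
  cols <- lapply(df, .fmt_field)
  if (any(vapply(cols, function(x) any(grepl("[,\"\n]", x)), logical(1)))) {
    stop("field values containing commas, quotes or newlines are not ",
         "supported by the CSV writer", call. = FALSE)
  }
  lines <- c(paste(names(df), collapse = ","),
             if (nrow(df)) do.call(paste, c(cols, sep = ",")))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Write a cohort to subject and event CSV files
#'
#' Numeric fields are serialized to full double precision (17 significant
#' digits), booleans as `"true"`/`"false"`, missing values as empty cells,
#' so that [read_cohort()] reproduces the cohort exactly, field by field.
#'
#' @param cohort A valid `fracture_cohort`.
#' @param subjects_path,events_path Output file paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_cohort <- function(cohort, subjects_path, events_path) {
  validate_cohort(cohort)
  .write_csv_exact(cohort$subjects, subjects_path)
  .write_csv_exact(cohort$events, events_path)
  invisible(c(subjects = subjects_path, events = events_path))
}

.parse_numeric <- function(raw, col, file) {
  out <- suppressWarnings(as.numeric(ifelse(raw == "", NA, raw)))
  bad <- which(raw != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: column '%s', row %d: cannot parse '%s' as a number",
                 file, col, bad[1L], raw[bad[1L]]), call. = FALSE)
  }
  out
}

.parse_logical <- function(raw, col, file, na_ok = FALSE) {
  low <- tolower(raw)
  out <- ifelse(low %in% c("true", "t", "1"), TRUE,
                ifelse(low %in% c("false", "f", "0"), FALSE, NA))
  bad <- which(raw != "" & is.na(out))
  if (length(bad)) {
    stop(sprintf("%s: column '%s', row %d: cannot parse '%s' as true/false",
                 file, col, bad[1L], raw[bad[1L]]), call. = FALSE)
  }
  if (!na_ok && any(raw == "")) {
    stop(sprintf("%s: column '%s' has missing values", file, col),
         call. = FALSE)
  }
  as.logical(out)
}

.read_raw_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, colClasses = "character", check.names = FALSE,
                  na.strings = character())
}

#' Read a cohort from subject and event CSV files
#'
#' Inverse of [write_cohort()].  Schema violations (missing columns,
#' unparseable values) are reported with the offending column and row;
#' all cohort invariants are then enforced by [validate_cohort()].
#' Optional columns left empty are loaded as missing, never as zero.
#' Columns beyond the documented schema are carried through (numerics and
#' `"true"`/`"false"` fields are type-converted).
#'
#' @param subjects_path Path of the subjects CSV.
#' @param events_path Path of the long-format events CSV, or `NULL` for a
#'   cohort with no recorded fractures.
#' @param provenance Provenance string; defaults to `subjects_path`.
#' @return A validated `fracture_cohort`.
#' @export
read_cohort <- function(subjects_path, events_path = NULL,
                        provenance = subjects_path) {
  raw <- .read_raw_csv(subjects_path)
  miss <- setdiff(.subject_required, names(raw))
  if (length(miss)) {
    stop(subjects_path, ": missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  s <- data.frame(subject_id = raw$subject_id, arm = raw$arm,
                  stringsAsFactors = FALSE)
  for (col in .subject_numeric) {
    s[[col]] <- .parse_numeric(raw[[col]], col, subjects_path)
  }
  for (col in .subject_logical) {
    s[[col]] <- .parse_logical(raw[[col]], col, subjects_path)
  }
  extra <- setdiff(names(raw), c(names(s)))
  for (col in extra) {
    v <- raw[[col]]
    if (all(v %in% c("true", "false", ""))) {
      s[[col]] <- .parse_logical(v, col, subjects_path, na_ok = TRUE)
    } else {
      s[[col]] <- utils::type.convert(ifelse(v == "", NA, v), as.is = TRUE)
    }
  }
  s <- s[, c(.subject_required, setdiff(names(s), .subject_required)),
         drop = FALSE]

  if (is.null(events_path)) {
    e <- .empty_events()
  } else {
    raw_e <- .read_raw_csv(events_path)
    miss_e <- setdiff(.event_required, names(raw_e))
    if (length(miss_e)) {
      stop(events_path, ": missing required column(s): ",
           paste(miss_e, collapse = ", "), call. = FALSE)
    }
    e <- data.frame(subject_id = raw_e$subject_id,
                    event_type = raw_e$event_type,
                    time_years = .parse_numeric(raw_e$time_years,
                                                "time_years", events_path),
                    stringsAsFactors = FALSE)
  }
  fracture_cohort(s, e, provenance = provenance)
}
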