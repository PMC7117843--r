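# Small programmatic fixtures shared across test files.

subj_row <- function(id, arm = "denosumab_longterm", age = 70, bmi = 26,
                     fn = -2.1, th0 = -2.0, th_end = NA_real_,
                     pvf = FALSE, pnvf = FALSE, smoker = FALSE,
                     core = 3, ext = 7,
                     frax_mof = NA_real_, frax_hip = NA_real_) {
  data.frame(
    subject_id = id, arm = arm, age_years = age, bmi = bmi,
    femoral_neck_tscore = fn, total_hip_tscore_baseline = th0,
    total_hip_tscore_end_core = th_end,
    prior_vertebral_fx = pvf, prior_nonvertebral_fx = pnvf,
    ever_smoker = smoker,
    core_followup_years = core, extension_followup_years = ext,
    frax_mof_prob = frax_mof, frax_hip_prob = frax_hip,
    stringsAsFactors = FALSE
  )
}

event_row <- function(id, type, time) {
  data.frame(subject_id = id, event_type = type, time_years = time,
             stringsAsFactors = FALSE)
}

# Cohort of n subjects with complete 10-year follow-up and at most one
# event each, drawn from a constant hazard; used by the KM tests.
constant_hazard_cohort <- function(n, lambda, seed,
                                   arm = "denosumab_longterm",
                                   censor_rate = 0) {
  set.seed(seed)
  t_ev <- rexp(n, lambda)
  fu <- rep(10, n)
  if (censor_rate > 0) fu <- pmin(10, rexp(n, censor_rate))
  core <- pmin(3, fu)
  ext <- pmax(0, fu - 3)
  ids <- sprintf("C%05d", seq_len(n))
  subjects <- subj_row(ids, arm = arm, core = core, ext = ext)
  has_ev <- t_ev < fu
  events <- event_row(ids[has_ev], "forearm", t_ev[has_ev])
  fracture_cohort(subjects, events, provenance = "constant hazard fixture")
}

# A small two-arm cohort with enough structure to fit both placebo models.
small_twoarm_cohort <- function(seed = 1, n_per_arm = 400) {
  generate_cohort(sim_config(n_per_arm = n_per_arm, seed = seed))$cohort
}
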