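# Small in-code fixtures shared across test files.

# quick visit-table builder: one patient unless ids given
make_visits <- function(times, gds, fast = gds, ids = "p1",
                        sex = "F", age = NA_real_, edu = NA_real_) {
  df <- data.frame(patient_id = rep_len(ids, length(times)),
                   visit_time = times,
                   gds_stage = as.integer(rep_len(gds, length(times))),
                   fast_stage = as.integer(rep_len(fast, length(times))),
                   sex = rep_len(sex, length(times)),
                   age_at_visit = rep_len(age, length(times)),
                   education_years = rep_len(edu, length(times)),
                   stringsAsFactors = FALSE)
  class(df) <- c("visit_cohort", "data.frame")
  df
}

# bare intervals row(s) for direct NPMLE-level tests
make_intervals <- function(XL, XR, ZL, ZR, ids = NULL) {
  n <- length(XL)
  df <- data.frame(patient_id = ids %||% sprintf("p%03d", seq_len(n)),
                   stage = 5L, scale = "gds",
                   XL = XL, XR = XR, ZL = ZL, ZR = ZR,
                   stringsAsFactors = FALSE)
  class(df) <- c("stage_intervals", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# single-stage recovery cohort used by several tests
recovery_config <- function(stage, n = 2000, seed = 1,
                            family = "exponential", cv = 1,
                            schedule = schedule_preset("paper_visits")) {
  cohort_config(
    n_patients = n, entry_mode = "at_onset",
    entry_stage_distribution = stats::setNames(1, as.character(stage)),
    duration_model = stage_duration_model(family = family, cv = cv),
    schedule = schedule,
    follow_through_exit = TRUE, scale_agreement_prob = 1, seed = seed)
}
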