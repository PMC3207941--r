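# YAML serialization of simulation configurations, so that cohorts can be
# regenerated from a plain-text file and a seed.

#' Read/write a cohort simulation configuration
#'
#' The YAML layout mirrors [cohort_config()]: top-level scalar fields plus
#' `duration_model` (stages/means/family/cv) and `schedule` sections.
#'
#' @param config a [cohort_config()].
#' @param path file path.
#' @return `read_cohort_config` returns a `cohort_config`;
#'   `write_cohort_config` returns `path` invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  dm <- config$duration_model
  s <- config$schedule
  out <- list(
    n_patients = config$n_patients,
    entry_mode = config$entry_mode,
    entry_stage_distribution = as.list(config$entry_stage_distribution),
    duration_model = list(stages = dm$stages, means = dm$means,
                          family = dm$family, cv = dm$cv),
    schedule = list(mode = s$mode, nominal_interval = s$nominal_interval,
                    attendance_prob = s$attendance_prob,
                    jitter_sd = s$jitter_sd,
                    count_distribution =
                      if (is.null(s$count_distribution)) NULL
                      else as.list(s$count_distribution),
                    max_follow_up = s$max_follow_up),
    follow_through_exit = config$follow_through_exit,
    age_mean = config$age_mean, age_sd = config$age_sd,
    fraction_female = config$fraction_female,
    education_mean = config$education_mean,
    education_sd = config$education_sd,
    scale_agreement_prob = config$scale_agreement_prob,
    calendar_period = config$calendar_period,
    seed = config$seed
  )
  yaml::write_yaml(out, path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_config
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  dm <- y$duration_model
  means <- setNames(as.numeric(dm$means), as.character(dm$stages))
  model <- stage_duration_model(means = means,
                                family = as.character(dm$family),
                                cv = as.numeric(dm$cv))
  sc <- y$schedule
  schedule <- visit_schedule_model(
    mode = sc$mode,
    nominal_interval = sc$nominal_interval,
    attendance_prob = sc$attendance_prob,
    jitter_sd = sc$jitter_sd,
    count_distribution =
      if (is.null(sc$count_distribution)) NULL
      else unlist(sc$count_distribution),
    max_follow_up = sc$max_follow_up
  )
  cohort_config(
    n_patients = y$n_patients,
    entry_mode = y$entry_mode,
    entry_stage_distribution = unlist(y$entry_stage_distribution),
    duration_model = model,
    schedule = schedule,
    follow_through_exit = isTRUE(y$follow_through_exit),
    age_mean = y$age_mean, age_sd = y$age_sd,
    fraction_female = y$fraction_female,
    education_mean = y$education_mean, education_sd = y$education_sd,
    scale_agreement_prob = y$scale_agreement_prob,
    calendar_period = as.numeric(y$calendar_period),
    seed = y$seed
  )
}
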