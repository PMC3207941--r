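test_that("sample_durations moment-matches each family", {
  model <- stage_duration_model(c("4" = 2.0), family = "fixed", cv = 0)
  expect_equal(sample_durations(model, 4, 10), rep(2, 10))

  set.seed(11)
  # exponential: LLN bound, se = mean/sqrt(n)
  m <- stage_duration_model(c("4" = 2.0), family = "exponential")
  x <- sample_durations(m, 4, 1e5)
  expect_true(abs(mean(x) - 2.0) < 3 * 2.0 / sqrt(1e5))

  g <- stage_duration_model(c("4" = 2.0), family = "gamma", cv = 0.5)
  x <- sample_durations(g, 4, 1e5)
  expect_equal(mean(x), 2.0, tolerance = 0.02)
  expect_equal(sd(x) / mean(x), 0.5, tolerance = 0.02)

  for (fam in c("lognormal", "weibull")) {
    mm <- stage_duration_model(c("5" = 1.5), family = fam, cv = 0.7)
    x <- sample_durations(mm, 5, 2e5)
    expect_equal(mean(x), 1.5, tolerance = 0.03)
    expect_equal(sd(x) / mean(x), 0.7, tolerance = 0.03)
    expect_true(all(x > 0))
  }

  expect_error(stage_duration_model(c("4" = 2), family = "fixed", cv = 1),
               "cv = 0")
  expect_error(sample_durations(m, 2, 1), "no duration model")
})

test_that("cohort generation is a pure function of (config, seed)", {
  cfg <- cohort_config(n_patients = 30, seed = 99)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c2 <- generate_cohort(cfg, seed = 100)
  expect_false(identical(a$visits, c2$visits))
})

test_that("recorded GDS stage equals the ground-truth stage at each visit", {
  cfg <- cohort_config(n_patients = 150, scale_agreement_prob = 1, seed = 5)
  sim <- generate_cohort(cfg)
  tr <- split(sim$truth, sim$truth$patient_id)
  for (id in names(tr)) {
    t_onsets <- tr[[id]]
    v <- sim$visits[sim$visits$patient_id == id, ]
    # true stage at time t: entry stage plus boundaries crossed (half-open)
    entry_stage <- min(t_onsets$stage)
    bounds <- t_onsets$onset_time + t_onsets$duration
    expected <- entry_stage +
      vapply(v$visit_time, function(ti) sum(ti >= bounds - 1e-9), numeric(1))
    expect_equal(v$gds_stage, pmin(as.integer(expected), 7L))
    # FAST identical when agreement prob is 1
    expect_equal(v$fast_stage, v$gds_stage)
  }
})

test_that("entry at onset places the first visit exactly at stage onset", {
  cfg <- recovery_config(stage = 5, n = 80, seed = 3)
  sim <- generate_cohort(cfg)
  first_visit <- tapply(sim$visits$visit_time, sim$visits$patient_id, min)
  onset5 <- setNames(sim$truth$onset_time[sim$truth$stage == 5],
                     sim$truth$patient_id[sim$truth$stage == 5])
  expect_equal(as.numeric(first_visit[names(onset5)]), unname(onset5),
               tolerance = 1e-9)
  # point-mass entry distribution: every first stage is 5
  first_stage <- tapply(sim$visits$gds_stage, sim$visits$patient_id,
                        function(s) s[1])
  expect_true(all(first_stage == 5))
})

test_that("deterministic walk crosses stage boundaries on schedule", {
  cfg <- cohort_config(
    n_patients = 1, entry_mode = "at_onset",
    entry_stage_distribution = c("4" = 1),
    duration_model = stage_duration_model(
      c("4" = 2.0, "5" = 2.0, "6" = 2.0), family = "fixed", cv = 0),
    schedule = visit_schedule_model("process", nominal_interval = 2,
                                    attendance_prob = 1, jitter_sd = 0,
                                    max_follow_up = 12),
    scale_agreement_prob = 1, seed = 1)
  sim <- generate_cohort(cfg)
  v <- sim$visits
  # q = 1, interval 2, follow-up 12 -> 7 attended visits
  expect_equal(nrow(v), 7)
  expect_equal(v$visit_time - v$visit_time[1], seq(0, 12, by = 2))
  # stage 4 lasts exactly 2.0: visit at t = 2 reports stage 5 (half-open)
  expect_equal(v$gds_stage[1:3], c(4L, 5L, 6L))
})

test_that("attended inter-visit gaps have mean nominal_interval / q", {
  # long follow-up keeps the boundary truncation bias well below the
  # Monte-Carlo noise (dropped final partial gaps shorten the observed mean)
  sched <- visit_schedule_model("process", nominal_interval = 2,
                                attendance_prob = 0.66, jitter_sd = 0,
                                max_follow_up = 400)
  set.seed(21)
  times <- sample_visit_times(sched, 100)
  gaps <- unlist(lapply(times, diff))
  expect_gt(length(gaps), 1e4)
  se <- sd(gaps) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 2 / 0.66), 3 * se)
})

test_that("count-mode preset reproduces the records-per-patient moments", {
  sched <- schedule_preset("paper_counts")
  set.seed(31)
  counts <- lengths(sample_visit_times(sched, 2e4))
  # weights (2: .685, 3: .03, 4: .285) give mean 2.6, sd 0.9
  se_mean <- sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 2.6), 3 * se_mean)
  expect_equal(sd(counts), 0.9, tolerance = 0.02)
})

test_that("true_duration_distribution summarises ground truth", {
  tr <- data.frame(patient_id = c("a", "b", "c"), stage = 4,
                   onset_time = 0, duration = c(2, 2, 2),
                   entry_time = 0, censor_time = 10)
  d <- true_duration_distribution(tr, 4)
  expect_equal(mean_sd(d), c(mean = 2, sd = 0))

  tr2 <- data.frame(patient_id = c("a", "b"), stage = 4, onset_time = 0,
                    duration = c(1, 3), entry_time = 0, censor_time = 10)
  d2 <- true_duration_distribution(tr2, 4)
  expect_equal(mean_sd(d2)[["mean"]], 2)
  expect_equal(sd(c(1, 3)), sqrt(2))  # sample sd of the raw durations
  expect_error(true_duration_distribution(tr2, 6), "no ground-truth")
})

test_that("config YAML round-trips through read/write", {
  cfg <- cohort_config(n_patients = 12,
                       schedule = schedule_preset("paper_counts"),
                       follow_through_exit = TRUE, seed = 7)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  cfg2 <- read_cohort_config(path)
  expect_equal(cfg2, cfg, tolerance = 1e-12)
  # regenerated cohorts are identical
  expect_identical(generate_cohort(cfg), generate_cohort(cfg2))
})
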