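test_that("build_grids lays out midpoint cells and keeps exact values", {
  g <- build_grids(make_intervals(XL = 0, XR = 0, ZL = 0.5, ZR = 2),
                   delta = 0.5, t_max = 2.01)
  expect_equal(g$duration[1:4], c(0.25, 0.75, 1.25, 1.75))

  iv <- make_intervals(XL = 0, XR = 0, ZL = 2, ZR = 5)
  g1 <- build_grids(iv, delta = 1, t_max = 6)
  cells <- expand.grid(u = g1$onset, t = g1$duration)
  comp <- mapply(function(u, t) interval_compatible(iv, u, t),
                 cells$u, cells$t)
  expect_equal(sort(cells$t[comp]), c(2.5, 3.5, 4.5))
  expect_true(all(cells$u[comp] == 0))

  # degenerate exact observation: its value joins the grid, one cell
  ivd <- make_intervals(XL = 1, XR = 1, ZL = 4.13, ZR = 4.13)
  gd <- build_grids(ivd, delta = 0.5, t_max = 6)
  expect_true(any(abs(gd$duration - 3.13) < 1e-9))
  cd <- compatible <- 0
  for (u in gd$onset) for (t in gd$duration) {
    if (interval_compatible(ivd, u, t)) compatible <- compatible + 1
  }
  expect_equal(compatible, 1)
})

test_that("interval_compatible checks both windows, open on infinite ends", {
  iv <- make_intervals(XL = 0, XR = 0, ZL = 2, ZR = 5)
  expect_true(interval_compatible(iv, 0, 3))
  expect_false(interval_compatible(iv, 0, 6))
  expect_false(interval_compatible(iv, 1, 3))  # onset outside [0,0]
  iv_inf <- make_intervals(XL = 0, XR = 0, ZL = 2, ZR = Inf)
  expect_true(interval_compatible(iv_inf, 0, 100))
})

test_that("EM reduces to the empirical distribution for exact observations", {
  iv <- make_intervals(XL = 0, XR = 0, ZL = c(2, 2, 3), ZR = c(2, 2, 3))
  fit <- em_fit(iv, delta = 1, t_max = 5)
  d <- fit$duration_dist
  expect_equal(d$weights[abs(d$support - 2) < 1e-9], 2 / 3)
  expect_equal(d$weights[abs(d$support - 3) < 1e-9], 1 / 3)
  expect_equal(sum(d$weights), 1, tolerance = 1e-12)
})

test_that("indistinguishable cells share mass equally", {
  iv <- make_intervals(XL = 0, XR = 0, ZL = 1, ZR = 2)
  fit <- em_fit(iv, delta = 0.5, t_max = 2)
  d <- fit$duration_dist
  expect_equal(d$weights[abs(d$support - 1.25) < 1e-9], 0.5)
  expect_equal(d$weights[abs(d$support - 1.75) < 1e-9], 0.5)
  # symmetric likelihood: constant across iterations
  expect_lt(diff(range(fit$loglik_trace)), 1e-12)
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  cfg <- recovery_config(stage = 4, n = 300, seed = 2)
  sim <- generate_cohort(cfg)
  ext <- extract_all(filter_repeated(sim$visits), 4, "gds")
  fit <- em_fit(ext$intervals)
  expect_true(all(diff(fit$loglik_trace) >= -1e-9))
  expect_true(fit$converged)
})

test_that("mean_sd matches closed forms", {
  expect_equal(mean_sd(discrete_dist(2, 1)), c(mean = 2, sd = 0))
  expect_equal(mean_sd(discrete_dist(1:3, rep(1 / 3, 3))),
               c(mean = 2, sd = sqrt(2 / 3)))
  expect_equal(mean_sd(discrete_dist(2:3, c(2 / 3, 1 / 3))),
               c(mean = 7 / 3, sd = sqrt(2) / 3))
})

test_that("dist_cdf is a right-continuous step function reaching 1", {
  pm <- dist_cdf(discrete_dist(2, 1))
  expect_equal(cdf_at(pm, c(1.99, 2, 2.5)), c(0, 1, 1))
  u <- dist_cdf(discrete_dist(1:2, c(0.5, 0.5)))
  expect_equal(cdf_at(u, c(0.9, 1, 1.5, 2)), c(0, 0.5, 0.5, 1))
  set.seed(4)
  w <- runif(5); w <- w / sum(w)
  d <- discrete_dist(sort(runif(5)), w)
  expect_equal(cdf_at(dist_cdf(d), max(d$support)), 1)
})

test_that("counting_cdf produces lower/upper bounds and spread", {
  iv <- make_intervals(XL = 0, XR = 0, ZL = 2, ZR = 5)  # T in [2,5]
  cc <- counting_cdf(iv, grid = c(1, 4, 6))
  expect_equal(cdf_at(cc$lower, 4), 0)
  expect_equal(cdf_at(cc$upper, 4), 1)
  expect_equal(cc$spread$values[2], 2 / 3)

  # all exact: three estimates collapse onto the empirical CDF
  ive <- make_intervals(XL = 0, XR = 0, ZL = c(1, 2, 3), ZR = c(1, 2, 3))
  cce <- counting_cdf(ive, grid = c(0.5, 1, 1.7, 2, 3))
  emp <- c(0, 1, 1, 2, 3) / 3
  expect_equal(cce$lower$values, emp)
  expect_equal(cce$upper$values, emp)
  expect_equal(cce$spread$values, emp)

  iv2 <- make_intervals(XL = 0, XR = 0, ZL = c(1, 3), ZR = c(1, 3))
  cc2 <- counting_cdf(iv2, grid = 2)
  expect_equal(cc2$spread$values, 0.5)
})

test_that("product-limit oracle matches hand-computed survival", {
  # exact durations, no censoring: empirical CDF
  iv <- make_intervals(XL = 0, XR = 0, ZL = 1:3, ZR = 1:3)
  pl <- product_limit_cdf(iv)
  expect_equal(cdf_at(pl, c(1, 2, 3)), c(1, 2, 3) / 3)

  # durations {1, 2+}: survival at 1.5 is 1/2, single jump at 1
  iv2 <- make_intervals(XL = 0, XR = 0, ZL = c(1, 2), ZR = c(1, Inf))
  pl2 <- product_limit_cdf(iv2)
  expect_equal(cdf_at(pl2, 1.5), 0.5)
  expect_equal(cdf_at(pl2, 0.99), 0)
  expect_equal(cdf_at(pl2, 10), 0.5)  # no further jumps

  # all censored: CDF identically zero
  iv3 <- make_intervals(XL = 0, XR = 0, ZL = c(1, 2), ZR = c(Inf, Inf))
  pl3 <- product_limit_cdf(iv3)
  expect_true(all(pl3$values == 0))

  expect_error(product_limit_cdf(make_intervals(0, 1, 2, 3)),
               "exactly observed onsets")
})

test_that("EM agrees with the product-limit oracle under right censoring", {
  set.seed(7)
  n <- 30
  dur <- rexp(n, 1 / 2)
  cens <- runif(n) < 0.3
  cens[which.max(dur)] <- FALSE  # pin the upper tail with an event
  iv <- make_intervals(XL = 0, XR = 0, ZL = dur,
                       ZR = ifelse(cens, Inf, dur))
  fit <- em_fit(iv, delta = 0.25, t_max = 25, tol = 0, max_iter = 5000)
  km <- product_limit_cdf(iv)
  ev <- sort(unique(dur[!cens]))
  gap <- cdf_at(dist_cdf(fit$duration_dist), ev + 1e-9) -
    cdf_at(km, ev + 1e-9)
  expect_lt(max(abs(gap)), 1e-6)
})

test_that("EM CDF is sandwiched by the counting bounds", {
  cfg <- recovery_config(stage = 4, n = 500, seed = 9)
  sim <- generate_cohort(cfg)
  ext <- extract_all(filter_repeated(sim$visits), 4, "gds")
  iv <- ext$intervals[is.finite(ext$intervals$ZR), ]
  fit <- em_fit(iv)
  grid <- fit$duration_dist$support
  em <- cumsum(fit$duration_dist$weights)
  cc <- counting_cdf(iv, grid = grid)
  expect_true(all(em >= cc$lower$values - 1e-9))
  expect_true(all(em <= cc$upper$values + 1e-9))
})

test_that("EM and counting-spread agree closely under fine observation", {
  # the two constructions estimate the same CDF; their sup-norm distance
  # scales with the width of the censoring windows, so the quantitative
  # agreement check runs on a schedule finer than the stage durations
  cfg <- cohort_config(
    n_patients = 500, entry_mode = "at_onset",
    entry_stage_distribution = c("4" = 1),
    duration_model = stage_duration_model(),
    schedule = visit_schedule_model("process", 0.5, 1, jitter_sd = 0,
                                    max_follow_up = 14),
    follow_through_exit = TRUE, scale_agreement_prob = 1, seed = 9)
  sim <- generate_cohort(cfg)
  ext <- extract_all(filter_repeated(sim$visits), 4, "gds")
  iv <- ext$intervals[is.finite(ext$intervals$ZR), ]
  fit <- em_fit(iv)
  em <- cumsum(fit$duration_dist$weights)
  cc <- counting_cdf(iv, grid = fit$duration_dist$support)
  expect_lt(max(abs(em - cc$spread$values)), 0.1)
})

test_that("halving the grid step moves the estimated mean by less than delta", {
  cfg <- recovery_config(stage = 4, n = 400, seed = 13)
  sim <- generate_cohort(cfg)
  ext <- extract_all(filter_repeated(sim$visits), 4, "gds")
  m1 <- mean_sd(em_fit(ext$intervals, delta = 0.5)$duration_dist)[["mean"]]
  m2 <- mean_sd(em_fit(ext$intervals, delta = 0.25)$duration_dist)[["mean"]]
  expect_lt(abs(m1 - m2), 0.5)
})

test_that("EM recovers simulated duration distributions", {
  # exponential truth
  cfg <- recovery_config(stage = 4, n = 2000, seed = 101)
  sim <- generate_cohort(cfg)
  ext <- extract_all(filter_repeated(sim$visits), 4, "gds")
  ms <- mean_sd(em_fit(ext$intervals)$duration_dist)
  tru <- sim$truth$duration[sim$truth$stage == 4]
  expect_equal(ms[["mean"]], mean(tru), tolerance = 0.10)
  expect_equal(ms[["sd"]], sd(tru), tolerance = 0.25)

  # gamma truth with cv 0.5
  cfg2 <- recovery_config(stage = 4, n = 2000, seed = 103,
                          family = "gamma", cv = 0.5)
  sim2 <- generate_cohort(cfg2)
  ext2 <- extract_all(filter_repeated(sim2$visits), 4, "gds")
  ms2 <- mean_sd(em_fit(ext2$intervals)$duration_dist)
  tru2 <- sim2$truth$duration[sim2$truth$stage == 4]
  expect_equal(ms2[["mean"]], mean(tru2), tolerance = 0.10)
  expect_equal(ms2[["sd"]], sd(tru2), tolerance = 0.25)
})

test_that("mass pushed past t_max is surfaced as tail_mass", {
  # wide-open right ends force mass into the last cell
  iv <- make_intervals(XL = 0, XR = 0, ZL = c(0.5, 1, 4.5, 4.6, 4.7),
                       ZR = c(1, 1.5, Inf, Inf, Inf))
  fit <- em_fit(iv, delta = 0.5, t_max = 5)
  expect_gt(fit$tail_mass, 0.01)
  # no right-open patients: tail mass is zero
  iv2 <- make_intervals(XL = 0, XR = 0, ZL = c(1, 2), ZR = c(2, 3))
  expect_equal(em_fit(iv2, delta = 0.5, t_max = 5)$tail_mass, 0)
})
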