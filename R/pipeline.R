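# Orchestration: per-stage, per-scale estimation and study-level reports.

#' Estimate the duration distribution of one stage on one scale
#'
#' Composes interval extraction ([extract_all()]), grid construction and
#' the self-consistency fit ([em_fit()]) and summarises the result as
#' mean, sd and CDF. Stages 3 and 7 are refused by default: stage 3 is
#' typically too sparsely represented in referral cohorts and stage 7 has
#' no observable end without mortality data, so their estimates are
#' unreliable; set `force_stage = TRUE` to compute them anyway.
#'
#' @param visits a visit cohort.
#' @param stage stage to estimate (4-6 unless `force_stage`).
#' @param scale `"gds"` or `"fast"`.
#' @param first_visit_rule apply the first-visit-at-onset convention.
#' @param nonmonotone policy for stage reversals (see
#'   [extract_intervals()]).
#' @param delta,t_max,tol,max_iter,estimate_onset passed to [em_fit()].
#' @param force_stage allow stages 3 and 7.
#' @return an object of class `stage_duration_estimate`: list with
#'   `stage`, `scale`, `mean`, `sd`, `cdf`, `n_contributing`, `tail_mass`,
#'   `method`, `em` (the full [em_fit()] result), `exclusions`, and
#'   `failed`/`reason` when no informative patients exist.
#' @export
run_stage_analysis <- function(visits, stage, scale = c("gds", "fast"),
                               first_visit_rule = TRUE,
                               nonmonotone = c("reject", "carry_forward"),
                               delta = 0.25, t_max = 20, tol = 1e-8,
                               max_iter = 5000, estimate_onset = TRUE,
                               force_stage = FALSE) {
  scale <- match.arg(scale)
  nonmonotone <- match.arg(nonmonotone)
  if (!stage %in% 4:6 && !force_stage) {
    stop("stage ", stage, " estimation is disabled by default ",
         "(sparse records below stage 4; unobservable end of stage 7); ",
         "use force_stage = TRUE to override")
  }
  ext <- extract_all(visits, stage, scale, first_visit_rule, nonmonotone)
  failed <- function(reason) {
    structure(list(stage = stage, scale = scale, mean = NA_real_,
                   sd = NA_real_, cdf = NULL, n_contributing = 0L,
                   tail_mass = NA_real_, method = "em",
                   em = NULL, exclusions = ext$exclusions,
                   failed = TRUE, reason = reason),
              class = "stage_duration_estimate")
  }
  if (nrow(ext$intervals) == 0) return(failed("no informative patients"))
  fit <- tryCatch(
    em_fit(ext$intervals, delta = delta, t_max = t_max, tol = tol,
           max_iter = max_iter, estimate_onset = estimate_onset),
    error = function(e) e)
  if (inherits(fit, "error")) return(failed(conditionMessage(fit)))
  ms <- mean_sd(fit$duration_dist)
  structure(list(stage = stage, scale = scale,
                 mean = ms[["mean"]], sd = ms[["sd"]],
                 cdf = dist_cdf(fit$duration_dist, method = "em"),
                 n_contributing = fit$n_used,
                 tail_mass = fit$tail_mass, method = "em", em = fit,
                 exclusions = ext$exclusions, failed = FALSE,
                 reason = NULL),
            class = "stage_duration_estimate")
}

#' @export
print.stage_duration_estimate <- function(x, ...) {
  cat(sprintf("Stage %d (%s): ", x$stage, toupper(x$scale)))
  if (isTRUE(x$failed)) {
    cat("estimation failed -", x$reason, "\n")
  } else {
    cat(sprintf("mean %.2f y, sd %.2f y (n = %d%s)\n", x$mean, x$sd,
                x$n_contributing,
                if (x$tail_mass > 0.01) "; mean/sd are lower bounds" else ""))
  }
  invisible(x)
}

#' Full study report: stages 4-6 on both scales
#'
#' Runs [run_stage_analysis()] for each requested stage on each scale and
#' collects the estimates with cohort statistics, per-scale transition
#' tables, the published reference mean durations (2.0 / 1.5 / 2.5 years
#' for stages 4 / 5 / 6) for comparison, and a provenance block. Failed
#' estimates are retained with their reason rather than aborting the
#' report.
#'
#' @param visits a visit cohort (single-visit patients are dropped).
#' @param stages stages to estimate (default 4:6).
#' @param scales scales to estimate (default both).
#' @param ... passed to [run_stage_analysis()].
#' @return an object of class `study_report`: list with `estimates`
#'   (named `stage<k>_<scale>`), `cohort_stats`, `transition_tables`,
#'   `reference_means`, `provenance`.
#' @export
full_report <- function(visits, stages = 4:6, scales = c("gds", "fast"),
                        ...) {
  validate_visits(visits)
  rep_cohort <- filter_repeated(visits)
  if (nrow(rep_cohort) == 0) stop("no patients with repeated records")
  estimates <- list()
  for (sc in scales) {
    for (st in stages) {
      estimates[[sprintf("stage%d_%s", st, sc)]] <-
        run_stage_analysis(rep_cohort, st, sc, ...)
    }
  }
  opts <- list(...)
  structure(list(
    estimates = estimates,
    cohort_stats = cohort_statistics(rep_cohort),
    transition_tables = setNames(
      lapply(scales, function(sc) transition_table(rep_cohort, sc)), scales),
    reference_means = c("4" = 2.0, "5" = 1.5, "6" = 2.5),
    provenance = list(
      package_version = as.character(packageVersion("stagedur")),
      n_patients = length(unique(rep_cohort$patient_id)),
      delta = opts$delta %||% 0.25,
      t_max = opts$t_max %||% 20,
      tol = opts$tol %||% 1e-8,
      first_visit_rule = opts$first_visit_rule %||% TRUE,
      options_hash = config_hash(opts)
    )
  ), class = "study_report")
}

config_hash <- function(x) {
  # cheap stable fingerprint of the option list (no external digest dep)
  if (length(x) > 0 && !is.null(names(x))) x <- x[order(names(x))]
  s <- paste(deparse(x), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

#' @export
print.study_report <- function(x, ...) {
  cat("Stage-duration study report\n")
  cat(sprintf("  patients with repeated records: %d\n",
              x$provenance$n_patients))
  for (e in x$estimates) print(e)
  cat("  reference means (stage 4/5/6):",
      paste(x$reference_means, collapse = " / "), "years\n")
  invisible(x)
}

#' Write a study report to disk
#'
#' Writes `report.json` (the full report), one `estimate_<stage>_<scale>.csv`
#' per estimate (`t,f,F` rows preceded by `# key=value` header lines with
#' mean, sd, n_used, tail_mass, n_iter, converged), `transition_<scale>.csv`
#' and `cohort_stats.csv`.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (name in names(report$estimates)) {
    e <- report$estimates[[name]]
    if (isTRUE(e$failed)) next
    write_estimate(e, file.path(dir, paste0("estimate_", name, ".csv")))
  }
  for (sc in names(report$transition_tables)) {
    tt <- report$transition_tables[[sc]]
    df <- as.data.frame.matrix(unclass(tt))
    df <- cbind(first_stage = rownames(df), df)
    write.csv(df, file.path(dir, paste0("transition_", sc, ".csv")),
              row.names = FALSE)
  }
  write.csv(as.data.frame(report$cohort_stats),
            file.path(dir, "cohort_stats.csv"), row.names = FALSE)
  json <- list(
    estimates = lapply(report$estimates, function(e) {
      if (isTRUE(e$failed)) {
        list(stage = e$stage, scale = e$scale, failed = TRUE,
             reason = e$reason)
      } else {
        list(stage = e$stage, scale = e$scale, mean = e$mean, sd = e$sd,
             n_contributing = e$n_contributing, tail_mass = e$tail_mass,
             cdf = list(t = e$cdf$grid, F = e$cdf$values))
      }
    }),
    reference_means = as.list(report$reference_means),
    provenance = report$provenance
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

write_estimate <- function(estimate, path) {
  fit <- estimate$em
  hdr <- c(
    sprintf("# stage=%d", estimate$stage),
    sprintf("# scale=%s", estimate$scale),
    sprintf("# mean=%.10g", estimate$mean),
    sprintf("# sd=%.10g", estimate$sd),
    sprintf("# n_used=%d", estimate$n_contributing),
    sprintf("# tail_mass=%.10g", estimate$tail_mass),
    sprintf("# n_iter=%d", fit$n_iter),
    sprintf("# converged=%s", tolower(as.character(fit$converged)))
  )
  body <- data.frame(t = fit$duration_dist$support,
                     f = fit$duration_dist$weights,
                     F = cumsum(fit$duration_dist$weights))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines("t,f,F", con)
  writeLines(sprintf("%.10g,%.10g,%.10g", body$t, body$f, body$F), con)
  invisible(path)
}

#' Early/late cohort comparison
#'
#' Splits the cohort at a calendar cut ([split_by_date()]), runs
#' [full_report()] on each half, and reports per-stage/scale differences
#' in estimated mean duration, both raw and scaled by the pooled sd, with
#' a large-sample z score from the approximate standard error
#' `sqrt(sd_e^2/n_e + sd_l^2/n_l)`. Used to check whether progression
#' changed over the study period.
#'
#' @param visits a visit cohort.
#' @param cut_time calendar split point (decimal years).
#' @param ... passed to [full_report()].
#' @return list with `early`, `late` (study reports) and `differences`
#'   (data frame).
#' @export
early_late_comparison <- function(visits, cut_time, ...) {
  halves <- split_by_date(visits, cut_time)
  for (h in names(halves)) {
    if (nrow(filter_repeated(halves[[h]])) == 0) {
      stop("the '", h, "' half at cut ", cut_time,
           " has no patients with repeated records")
    }
  }
  early <- full_report(halves$early, ...)
  late <- full_report(halves$late, ...)
  rows <- lapply(names(early$estimates), function(name) {
    e <- early$estimates[[name]]; l <- late$estimates[[name]]
    if (isTRUE(e$failed) || isTRUE(l$failed)) {
      return(data.frame(estimate = name, mean_early = NA, mean_late = NA,
                        diff = NA, pooled_sd = NA, scaled_diff = NA,
                        z = NA))
    }
    pooled <- sqrt(((e$n_contributing - 1) * e$sd^2 +
                      (l$n_contributing - 1) * l$sd^2) /
                     max(1, e$n_contributing + l$n_contributing - 2))
    se <- sqrt(e$sd^2 / e$n_contributing + l$sd^2 / l$n_contributing)
    d <- l$mean - e$mean
    data.frame(estimate = name, mean_early = e$mean, mean_late = l$mean,
               diff = d, pooled_sd = pooled,
               scaled_diff = if (pooled > 0) d / pooled else NA_real_,
               z = if (se > 0) d / se else NA_real_)
  })
  list(early = early, late = late, differences = do.call(rbind, rows))
}

#' Per-patient progression rate
#'
#' `"stages"` (default): observed stage change divided by observed time,
#' `(last stage - first stage) / (last time - first time)` in stages per
#' year. `"duration_weighted"`: the stages traversed are first converted
#' to expected years of progression using estimated mean stage durations,
#' giving a rate in expected-years per year.
#'
#' @param visits a visit cohort.
#' @param scale `"gds"` or `"fast"`.
#' @param method rate definition (see above).
#' @param mean_durations named vector of mean stage durations (years) for
#'   the `duration_weighted` method, e.g. `c("4" = 2, "5" = 1.5, "6" = 2.5)`.
#' @return data frame `patient_id, rate` (patients with zero follow-up
#'   are skipped).
#' @export
progression_rate <- function(visits, scale = c("gds", "fast"),
                             method = c("stages", "duration_weighted"),
                             mean_durations = NULL) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  validate_visits(visits)
  col <- stage_column(scale)
  by_pat <- split(seq_len(nrow(visits)), visits$patient_id)
  rows <- lapply(names(by_pat), function(id) {
    i <- by_pat[[id]]
    tt <- visits$visit_time[i]; s <- visits[[col]][i]
    o <- order(tt)
    tt <- tt[o]; s <- s[o]
    dt <- tt[length(tt)] - tt[1]
    if (length(tt) < 2 || dt <= 0) return(NULL)
    if (method == "stages") {
      rate <- (s[length(s)] - s[1]) / dt
    } else {
      if (is.null(mean_durations)) {
        stop("duration_weighted rate requires `mean_durations`")
      }
      span <- 0
      s1 <- s[1]; s2 <- s[length(s)]
      if (s2 > s1) {
        for (st in s1:(s2 - 1)) {
          m <- mean_durations[[as.character(st)]]
          if (is.null(m) || is.na(m)) return(NULL)
          span <- span + m
        }
      }
      rate <- span / dt
    }
    data.frame(patient_id = id, rate = rate, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(patient_id = character(),
                                      rate = numeric())
  rownames(out) <- NULL
  out
}

#' Back-calculated age at disease onset
#'
#' Estimates each patient's age at the onset of stage 4 (taken as the
#' start of the disease proper) by subtracting the estimated mean
#' durations of the stages completed before the first visit from the age
#' at first visit. Under the first-visit-at-onset convention the stage
#' occupied at the first visit contributes nothing, so a patient first
#' seen at stage 4 has onset age equal to their age at first visit; first
#' seen at stage 6, onset age = age - (mean4 + mean5). Patients first
#' seen below stage 4, with missing age, or with a missing required mean
#' get `NA`.
#'
#' @param visits a visit cohort.
#' @param mean_durations named mean durations (years) for stages
#'   `"4"`, `"5"`, `"6"` as needed.
#' @param scale `"gds"` or `"fast"`.
#' @return data frame `patient_id, first_stage, age_at_first_visit,
#'   onset_age`.
#' @export
back_calculate_onset_age <- function(visits, mean_durations,
                                     scale = c("gds", "fast")) {
  scale <- match.arg(scale)
  validate_visits(visits)
  col <- stage_column(scale)
  by_pat <- split(seq_len(nrow(visits)), visits$patient_id)
  rows <- lapply(names(by_pat), function(id) {
    i <- by_pat[[id]]
    o <- order(visits$visit_time[i])
    first <- i[o][1]
    s <- visits[[col]][first]
    age <- visits$age_at_visit[first]
    onset <- NA_real_
    if (!is.na(age) && s >= 4 && s <= 7) {
      need <- if (s > 4) as.character(4:(s - 1)) else character(0)
      ms <- vapply(need, function(k) {
        v <- mean_durations[[k]]
        if (is.null(v)) NA_real_ else v
      }, numeric(1))
      onset <- if (anyNA(ms)) NA_real_ else age - sum(ms)
    }
    data.frame(patient_id = id, first_stage = s, age_at_first_visit = age,
               onset_age = onset, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Correlation of progression rate with demographic factors
#'
#' Computes, across patients, the product-moment correlation of the
#' progression rate with age at baseline, years of education, and
#' back-calculated onset age, and the point-biserial correlation with sex
#' (female = 1). Significance is descriptive only: a two-sided p-value
#' from the large-sample normal approximation on the Fisher-transformed
#' coefficient; no multiple-testing adjustment is applied and the number
#' of tests is reported alongside.
#'
#' @param visits a visit cohort.
#' @param mean_durations named mean stage durations used for
#'   back-calculating onset age; when `NULL`, the onset-age row is
#'   omitted.
#' @param scale `"gds"` or `"fast"`.
#' @param method rate definition for [progression_rate()].
#' @return data frame `variable, r, n, p` with attribute `n_tests`;
#'   zero-variance variables yield `NA` coefficients.
#' @export
demographic_correlations <- function(visits, mean_durations = NULL,
                                     scale = c("gds", "fast"),
                                     method = "stages") {
  scale <- match.arg(scale)
  validate_visits(visits)
  rate <- progression_rate(visits, scale, method,
                           mean_durations = mean_durations)
  by_pat <- split(seq_len(nrow(visits)), visits$patient_id)
  base <- lapply(names(by_pat), function(id) {
    i <- by_pat[[id]]
    first <- i[order(visits$visit_time[i])][1]
    data.frame(patient_id = id,
               age = visits$age_at_visit[first],
               education = visits$education_years[first],
               female = switch(visits$sex[first], F = 1, M = 0, NA_real_),
               stringsAsFactors = FALSE)
  })
  base <- do.call(rbind, base)
  df <- merge(rate, base, by = "patient_id")
  if (!is.null(mean_durations)) {
    oa <- back_calculate_onset_age(visits, mean_durations, scale)
    df <- merge(df, oa[c("patient_id", "onset_age")], by = "patient_id")
  }
  vars <- c(age = "age", education = "education", sex = "female")
  if (!is.null(mean_durations)) vars <- c(vars, onset_age = "onset_age")
  rows <- lapply(names(vars), function(v) {
    x <- df[[vars[[v]]]]
    ok <- !is.na(x) & !is.na(df$rate)
    n <- sum(ok)
    r <- if (n >= 3 && sd(x[ok]) > 0 && sd(df$rate[ok]) > 0) {
      cor(df$rate[ok], x[ok])
    } else NA_real_
    p <- if (!is.na(r) && abs(r) < 1 && n > 3) {
      z <- atanh(r) * sqrt(n - 3)
      2 * pnorm(-abs(z))
    } else NA_real_
    data.frame(variable = v, r = r, n = n, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_tests") <- nrow(out)
  out
}
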