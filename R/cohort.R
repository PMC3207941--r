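#' @importFrom stats sd rexp rgamma rlnorm rweibull rnorm runif rbinom
#'   uniroot cor pnorm stepfun setNames
#' @importFrom utils read.csv write.csv head packageVersion
NULL

VISIT_COLUMNS <- c("patient_id", "visit_time", "gds_stage", "fast_stage",
                   "sex", "age_at_visit", "education_years")

`%||%` <- function(a, b) if (is.null(a)) b else a

# decimal-year conversion for an ISO-8601 date string
iso_to_decimal_year <- function(x) {
  d <- as.Date(x, format = "%Y-%m-%d")
  year <- as.integer(format(d, "%Y"))
  yday <- as.integer(format(d, "%j"))
  year + (yday - 1) / 365.25
}

#' Read a visit-record cohort from CSV
#'
#' Reads a longitudinal visit table with one row per clinic visit and
#' returns it grouped by patient and sorted by visit time. The expected
#' header is `patient_id,visit_time,gds_stage,fast_stage,sex,age_at_visit,
#' education_years`. `visit_time` may be decimal years (e.g. `1991.54`) or
#' an ISO-8601 date, which is converted to decimal years on read
#' (year + (day-of-year - 1)/365.25). `sex` is one of `F`, `M`, `U`
#' (empty cells become `U`); missing numeric demographics are empty cells.
#'
#' @param path path to a CSV file.
#' @return A `data.frame` of visit records (class `visit_cohort`), grouped
#'   by `patient_id` in order of first appearance and sorted by
#'   `visit_time` within patient.
#' @details Rows with stage values outside 1..7 (or unparsable) raise a
#'   validation error citing the offending data rows. Duplicate
#'   `(patient_id, visit_time)` pairs raise an error naming the patient.
#' @seealso [write_visits()], [filter_repeated()], [cohort_statistics()]
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  missing_cols <- setdiff(VISIT_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  n <- nrow(raw)
  if (n == 0) return(as_visit_cohort(empty_visits()))

  parse_stage <- function(x, col) {
    v <- suppressWarnings(as.integer(x))
    bad <- which(is.na(v) | v < 1 | v > 7)
    if (length(bad) > 0) {
      stop(sprintf("invalid %s value(s) in data row(s) %s (must be 1-7)",
                   col, paste(head(bad, 5), collapse = ", ")))
    }
    v
  }
  time <- suppressWarnings(as.numeric(raw$visit_time))
  isoish <- is.na(time) & grepl("^\\d{4}-\\d{2}-\\d{2}$", raw$visit_time)
  if (any(isoish)) time[isoish] <- iso_to_decimal_year(raw$visit_time[isoish])
  if (anyNA(time)) {
    stop("unparsable visit_time in data row(s) ",
         paste(head(which(is.na(time)), 5), collapse = ", "))
  }
  gds <- parse_stage(raw$gds_stage, "gds_stage")
  fast <- parse_stage(raw$fast_stage, "fast_stage")
  sex <- toupper(raw$sex)
  sex[sex == "" | is.na(sex)] <- "U"
  bad_sex <- which(!sex %in% c("F", "M", "U"))
  if (length(bad_sex) > 0) {
    stop("invalid sex value in data row(s) ",
         paste(head(bad_sex, 5), collapse = ", "), " (must be F, M or U)")
  }
  num_or_na <- function(x, col) {
    v <- suppressWarnings(as.numeric(x))
    v[x == ""] <- NA_real_
    bad <- which(!is.na(x) & x != "" & is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("unparsable %s in data row(s) %s", col,
                   paste(head(bad, 5), collapse = ", ")))
    }
    v
  }
  visits <- data.frame(
    patient_id = raw$patient_id,
    visit_time = time,
    gds_stage = gds,
    fast_stage = fast,
    sex = sex,
    age_at_visit = num_or_na(raw$age_at_visit, "age_at_visit"),
    education_years = num_or_na(raw$education_years, "education_years"),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(visits[c("patient_id", "visit_time")])
  if (any(dup)) {
    stop("duplicate (patient_id, visit_time) for patient ",
         visits$patient_id[which(dup)[1]])
  }
  as_visit_cohort(visits)
}

empty_visits <- function() {
  data.frame(patient_id = character(), visit_time = numeric(),
             gds_stage = integer(), fast_stage = integer(),
             sex = character(), age_at_visit = numeric(),
             education_years = numeric(), stringsAsFactors = FALSE)
}

as_visit_cohort <- function(visits) {
  ord <- order(match(visits$patient_id, unique(visits$patient_id)),
               visits$visit_time)
  visits <- visits[ord, , drop = FALSE]
  rownames(visits) <- NULL
  class(visits) <- c("visit_cohort", "data.frame")
  visits
}

validate_visits <- function(visits) {
  stopifnot(is.data.frame(visits))
  missing_cols <- setdiff(VISIT_COLUMNS, names(visits))
  if (length(missing_cols) > 0) {
    stop("not a visit table; missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (any(!visits$gds_stage %in% 1:7) || any(!visits$fast_stage %in% 1:7)) {
    stop("stage values must lie in 1..7")
  }
  invisible(visits)
}

#' Write a visit-record cohort to CSV
#'
#' Inverse of [read_visits()]: `read_visits(write_visits(cohort, path))`
#' reproduces the cohort field for field. Missing demographics become
#' empty cells.
#'
#' @param visits a visit cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  validate_visits(visits)
  out <- as.data.frame(visits)[, VISIT_COLUMNS, drop = FALSE]
  out$visit_time <- format(out$visit_time, digits = 15, trim = TRUE,
                           scientific = FALSE)
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Keep only patients seen more than once
#'
#' Repeated records are the informative subset for duration estimation:
#' a single visit bounds no stage transition.
#'
#' @param visits a visit cohort.
#' @return the sub-cohort of patients with at least two visits, patient
#'   order preserved.
#' @export
filter_repeated <- function(visits) {
  validate_visits(visits)
  counts <- table(visits$patient_id)
  keep <- names(counts)[counts >= 2]
  out <- visits[visits$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(visits)
  out
}

#' Cohort descriptive statistics
#'
#' Summaries of cohort size, visit scheduling and demographics: number of
#' patients and of patients with repeated records, records per patient,
#' inter-visit time, follow-up (first-to-last-visit) time, age at first
#' visit, fraction female, and years of education. All spreads are sample
#' standard deviations (n-1 denominator). Missing demographics are
#' excluded pairwise.
#'
#' @param visits a visit cohort (nonempty).
#' @param inter_visit_mode `"pooled"` (default) pools all consecutive-visit
#'   gaps across patients; `"per_patient"` first averages gaps within each
#'   patient, then summarises those per-patient means.
#' @return an object of class `cohort_stats`: a list with components
#'   `n_patients`, `n_repeated`, `records_per_patient`, `inter_visit_time`,
#'   `follow_up_time`, `age_at_first_visit`, `fraction_female`,
#'   `education`; each `(mean, sd)` pair is a named numeric vector.
#'   Quantities undefined for the cohort (e.g. inter-visit times when no
#'   patient has two visits) are `NaN`.
#' @export
cohort_statistics <- function(visits,
                              inter_visit_mode = c("pooled", "per_patient")) {
  validate_visits(visits)
  inter_visit_mode <- match.arg(inter_visit_mode)
  if (nrow(visits) == 0) stop("empty cohort")
  by_pat <- split(seq_len(nrow(visits)), visits$patient_id)
  nrec <- vapply(by_pat, length, integer(1))
  gaps_by_pat <- lapply(by_pat, function(i) diff(visits$visit_time[i]))
  gaps <- unlist(gaps_by_pat, use.names = FALSE)
  if (inter_visit_mode == "per_patient") {
    gaps <- vapply(Filter(function(g) length(g) > 0, gaps_by_pat),
                   mean, numeric(1))
  }
  follow <- vapply(by_pat, function(i) {
    t <- visits$visit_time[i]
    if (length(t) >= 2) max(t) - min(t) else NA_real_
  }, numeric(1))
  follow <- follow[!is.na(follow)]
  first_row <- vapply(by_pat, function(i) i[1], integer(1))
  age1 <- visits$age_at_visit[first_row]
  edu <- visits$education_years[first_row]
  sex <- visits$sex[first_row]
  mean_sd_vec <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(c(mean = NaN, sd = NaN))
    c(mean = mean(x), sd = if (length(x) >= 2) sd(x) else NaN)
  }
  structure(list(
    n_patients = length(by_pat),
    n_repeated = sum(nrec >= 2),
    records_per_patient = mean_sd_vec(nrec),
    inter_visit_time = mean_sd_vec(gaps),
    follow_up_time = mean_sd_vec(follow),
    age_at_first_visit = mean_sd_vec(age1),
    fraction_female = if (any(sex != "U")) mean(sex[sex != "U"] == "F") else NaN,
    education = mean_sd_vec(edu),
    inter_visit_mode = inter_visit_mode
  ), class = "cohort_stats")
}

#' @export
print.cohort_stats <- function(x, ...) {
  fmt <- function(v) sprintf("%.2f +/- %.2f", v[["mean"]], v[["sd"]])
  cat("Cohort statistics\n")
  cat(sprintf("  patients: %d (%d with repeated records)\n",
              x$n_patients, x$n_repeated))
  cat("  records per patient:", fmt(x$records_per_patient), "\n")
  cat(sprintf("  inter-visit time (%s): %s years\n",
              x$inter_visit_mode, fmt(x$inter_visit_time)))
  cat("  follow-up time:", fmt(x$follow_up_time), "years\n")
  cat("  age at first visit:", fmt(x$age_at_first_visit), "years\n")
  cat(sprintf("  fraction female: %.2f\n", x$fraction_female))
  cat("  education:", fmt(x$education), "years\n")
  invisible(x)
}

#' @export
as.data.frame.cohort_stats <- function(x, ...) {
  rows <- list(
    c("n_patients", x$n_patients, NA),
    c("n_repeated", x$n_repeated, NA),
    c("records_per_patient", x$records_per_patient[["mean"]],
      x$records_per_patient[["sd"]]),
    c("inter_visit_time", x$inter_visit_time[["mean"]],
      x$inter_visit_time[["sd"]]),
    c("follow_up_time", x$follow_up_time[["mean"]], x$follow_up_time[["sd"]]),
    c("age_at_first_visit", x$age_at_first_visit[["mean"]],
      x$age_at_first_visit[["sd"]]),
    c("fraction_female", x$fraction_female, NA),
    c("education", x$education[["mean"]], x$education[["sd"]])
  )
  out <- data.frame(statistic = vapply(rows, `[[`, character(1), 1),
                    mean = as.numeric(vapply(rows, `[[`, character(1), 2)),
                    sd = as.numeric(vapply(rows, `[[`, character(1), 3)),
                    stringsAsFactors = FALSE)
  out
}

stage_column <- function(scale) {
  scale <- match.arg(tolower(scale), c("gds", "fast"))
  paste0(scale, "_stage")
}

#' First-visit / last-visit stage transition table
#'
#' Counts patients by their stage at the first and at the last recorded
#' visit on the chosen scale, for stages 3-7. Patients whose first or last
#' stage falls outside 3..7 are counted in an `overflow` attribute rather
#' than the table body.
#'
#' @param visits a visit cohort (normally after [filter_repeated()]).
#' @param scale `"gds"` or `"fast"`.
#' @return a 5 x 5 integer matrix of class `transition_table`, rows the
#'   first-visit stage, columns the last-visit stage, with attributes
#'   `scale` and `overflow`.
#' @export
transition_table <- function(visits, scale = c("gds", "fast")) {
  validate_visits(visits)
  scale <- match.arg(scale)
  col <- stage_column(scale)
  by_pat <- split(visits[[col]], visits$patient_id)
  # split() reorders by id; order is immaterial for counts
  first <- vapply(by_pat, function(s) s[1], numeric(1))
  last <- vapply(by_pat, function(s) s[length(s)], numeric(1))
  tab <- matrix(0L, 5, 5, dimnames = list(first = 3:7, last = 3:7))
  inside <- first >= 3 & first <= 7 & last >= 3 & last <= 7
  for (k in which(inside)) {
    i <- first[k] - 2L; j <- last[k] - 2L
    tab[i, j] <- tab[i, j] + 1L
  }
  structure(tab, scale = scale, overflow = sum(!inside),
            class = c("transition_table", "matrix"))
}

#' @export
print.transition_table <- function(x, ...) {
  cat(sprintf("Transition table (%s): first-visit stage (rows) x last-visit stage (cols)\n",
              toupper(attr(x, "scale"))))
  print(unclass(x)[, , drop = FALSE])
  if (attr(x, "overflow") > 0) {
    cat("  patients outside stages 3-7 (overflow):", attr(x, "overflow"), "\n")
  }
  invisible(x)
}

#' Split a cohort by calendar date of first visit
#'
#' Partitions patients into an "early" and a "late" sub-cohort by whether
#' their first visit falls before the cut time. Used for period-effect
#' robustness checks.
#'
#' @param visits a visit cohort.
#' @param cut_time calendar time (decimal years); first visit `< cut_time`
#'   goes to `early`, `>= cut_time` to `late`.
#' @return `list(early = , late = )`, a disjoint exhaustive partition.
#' @export
split_by_date <- function(visits, cut_time) {
  validate_visits(visits)
  by_pat <- split(visits$visit_time, visits$patient_id)
  first <- vapply(by_pat, min, numeric(1))
  early_ids <- names(first)[first < cut_time]
  early <- visits[visits$patient_id %in% early_ids, , drop = FALSE]
  late <- visits[!visits$patient_id %in% early_ids, , drop = FALSE]
  rownames(early) <- rownames(late) <- NULL
  class(early) <- class(late) <- class(visits)
  list(early = early, late = late)
}
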