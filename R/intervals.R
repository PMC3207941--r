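# Doubly interval-censored representation of a stage.
#
# For stage i and one patient, the visit sequence bounds the stage onset
# by [XL, XR] (latest visit below stage i, earliest visit at stage >= i)
# and the stage end by [ZL, ZR] (latest visit at stage <= i, earliest
# visit above stage i; ZR = Inf when no such visit exists). Under the
# first-visit rule, a patient whose first visit is already at stage i has
# a degenerate onset at that visit time. Times are shifted so t = 0 at
# each patient's first visit: only durations matter downstream.

interval_columns <- c("patient_id", "stage", "scale",
                      "XL", "XR", "ZL", "ZR")

#' Extract the onset/end censoring intervals of a stage for one patient
#'
#' Applies the interval-construction rules to a single patient history:
#' the onset window of stage `stage` is bounded by the latest visit at a
#' lower stage and the earliest visit at `stage` or higher; the end window
#' by the latest visit at `stage` or lower and the earliest visit at a
#' higher stage (right bound `Inf` when the patient is never seen past the
#' stage). With `first_visit_rule = TRUE`, a patient first seen at exactly
#' `stage` has onset fixed at the first visit time (the assessment that
#' triggers the first referral is taken to coincide with stage onset).
#'
#' @param history visit rows for a single patient.
#' @param stage stage of interest, 3-7.
#' @param scale `"gds"` or `"fast"`.
#' @param first_visit_rule apply the first-visit-at-onset convention.
#' @param nonmonotone how to treat apparent stage reversals:
#'   `"reject"` (default) excludes the patient, `"carry_forward"` replaces
#'   the sequence by its running maximum.
#' @return a one-row data frame with columns
#'   `patient_id, stage, scale, XL, XR, ZL, ZR` (times in years since the
#'   patient's first visit), or a zero-row frame when the patient is not
#'   informative for the stage; in that case the reason is attached as
#'   attribute `"reason"` (`"never_reached"`,
#'   `"entered_before_observation"`, `"onset_left_unbounded"` or
#'   `"non_monotone"`).
#' @export
extract_intervals <- function(history, stage, scale = c("gds", "fast"),
                              first_visit_rule = TRUE,
                              nonmonotone = c("reject", "carry_forward")) {
  scale <- match.arg(scale)
  nonmonotone <- match.arg(nonmonotone)
  if (!stage %in% 3:7) stop("stage must be in 3..7")
  validate_visits(history)
  if (length(unique(history$patient_id)) != 1) {
    stop("`history` must contain a single patient")
  }
  ord <- order(history$visit_time)
  t <- history$visit_time[ord] - min(history$visit_time)
  s <- history[[stage_column(scale)]][ord]
  not_informative <- function(reason) {
    out <- data.frame(patient_id = character(), stage = integer(),
                      scale = character(), XL = numeric(), XR = numeric(),
                      ZL = numeric(), ZR = numeric(),
                      stringsAsFactors = FALSE)
    structure(out, reason = reason,
              class = c("stage_intervals", "data.frame"))
  }
  if (any(diff(s) < 0)) {
    if (nonmonotone == "reject") return(not_informative("non_monotone"))
    s <- cummax(s)
  }
  if (!any(s >= stage)) return(not_informative("never_reached"))
  if (s[1] > stage) return(not_informative("entered_before_observation"))
  below <- which(s < stage)
  at_or_above <- which(s >= stage)
  XR <- t[at_or_above[1]]
  if (length(below) > 0) {
    XL <- t[max(below)]
  } else if (first_visit_rule && s[1] == stage) {
    XL <- XR <- t[1]
  } else {
    return(not_informative("onset_left_unbounded"))
  }
  at_or_below <- which(s <= stage)
  above <- which(s > stage)
  ZL <- t[max(at_or_below)]
  ZR <- if (length(above) > 0) t[above[1]] else Inf
  out <- data.frame(patient_id = history$patient_id[1], stage = stage,
                    scale = scale, XL = XL, XR = XR, ZL = ZL, ZR = ZR,
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_intervals", "data.frame")
  out
}

#' Duration bounds implied by the censoring intervals
#'
#' The stage duration T = Z - X of a patient with onset in `[XL, XR]` and
#' end in `[ZL, ZR]` is bounded by `T_min = max(0, ZL - XR)` and
#' `T_max = ZR - XL` (`Inf` when the end is right-open).
#'
#' @param intervals a `stage_intervals` data frame (one or more rows).
#' @return a data frame with columns `patient_id, T_min, T_max`.
#' @export
duration_bounds <- function(intervals) {
  stopifnot(all(interval_columns %in% names(intervals)))
  data.frame(patient_id = intervals$patient_id,
             T_min = pmax(0, intervals$ZL - intervals$XR),
             T_max = intervals$ZR - intervals$XL,
             stringsAsFactors = FALSE)
}

#' Extract censoring intervals for every informative patient
#'
#' Applies [extract_intervals()] across a repeated-records cohort and
#' collects the informative patients' intervals together with an
#' exclusion log counting, per reason, the patients that carry no
#' information about the stage (never seen at or above it, already past
#' it at entry, onset unbounded on the left, or a rejected non-monotone
#' sequence).
#'
#' @inheritParams extract_intervals
#' @param visits a visit cohort.
#' @return an object of class `stage_intervals_set`: a list with
#'   `intervals` (data frame, one row per informative patient) and
#'   `exclusions` (data frame `patient_id, reason`).
#' @export
extract_all <- function(visits, stage, scale = c("gds", "fast"),
                        first_visit_rule = TRUE,
                        nonmonotone = c("reject", "carry_forward")) {
  scale <- match.arg(scale)
  nonmonotone <- match.arg(nonmonotone)
  validate_visits(visits)
  ids <- unique(visits$patient_id)
  rows <- vector("list", length(ids))
  excl <- character(0); excl_id <- character(0)
  for (k in seq_along(ids)) {
    h <- visits[visits$patient_id == ids[k], , drop = FALSE]
    class(h) <- class(visits)
    si <- extract_intervals(h, stage, scale, first_visit_rule, nonmonotone)
    if (nrow(si) == 0) {
      excl_id <- c(excl_id, ids[k])
      excl <- c(excl, attr(si, "reason") %||% "not_informative")
    } else {
      rows[[k]] <- si
    }
  }
  intervals <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(intervals)) {
    intervals <- data.frame(patient_id = character(), stage = integer(),
                            scale = character(), XL = numeric(),
                            XR = numeric(), ZL = numeric(), ZR = numeric(),
                            stringsAsFactors = FALSE)
  }
  rownames(intervals) <- NULL
  class(intervals) <- c("stage_intervals", "data.frame")
  structure(list(intervals = intervals,
                 exclusions = data.frame(patient_id = excl_id, reason = excl,
                                         stringsAsFactors = FALSE)),
            class = "stage_intervals_set")
}

#' @export
print.stage_intervals_set <- function(x, ...) {
  cat(sprintf("Stage intervals: %d informative patients, %d excluded\n",
              nrow(x$intervals), nrow(x$exclusions)))
  if (nrow(x$exclusions) > 0) {
    print(table(x$exclusions$reason))
  }
  invisible(x)
}

#' Write/read censoring intervals as CSV
#'
#' Columns `patient_id,stage,scale,XL,XR,ZL,ZR`; unbounded right ends are
#' written as the literal `inf`.
#'
#' @param intervals a `stage_intervals` data frame.
#' @param path file path.
#' @return `path` (write) or the intervals data frame (read).
#' @export
write_intervals <- function(intervals, path) {
  stopifnot(all(interval_columns %in% names(intervals)))
  out <- as.data.frame(intervals)[, interval_columns]
  for (col in c("XL", "XR", "ZL", "ZR")) {
    out[[col]] <- ifelse(is.infinite(out[[col]]), "inf",
                         format(out[[col]], digits = 15, trim = TRUE,
                                scientific = FALSE))
  }
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_intervals
#' @export
read_intervals <- function(path) {
  raw <- read.csv(path, colClasses = "character", check.names = FALSE)
  missing_cols <- setdiff(interval_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing interval column(s): ", paste(missing_cols, collapse = ", "))
  }
  num <- function(x) {
    v <- suppressWarnings(as.numeric(x))
    v[tolower(x) %in% c("inf", "+inf", "infinity")] <- Inf
    if (anyNA(v)) stop("unparsable interval bound")
    v
  }
  out <- data.frame(patient_id = raw$patient_id,
                    stage = as.integer(raw$stage), scale = raw$scale,
                    XL = num(raw$XL), XR = num(raw$XR),
                    ZL = num(raw$ZL), ZR = num(raw$ZR),
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_intervals", "data.frame")
  out
}
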