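# Nonparametric estimation of stage-duration distributions from doubly
# interval-censored data.
#
# Model: patient k enters the stage at onset X_k and leaves at X_k + T_k,
# with X_k known only to lie in [XL_k, XR_k] and X_k + T_k in [ZL_k, ZR_k].
# Onsets and durations are treated as independent with discrete
# distributions w (on an onset grid u_i) and f (on a duration grid t_j).
# The self-consistency (EM) iteration redistributes each patient's
# posterior mass over the compatible (u_i, t_j) cells proportionally to
# the current w_i f_j and re-averages:
#   E: p_k(i,j) = w_i f_j A_k(i,j) / sum_{i'j'} w_i' f_j' A_k(i',j')
#   M: f_j = mean_k sum_i p_k(i,j),  w_i = mean_k sum_j p_k(i,j)
# where A_k(i,j) = 1 iff XL_k <= u_i <= XR_k and ZL_k <= u_i + t_j <= ZR_k.
# The observed-data log-likelihood is non-decreasing at every step.

EPS_BOUND <- 1e-9  # closed-interval tolerance for grid membership

# sort and collapse values closer than EPS_BOUND, keeping exact doubles
dedupe_sorted <- function(x) {
  x <- sort(x)
  x[c(TRUE, diff(x) > EPS_BOUND)]
}

#' Discrete probability distribution on a finite grid
#'
#' @param support strictly increasing numeric values (years).
#' @param weights nonnegative weights summing to 1 (within 1e-10).
#' @return an object of class `discrete_dist`.
#' @export
discrete_dist <- function(support, weights) {
  stopifnot(length(support) == length(weights), length(support) >= 1,
            all(diff(support) > 0), all(weights >= -1e-12))
  weights <- pmax(weights, 0)
  if (abs(sum(weights) - 1) > 1e-10) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  structure(list(support = support, weights = weights),
            class = "discrete_dist")
}

#' @export
print.discrete_dist <- function(x, ...) {
  ms <- mean_sd(x)
  cat(sprintf("Discrete distribution on %d points in [%g, %g]; mean %.3f, sd %.3f\n",
              length(x$support), min(x$support), max(x$support),
              ms[["mean"]], ms[["sd"]]))
  invisible(x)
}

#' Mean and standard deviation of a discrete distribution
#'
#' `mean = sum f_j t_j`; `sd = sqrt(sum f_j t_j^2 - mean^2)` (the
#' distribution's own sd, not a sample estimate).
#'
#' @param dist a [discrete_dist()].
#' @return named numeric vector `c(mean = , sd = )`.
#' @export
mean_sd <- function(dist) {
  stopifnot(inherits(dist, "discrete_dist"))
  m <- sum(dist$weights * dist$support)
  v <- sum(dist$weights * dist$support^2) - m^2
  c(mean = m, sd = sqrt(max(0, v)))
}

#' Cumulative distribution function of a discrete distribution
#'
#' @param dist a [discrete_dist()].
#' @param method method tag carried on the result.
#' @return an object of class `cdf_estimate`: list with `grid` (support),
#'   `values` (right-continuous CDF at the grid) and `method`.
#' @export
dist_cdf <- function(dist, method = "em") {
  stopifnot(inherits(dist, "discrete_dist"))
  structure(list(grid = dist$support, values = cumsum(dist$weights),
                 method = method),
            class = "cdf_estimate")
}

#' Evaluate a CDF estimate at arbitrary times
#'
#' @param est a `cdf_estimate`.
#' @param t numeric times.
#' @return CDF values (right-continuous step function, 0 below the grid).
#' @export
cdf_at <- function(est, t) {
  stopifnot(inherits(est, "cdf_estimate"))
  stepfun(est$grid, c(0, est$values), right = FALSE)(t)
}

#' @export
print.cdf_estimate <- function(x, ...) {
  cat(sprintf("CDF estimate (%s) on %d points in [%g, %g]; final value %.4f\n",
              x$method, length(x$grid), min(x$grid), max(x$grid),
              x$values[length(x$values)]))
  invisible(x)
}

#' Onset/duration grids for the self-consistency estimator
#'
#' The duration grid holds cell midpoints `delta/2, 3 delta/2, ...` up to
#' `t_max`; the onset grid spans the observed onset windows at step
#' `delta`. Exactly observed onsets and durations (degenerate windows) are
#' added to the grids so that exact observations keep their mass on the
#' observed value. If a patient would end up with no compatible
#' (onset, duration) cell, local grid points are added for that patient
#' with a warning.
#'
#' @param intervals a `stage_intervals` data frame.
#' @param delta grid step (years), default 0.25.
#' @param t_max upper end of the duration grid (years), default 20;
#'   durations beyond it are truncated into the last cell (see
#'   [em_fit()]'s `tail_mass`).
#' @return list with `onset`, `duration` (increasing numeric grids),
#'   `delta`, `t_max`.
#' @export
build_grids <- function(intervals, delta = 0.25, t_max = 20) {
  stopifnot(delta > 0, t_max > delta)
  if (nrow(intervals) == 0) stop("no intervals to build grids from")
  u <- seq(min(intervals$XL), max(intervals$XR) + delta / 2, by = delta)
  deg_onset <- with(intervals, XL[abs(XR - XL) < EPS_BOUND])
  u <- dedupe_sorted(c(u, deg_onset))
  tg <- seq(delta / 2, t_max, by = delta)
  deg <- with(intervals, abs(XR - XL) < EPS_BOUND &
                is.finite(ZR) & abs(ZR - ZL) < EPS_BOUND)
  exact_dur <- with(intervals, (ZL - XL)[deg])
  exact_dur <- exact_dur[exact_dur > 0 & exact_dur <= t_max]
  tg <- dedupe_sorted(c(tg, exact_dur))
  grids <- list(onset = u, duration = tg, delta = delta, t_max = t_max)
  # ensure each patient has at least one compatible cell
  for (k in seq_len(nrow(intervals))) {
    iv <- intervals[k, ]
    if (n_compatible(iv, grids) == 0) {
      uk <- iv$XL
      tlo <- max(iv$ZL - uk, delta / 2)
      thi <- iv$ZR - uk
      tk <- if (is.finite(thi)) min(tlo, thi) + abs(thi - tlo) / 2 else tlo
      if (tk <= 0) tk <- delta / 2
      grids$onset <- dedupe_sorted(c(grids$onset, uk))
      grids$duration <- dedupe_sorted(c(grids$duration, tk))
      warning("added local grid points for patient ", iv$patient_id,
              " (no compatible cell on the regular grid)")
    }
  }
  grids
}

#' Compatibility of an (onset, duration) cell with a patient's intervals
#'
#' TRUE iff `XL <= u <= XR` and `ZL <= u + t <= ZR` (closed intervals,
#' with an infinite `ZR` always satisfied on the right).
#'
#' @param intervals a one-row `stage_intervals` data frame.
#' @param u onset value(s).
#' @param t duration value(s) (recycled against `u`).
#' @return logical vector.
#' @export
interval_compatible <- function(intervals, u, t) {
  stopifnot(nrow(intervals) == 1)
  e <- EPS_BOUND
  u >= intervals$XL - e & u <= intervals$XR + e &
    u + t >= intervals$ZL - e &
    (is.infinite(intervals$ZR) | u + t <= intervals$ZR + e)
}

n_compatible <- function(iv, grids) {
  nrow(compatible_cells(iv, grids))
}

# all compatible (i, j) grid index pairs for one patient
compatible_cells <- function(iv, grids) {
  e <- EPS_BOUND
  u <- grids$onset; tg <- grids$duration
  iu <- which(u >= iv$XL - e & u <= iv$XR + e)
  if (length(iu) == 0) return(cbind(i = integer(0), j = integer(0)))
  out_i <- integer(0); out_j <- integer(0)
  for (i in iu) {
    lo <- iv$ZL - u[i] - e
    hi <- if (is.finite(iv$ZR)) iv$ZR - u[i] + e else Inf
    j <- which(tg >= lo & tg <= hi)
    if (length(j) > 0) {
      out_i <- c(out_i, rep.int(i, length(j)))
      out_j <- c(out_j, j)
    }
  }
  cbind(i = out_i, j = out_j)
}

#' Self-consistency (EM) fit of the duration distribution
#'
#' Nonparametric maximum likelihood estimation of the stage-duration
#' distribution from doubly interval-censored onset/end windows, by the
#' alternating self-consistency iteration over a discrete
#' (onset x duration) grid. The onset distribution is a nuisance
#' estimated jointly by default; with `estimate_onset = FALSE` each
#' patient's onset is instead held uniform over the grid points in their
#' onset window (a sensitivity-analysis mode).
#'
#' @param intervals a `stage_intervals` data frame (or a
#'   `stage_intervals_set`, whose `$intervals` is used).
#' @param grids optional grids from [build_grids()]; built automatically
#'   otherwise.
#' @param delta,t_max grid parameters when `grids` is not supplied.
#' @param tol convergence tolerance on the relative change of the
#'   log-likelihood between iterations.
#' @param max_iter iteration cap.
#' @param estimate_onset jointly estimate the onset distribution (default)
#'   or condition on per-patient uniform onsets.
#' @return an object of class `em_fit`: list with `duration_dist` and
#'   `onset_dist` ([discrete_dist()]), `loglik_trace`, `n_iter`,
#'   `converged`, `n_used`, `excluded` (patients with no compatible cell),
#'   `tail_mass` (posterior mass of right-open patients truncated into the
#'   last duration cell; when above 1% the mean/sd should be read as lower
#'   bounds), and `grids`.
#' @export
em_fit <- function(intervals, grids = NULL, delta = 0.25, t_max = 20,
                   tol = 1e-8, max_iter = 5000, estimate_onset = TRUE) {
  if (inherits(intervals, "stage_intervals_set")) {
    intervals <- intervals$intervals
  }
  stopifnot(all(interval_columns %in% names(intervals)))
  if (nrow(intervals) == 0) stop("no informative patients to fit")
  if (is.null(grids)) grids <- build_grids(intervals, delta, t_max)
  n_u <- length(grids$onset); n_t <- length(grids$duration)

  kk <- integer(0); ii <- integer(0); jj <- integer(0)
  excluded <- character(0)
  cell_list <- vector("list", nrow(intervals))
  for (k in seq_len(nrow(intervals))) {
    cells <- compatible_cells(intervals[k, ], grids)
    cell_list[[k]] <- cells
  }
  keep <- vapply(cell_list, nrow, integer(1)) > 0
  excluded <- intervals$patient_id[!keep]
  if (!any(keep)) stop("no patient has a compatible grid cell")
  cell_list <- cell_list[keep]
  N <- length(cell_list)
  npairs <- vapply(cell_list, nrow, integer(1))
  kk <- rep.int(seq_len(N), npairs)
  ii <- unlist(lapply(cell_list, function(m) m[, "i"]), use.names = FALSE)
  jj <- unlist(lapply(cell_list, function(m) m[, "j"]), use.names = FALSE)

  # sparse incidence: patients x (used cells)
  cell_id <- (ii - 1L) * n_t + jj
  used <- sort(unique(cell_id))
  cid <- match(cell_id, used)
  A <- Matrix::sparseMatrix(i = kk, j = cid, x = 1,
                            dims = c(N, length(used)))
  cell_i <- (used - 1L) %/% n_t + 1L
  cell_j <- (used - 1L) %% n_t + 1L

  f <- rep(0, n_t); f[unique(cell_j)] <- 1 / length(unique(cell_j))
  w <- rep(0, n_u); w[unique(cell_i)] <- 1 / length(unique(cell_i))

  loglik <- numeric(0)
  converged <- FALSE
  iter <- 0
  repeat {
    iter <- iter + 1
    wf <- if (estimate_onset) w[cell_i] * f[cell_j] else f[cell_j]
    den <- as.numeric(A %*% wf)
    ll <- sum(log(den))
    loglik <- c(loglik, ll)
    if (iter > 1) {
      rel <- abs(ll - loglik[iter - 1]) / (abs(loglik[iter - 1]) + 1e-300)
      if (rel < tol) { converged <- TRUE; break }
    }
    if (iter >= max_iter) break
    s <- as.numeric(Matrix::crossprod(A, 1 / den))
    m <- wf * s / N  # expected cell masses, summed over patients
    f_new <- rep(0, n_t)
    f_new[seq_len(n_t)] <- 0
    f_agg <- rowsum(m, cell_j)
    f_new[as.integer(rownames(f_agg))] <- f_agg[, 1]
    f <- f_new / sum(f_new)
    if (estimate_onset) {
      w_new <- rep(0, n_u)
      w_agg <- rowsum(m, cell_i)
      w_new[as.integer(rownames(w_agg))] <- w_agg[, 1]
      w <- w_new / sum(w_new)
    }
  }

  # posterior mass of right-open patients in the last duration cell
  wf <- if (estimate_onset) w[cell_i] * f[cell_j] else f[cell_j]
  den <- as.numeric(A %*% wf)
  inf_pat <- which(!is.finite(intervals$ZR[keep]))
  tail_mass <- 0
  if (length(inf_pat) > 0) {
    last_ind <- as.numeric(cell_j == n_t)
    num <- as.numeric(A[inf_pat, , drop = FALSE] %*% (wf * last_ind))
    tail_mass <- sum(num / den[inf_pat]) / N
  }

  if (!estimate_onset) {
    w <- rep(0, n_u)
    w_agg <- rowsum(wf * as.numeric(Matrix::crossprod(A, 1 / den)) / N, cell_i)
    w[as.integer(rownames(w_agg))] <- w_agg[, 1]
    w <- w / sum(w)
  }

  structure(list(
    duration_dist = discrete_dist(grids$duration, f / sum(f)),
    onset_dist = discrete_dist(grids$onset, w / sum(w)),
    loglik_trace = loglik,
    n_iter = iter,
    converged = converged,
    n_used = N,
    excluded = excluded,
    tail_mass = tail_mass,
    grids = grids
  ), class = "em_fit")
}

#' @export
print.em_fit <- function(x, ...) {
  ms <- mean_sd(x$duration_dist)
  cat(sprintf("Self-consistency NPMLE: %d patients, %d iterations (%s)\n",
              x$n_used, x$n_iter,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  duration mean %.3f y, sd %.3f y; tail mass %.4f\n",
              ms[["mean"]], ms[["sd"]], x$tail_mass))
  if (x$tail_mass > 0.01) {
    cat("  note: >1% of mass truncated at t_max; mean/sd are lower bounds\n")
  }
  invisible(x)
}

#' Counting-method CDF bounds and spread estimate
#'
#' A direct, model-free cross-check of the EM estimate built from each
#' patient's duration bounds `[T_min, T_max]`:
#' `lower(t)` = fraction of patients certainly done by `t`
#' (`T_max <= t`), `upper(t)` = fraction possibly done
#' (`T_min <= t`), and `spread(t)` spreads each patient's unit mass
#' uniformly over its bounds,
#' `mean_k clip((t - T_min_k)/(T_max_k - T_min_k), 0, 1)` (a point mass
#' when the bounds coincide; a right-open patient contributes 0 for all
#' finite `t` except through `upper`). Pointwise,
#' `lower <= spread <= upper`, and the EM CDF is bracketed by the same
#' bounds.
#'
#' @param intervals a `stage_intervals` data frame or `stage_intervals_set`.
#' @param grid evaluation times; defaults to the default duration grid.
#' @return list of three `cdf_estimate` objects: `lower`, `upper`,
#'   `spread`.
#' @export
counting_cdf <- function(intervals, grid = NULL) {
  if (inherits(intervals, "stage_intervals_set")) {
    intervals <- intervals$intervals
  }
  b <- duration_bounds(intervals)
  if (nrow(b) == 0) stop("no intervals")
  if (is.null(grid)) grid <- seq(0.125, 20, by = 0.25)
  N <- nrow(b)
  lower <- vapply(grid, function(t) sum(b$T_max <= t + EPS_BOUND) / N,
                  numeric(1))
  upper <- vapply(grid, function(t) sum(b$T_min <= t + EPS_BOUND) / N,
                  numeric(1))
  spread <- vapply(grid, function(t) {
    r <- ifelse(b$T_max - b$T_min < EPS_BOUND,
                as.numeric(t >= b$T_min - EPS_BOUND),
                (t - b$T_min) / (b$T_max - b$T_min))
    mean(pmin(pmax(r, 0), 1))
  }, numeric(1))
  mk <- function(v, tag) structure(list(grid = grid, values = v, method = tag),
                                   class = "cdf_estimate")
  list(lower = mk(lower, "counting_lower"),
       upper = mk(upper, "counting_upper"),
       spread = mk(spread, "counting_spread"))
}

#' Product-limit CDF for the right-censoring-only regime
#'
#' When every onset is exactly observed (degenerate `[XL, XR]`) and every
#' end is either exact or right-open, the doubly-censored problem reduces
#' to classical right-censored survival and the NPMLE is the product-limit
#' (Kaplan-Meier) estimator. Used as an independent oracle for [em_fit()]
#' in that regime.
#'
#' @param intervals a `stage_intervals` data frame or `stage_intervals_set`
#'   with degenerate onsets and exact-or-right-open ends.
#' @return a `cdf_estimate` (CDF = 1 - product-limit survival, on the
#'   observed event/censoring times).
#' @export
product_limit_cdf <- function(intervals) {
  if (inherits(intervals, "stage_intervals_set")) {
    intervals <- intervals$intervals
  }
  stopifnot(nrow(intervals) > 0)
  if (any(abs(intervals$XR - intervals$XL) > EPS_BOUND)) {
    stop("product-limit oracle requires exactly observed onsets")
  }
  exact_end <- is.finite(intervals$ZR) &
    abs(intervals$ZR - intervals$ZL) < EPS_BOUND
  open_end <- !is.finite(intervals$ZR)
  if (!all(exact_end | open_end)) {
    stop("product-limit oracle requires exact or right-open ends")
  }
  time <- intervals$ZL - intervals$XL
  event <- as.integer(exact_end)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(grid = sf$time, values = 1 - sf$surv,
                 method = "product_limit"),
            class = "cdf_estimate")
}
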