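#' Follow-up schedule for one intervention category
#'
#' Months from baseline of the end-of-treatment (EOT), short-term (ST) and
#' long-term (LT) fatigue assessments, plus the model horizon. ST is defined
#' as up to 3 months after EOT and LT as more than 3 months after EOT; the
#' constructor warns (but does not error) when the supplied times fall outside
#' those windows, since the times are study averages.
#'
#' @param t_eot Months from baseline to end of treatment, `> 0`.
#' @param t_st Months to the short-term follow-up, or `NA` if the category has
#'   no ST evidence.
#' @param t_lt Months to the long-term follow-up, or `NA`.
#' @param horizon Model horizon in months.
#' @return An object of class `"timepoint_schedule"`.
#' @export
timepoint_schedule <- function(t_eot, t_st = NA_real_, t_lt = NA_real_,
                               horizon = 24) {
  stopifnot(is.numeric(t_eot), length(t_eot) == 1)
  if (!(t_eot > 0)) stop("t_eot must be > 0")
  if (horizon <= 0) stop("horizon must be > 0")
  times <- c(eot = t_eot, st = t_st, lt = t_lt)
  present <- times[!is.na(times)]
  if (any(diff(present) <= 0))
    stop("follow-up times must be strictly increasing: ",
         paste(sprintf("%s=%g", names(present), present), collapse = ", "))
  if (!is.na(t_st) && t_st > t_eot + 3)
    warning("ST follow-up is more than 3 months after EOT (", t_st - t_eot,
            " months); ST is defined as up to 3 months after EOT")
  if (!is.na(t_lt) && t_lt <= t_eot + 3)
    warning("LT follow-up is within 3 months of EOT (", t_lt - t_eot,
            " months); LT is defined as more than 3 months after EOT")
  structure(list(t_eot = t_eot, t_st = t_st, t_lt = t_lt, horizon = horizon),
            class = "timepoint_schedule")
}

new_trajectory <- function(time, fss, baseline_fss, horizon, waning_mode) {
  stopifnot(length(time) == length(fss), !is.unsorted(time, strictly = TRUE))
  if (time[1] != 0) stop("first trajectory knot must be at t = 0")
  if (abs(time[length(time)] - horizon) > 1e-9)
    stop("last trajectory knot must be at the horizon")
  structure(list(knots = data.frame(time = time, fss = fss),
                 baseline_fss = baseline_fss, horizon = horizon,
                 waning_mode = waning_mode),
            class = "fatigue_trajectory")
}

#' @export
print.fatigue_trajectory <- function(x, ...) {
  cat(sprintf("<fatigue_trajectory> horizon %g months, waning '%s'\n",
              x$horizon, x$waning_mode))
  print(x$knots, row.names = FALSE)
  invisible(x)
}

#' Usual-care FSS trajectory
#'
#' Usual care keeps the absolute FSS score fixed at its baseline value at
#' every time point over the whole horizon.
#'
#' @param baseline A [baseline_fatigue()] object.
#' @param schedule A [timepoint_schedule()].
#' @return A `"fatigue_trajectory"` with constant FSS.
#' @export
build_usual_care_trajectory <- function(baseline, schedule) {
  stopifnot(inherits(baseline, "baseline_fatigue"),
            inherits(schedule, "timepoint_schedule"))
  tt <- c(0, schedule$t_eot, schedule$t_st, schedule$t_lt, schedule$horizon)
  tt <- sort(unique(tt[!is.na(tt) & tt <= schedule$horizon]))
  if (tt[length(tt)] < schedule$horizon) tt <- c(tt, schedule$horizon)
  new_trajectory(tt, rep(baseline$mean_fss, length(tt)),
                 baseline$mean_fss, schedule$horizon, "none")
}

# Small forward step used to represent an instantaneous return to baseline
# as a strictly-increasing knot sequence.
.knot_eps <- 1e-6

#' Intervention FSS trajectory with waning
#'
#' Builds the piecewise-linear absolute-FSS path for one strategy: baseline at
#' t = 0, then the baseline plus the SMD-derived FSS difference at each
#' observed follow-up point, then the waning assumption out to the horizon.
#'
#' Missing follow-up points: if the ST SMD is absent the path runs straight
#' from the EOT knot to the LT knot (a linear change in FSS between EOT and
#' LT); `force_zero_st = TRUE` instead inserts an ST knot with zero treatment
#' effect (at `t_st`, or at `t_eot + 3` months when the category has no ST
#' time), which is the pessimistic scenario for categories with no ST
#' evidence.
#'
#' Waning modes after the last observed follow-up:
#' \describe{
#'   \item{linear_to_horizon}{the FSS difference shrinks linearly to zero at
#'     the horizon (base case).}
#'   \item{immediate_return}{the FSS returns to baseline immediately after
#'     the last follow-up.}
#'   \item{none_beyond_followup}{the treatment effect is taken as zero
#'     wherever data are unavailable: missing interior follow-ups get
#'     zero-effect knots and the effect ends immediately after the last
#'     observed follow-up.}
#' }
#'
#' If the last observed follow-up lies at or beyond the horizon the path is
#' truncated at the horizon and no waning segment is added.
#'
#' @param baseline A [baseline_fatigue()] object.
#' @param smds Named numeric vector with elements `eot`, `st`, `lt` (use `NA`
#'   for timepoints without evidence). At least `eot` must be present.
#' @param schedule A [timepoint_schedule()].
#' @param sd_fss Population SD for the SMD conversion; defaults to the one in
#'   `baseline`.
#' @param waning_mode One of the three modes above.
#' @param force_zero_st Insert a zero-effect ST knot (scenario analysis).
#' @return A `"fatigue_trajectory"`.
#' @export
build_intervention_trajectory <- function(baseline, smds, schedule,
                                          sd_fss = baseline$sd_fss,
                                          waning_mode = "linear_to_horizon",
                                          force_zero_st = FALSE) {
  stopifnot(inherits(baseline, "baseline_fatigue"),
            inherits(schedule, "timepoint_schedule"))
  waning_mode <- match.arg(waning_mode, c("linear_to_horizon",
                                          "immediate_return",
                                          "none_beyond_followup"))
  smds <- smds[c("eot", "st", "lt")]
  names(smds) <- c("eot", "st", "lt")
  if (all(is.na(smds))) stop("no SMD available at any follow-up point")
  if (is.na(smds[["eot"]])) stop("an EOT SMD is required")
  b <- baseline$mean_fss
  horizon <- schedule$horizon
  eff <- smd_to_fss_diff(smds, sd_fss) # FSS points, NA where absent

  t_data <- c(schedule$t_eot, schedule$t_st, schedule$t_lt)
  keep <- !is.na(eff) & !is.na(t_data)
  times <- t_data[keep]
  diffs <- unname(eff[keep])

  # zero-effect ST knot for unobserved points (scenario v / missing-data
  # mode); only meaningful strictly between the EOT and the last data point
  zero_interior <- waning_mode == "none_beyond_followup"
  if ((force_zero_st || zero_interior) && is.na(smds[["st"]])) {
    t_st <- if (!is.na(schedule$t_st)) schedule$t_st else schedule$t_eot + 3
    if (t_st > schedule$t_eot && t_st < max(times) &&
        !any(abs(times - t_st) < 1e-9)) {
      times <- c(times, t_st)
      diffs <- c(diffs, 0)
    }
  }
  o <- order(times)
  times <- times[o]; diffs <- diffs[o]

  t_last <- max(times)
  if (t_last >= horizon - 1e-9) {
    # follow-up reaches the horizon: truncate, no waning segment
    path_t <- c(0, times)
    path_f <- c(b, b + diffs)
    f_h <- stats::approx(path_t, path_f, xout = horizon, rule = 2)$y
    keep_in <- path_t < horizon - 1e-9
    return(new_trajectory(c(path_t[keep_in], horizon),
                          c(path_f[keep_in], f_h), b, horizon, waning_mode))
  }

  tail_t <- switch(waning_mode,
    linear_to_horizon = horizon,
    immediate_return = c(t_last + .knot_eps, horizon),
    none_beyond_followup = c(t_last + .knot_eps, horizon))
  tail_f <- rep(b, length(tail_t))
  new_trajectory(c(0, times, tail_t), c(b, b + diffs, tail_f),
                 b, horizon, waning_mode)
}

# FSS value of a trajectory at arbitrary times (linear interpolation).
trajectory_fss <- function(traj, t) {
  stats::approx(traj$knots$time, traj$knots$fss, xout = t, rule = 2)$y
}

# Quadrature nodes and weights for the discounted AUC integral.
# Returns nodes (months) and weights w such that sum(w * u(nodes)) equals the
# trapezoid approximation of the integral of u(t) * disc(t) dt / 12 (QALYs).
# Knot times are always included as nodes so kinks in the piecewise-linear
# path never straddle a panel; for annual-step discounting the year
# boundaries are additionally split so each panel has a constant weight.
quadrature_weights <- function(knot_times, horizon, step = 0.25,
                               discount_rate = 0.035,
                               method = c("continuous", "annual")) {
  method <- match.arg(method)
  nodes <- sort(unique(c(seq(0, horizon, by = step), horizon, knot_times)))
  nodes <- nodes[nodes >= 0 & nodes <= horizon]
  if (method == "annual") {
    yb <- seq(12, horizon, by = 12)
    yb <- yb[yb < horizon]
    nodes <- sort(unique(c(nodes, yb, yb + .knot_eps)))
  }
  h <- diff(nodes)
  disc <- if (method == "continuous") {
    (1 + discount_rate)^(-nodes / 12)
  } else {
    (1 + discount_rate)^(-floor((nodes - .knot_eps / 2) / 12))
  }
  if (method == "annual") disc[1] <- 1
  # trapezoid: w_i = (h_{i-1} + h_i)/2, discounted, in years
  w <- c(h / 2, 0) + c(0, h / 2)
  list(nodes = nodes, w = w * disc / 12)
}

#' Discounted QALYs of an FSS trajectory
#'
#' Maps the piecewise-linear FSS path to utility pointwise at dense quadrature
#' nodes (FSS clamped to the instrument range first, utility clamped to its
#' configured range after mapping) and integrates the discounted utility by
#' trapezoidal area under the curve. With continuous discounting the
#' integrand is `u(t) * (1 + r)^(-t/12)` with `t` in months; the `"annual"`
#' method instead applies step weights `(1 + r)^(-floor(t/12))`.
#'
#' @param traj A `"fatigue_trajectory"`.
#' @param coeffs A [mapping_coefficients()] object.
#' @param discount_rate Annual discount rate, `>= 0`.
#' @param step Quadrature step in months (default 0.25).
#' @param method `"continuous"` (default) or `"annual"`.
#' @param utility_floor,utility_ceiling Utility clamp range.
#' @param fss_min,fss_max FSS clamp range.
#' @return Discounted QALYs over the trajectory horizon.
#' @export
#' @examples
#' b <- baseline_fatigue(43.73, sd_fss = 15.1)
#' s <- timepoint_schedule(3, 5, 12, horizon = 24)
#' uc <- build_usual_care_trajectory(b, s)
#' discounted_qalys(uc, mapping_coefficients(0.832, -0.0045), 0.035)
discounted_qalys <- function(traj, coeffs, discount_rate = 0.035,
                             step = 0.25, method = c("continuous", "annual"),
                             utility_floor = 0, utility_ceiling = 1,
                             fss_min = 9, fss_max = 63) {
  stopifnot(inherits(traj, "fatigue_trajectory"))
  if (discount_rate < 0) stop("discount_rate must be >= 0")
  if (nrow(traj$knots) < 2) stop("trajectory has no segments to integrate")
  qw <- quadrature_weights(traj$knots$time, traj$horizon, step,
                           discount_rate, method)
  fss <- clamp(trajectory_fss(traj, qw$nodes), fss_min, fss_max)
  u <- fss_to_utility(fss, coeffs, utility_floor, utility_ceiling)
  sum(qw$w * u)
}

#' Incremental QALYs of a strategy versus usual care
#'
#' @param strategy_traj,uc_traj Trajectories sharing the same horizon.
#' @param coeffs A [mapping_coefficients()] object.
#' @param discount_rate Annual discount rate.
#' @param ... Passed on to [discounted_qalys()].
#' @return `discounted_qalys(strategy) - discounted_qalys(usual care)`.
#' @export
incremental_qalys <- function(strategy_traj, uc_traj, coeffs,
                              discount_rate = 0.035, ...) {
  if (abs(strategy_traj$horizon - uc_traj$horizon) > 1e-9)
    stop("trajectories must share the same horizon (",
         strategy_traj$horizon, " vs ", uc_traj$horizon, " months)")
  discounted_qalys(strategy_traj, coeffs, discount_rate, ...) -
    discounted_qalys(uc_traj, coeffs, discount_rate, ...)
}

# Exact discounted QALYs for a piecewise-linear utility path: closed-form
# integral of (a + b t) e^(-c t) per segment. Independent of the trapezoid
# engine; used as the quadrature oracle in tests and to freeze the fixture's
# expected QALYs. Valid only when no FSS or utility clamp is active along the
# path, which the function verifies.
exact_discounted_qalys <- function(traj, coeffs, discount_rate = 0.035,
                                   utility_floor = 0, utility_ceiling = 1,
                                   fss_min = 9, fss_max = 63) {
  kt <- traj$knots$time
  kf <- traj$knots$fss
  if (any(kf < fss_min - 1e-9 | kf > fss_max + 1e-9))
    stop("exact oracle requires the FSS path inside the instrument range")
  u <- coeffs$intercept + coeffs$slope * kf
  if (any(u < utility_floor - 1e-12 | u > utility_ceiling + 1e-12))
    stop("exact oracle requires the utility path inside the clamp range")
  cc <- log(1 + discount_rate) / 12 # per-month continuous rate
  total <- 0
  for (i in seq_len(length(kt) - 1)) {
    t1 <- kt[i]; t2 <- kt[i + 1]
    if (t2 <= t1) next
    bseg <- (u[i + 1] - u[i]) / (t2 - t1)
    aseg <- u[i] - bseg * t1
    total <- total + if (cc == 0) {
      aseg * (t2 - t1) + bseg * (t2^2 - t1^2) / 2
    } else {
      F <- function(t) -exp(-cc * t) * ((aseg + bseg * t) / cc + bseg / cc^2)
      F(t2) - F(t1)
    }
  }
  total / 12
}

#' Export trajectories as a long table
#'
#' Evaluates each trajectory (FSS and mapped utility) on a regular grid for
#' plotting, in the layout `time_months, strategy, fss, utility`.
#'
#' @param trajectories Named list of `"fatigue_trajectory"` objects.
#' @param coeffs A [mapping_coefficients()] object.
#' @param step Grid step in months.
#' @param utility_floor,utility_ceiling,fss_min,fss_max Clamp ranges.
#' @return A data frame.
#' @export
trajectory_export <- function(trajectories, coeffs, step = 0.25,
                              utility_floor = 0, utility_ceiling = 1,
                              fss_min = 9, fss_max = 63) {
  stopifnot(length(names(trajectories)) == length(trajectories))
  out <- lapply(names(trajectories), function(nm) {
    tr <- trajectories[[nm]]
    tt <- sort(unique(c(seq(0, tr$horizon, by = step), tr$knots$time)))
    fss <- clamp(trajectory_fss(tr, tt), fss_min, fss_max)
    data.frame(time_months = tt, strategy = nm, fss = fss,
               utility = fss_to_utility(fss, coeffs, utility_floor,
                                        utility_ceiling))
  })
  do.call(rbind, out)
}
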