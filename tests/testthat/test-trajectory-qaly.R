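coeffs <- mapping_coefficients(0.832, -0.0045)
flat1 <- mapping_coefficients(1, 0, allow_positive_slope = TRUE)
bl <- baseline_fatigue(43.73, sd_fss = 15.1)

test_that("schedule validation orders timepoints and warns on windows", {
  expect_error(timepoint_schedule(6, 3, 12), "increasing")
  expect_error(timepoint_schedule(0), "> 0")
  expect_warning(timepoint_schedule(3, 8, 12), "3 months")
  expect_warning(timepoint_schedule(3, 5, 5.5), "more than 3 months")
  expect_silent(timepoint_schedule(3, 5, 12))
})

test_that("usual care is flat at baseline and its self-increment is zero", {
  s <- timepoint_schedule(3, 5, 12, horizon = 24)
  uc <- build_usual_care_trajectory(bl, s)
  expect_true(all(uc$knots$fss == 43.73))
  expect_equal(range(uc$knots$time), c(0, 24))
  expect_equal(incremental_qalys(uc, uc, coeffs, 0.035), 0)
  uc50 <- build_usual_care_trajectory(baseline_fatigue(50, sd_fss = 15.1),
                                      timepoint_schedule(3, horizon = 15))
  expect_true(all(uc50$knots$fss == 50))
})

test_that("intervention trajectory interpolates missing ST and wanes linearly", {
  s <- timepoint_schedule(3, NA, 9, horizon = 24)
  tr <- build_intervention_trajectory(bl, c(eot = -0.5, st = NA, lt = -0.5),
                                      s, sd_fss = 15.1)
  # knots: baseline, EOT and LT at 36.18, then back to baseline at horizon
  expect_equal(tr$knots$time, c(0, 3, 9, 24))
  expect_equal(tr$knots$fss, c(43.73, 36.18, 36.18, 43.73))
  # no ST knot: the 3 -> 9 segment is flat at 36.18
  expect_equal(fatiguecea:::trajectory_fss(tr, 6), 36.18)
  # waning: linear rise back to baseline, e.g. halfway at month 16.5
  expect_equal(fatiguecea:::trajectory_fss(tr, 16.5), (36.18 + 43.73) / 2)
})

test_that("zero SMDs reproduce usual care; missing effects error", {
  s <- timepoint_schedule(3, 5, 12, horizon = 24)
  uc <- build_usual_care_trajectory(bl, s)
  tr0 <- build_intervention_trajectory(bl, c(eot = 0, st = 0, lt = 0), s)
  expect_equal(incremental_qalys(tr0, uc, coeffs, 0.035), 0)
  expect_error(build_intervention_trajectory(
    bl, c(eot = NA, st = NA, lt = NA), s), "no SMD")
  expect_error(build_intervention_trajectory(
    bl, c(eot = NA, st = -0.3, lt = -0.3), s), "EOT")
})

test_that("immediate_return drops the effect right after the last follow-up", {
  s <- timepoint_schedule(3, NA, 9, horizon = 24)
  tr <- build_intervention_trajectory(bl, c(eot = -0.5, st = NA, lt = -0.5),
                                      s, waning_mode = "immediate_return")
  expect_equal(fatiguecea:::trajectory_fss(tr, 9), 36.18)
  expect_equal(fatiguecea:::trajectory_fss(tr, 9.001), 43.73,
               tolerance = 1e-6)
})

test_that("force_zero_st inserts a zero-effect knot in the ST window", {
  s <- timepoint_schedule(2, NA, 9, horizon = 24)
  tr <- build_intervention_trajectory(bl, c(eot = -0.65, st = NA, lt = -0.5),
                                      s, force_zero_st = TRUE)
  # zero-effect knot placed at t_eot + 3 = 5 months
  expect_true(any(abs(tr$knots$time - 5) < 1e-9))
  expect_equal(tr$knots$fss[tr$knots$time == 5], 43.73)
})

test_that("none_beyond_followup zeroes the effect where data are absent", {
  s <- timepoint_schedule(2, NA, 9, horizon = 24)
  tr <- build_intervention_trajectory(bl, c(eot = -0.65, st = NA, lt = -0.5),
                                      s, waning_mode = "none_beyond_followup")
  expect_equal(fatiguecea:::trajectory_fss(tr, 5), 43.73)       # zero ST
  expect_equal(fatiguecea:::trajectory_fss(tr, 9.001), 43.73,   # no tail
               tolerance = 1e-6)
})

test_that("discounted QALYs match closed forms for flat utility", {
  s <- timepoint_schedule(3, horizon = 12)
  uc12 <- build_usual_care_trajectory(bl, s)
  expect_equal(discounted_qalys(uc12, flat1, 0), 1.0)
  uc24 <- build_usual_care_trajectory(
    bl, timepoint_schedule(3, horizon = 24))
  closed <- (1 - 1.035^-2) / log(1.035)
  expect_equal(discounted_qalys(uc24, flat1, 0.035), closed,
               tolerance = 1e-6)
  # annual-step weights: sum of two discounted rectangle years
  annual <- discounted_qalys(uc24, flat1, 0.035, method = "annual")
  expect_equal(annual, 1 + 1.035^-1, tolerance = 1e-9)
})

test_that("trapezoid result matches the exact segment integral (oracle)", {
  set.seed(42)
  for (i in 1:8) {
    smds <- c(eot = runif(1, -0.8, -0.1), st = runif(1, -0.8, -0.1),
              lt = runif(1, -0.8, -0.1))
    if (i %% 3 == 0) smds["st"] <- NA
    t_eot <- runif(1, 1, 4)
    s <- timepoint_schedule(t_eot, if (is.na(smds["st"])) NA else
                            t_eot + runif(1, 0.5, 2.5),
                            t_eot + runif(1, 4, 10), horizon = 24)
    tr <- build_intervention_trajectory(bl, smds, s, sd_fss = 15.1)
    got <- discounted_qalys(tr, coeffs, 0.035, step = 0.25)
    want <- fatiguecea:::exact_discounted_qalys(tr, coeffs, 0.035)
    expect_equal(got, want, tolerance = 1e-6)
    # halving the step moves the result by < 1e-5
    finer <- discounted_qalys(tr, coeffs, 0.035, step = 0.125)
    expect_lt(abs(finer - got), 1e-5)
  }
})

test_that("QALYs are monotone in discount rate and horizon, bounded by 2", {
  smds <- c(eot = -0.6, st = -0.5, lt = -0.45)
  qal <- function(h, r) {
    s <- timepoint_schedule(3, 5, 12, horizon = h)
    tr <- build_intervention_trajectory(bl, smds, s)
    discounted_qalys(tr, coeffs, r)
  }
  expect_true(qal(24, 0.06) < qal(24, 0.035))
  expect_true(qal(24, 0.035) < qal(24, 0.015))
  expect_true(qal(15, 0.035) <= qal(24, 0.035))
  expect_true(qal(24, 0.035) <= qal(48, 0.035))
  expect_lte(qal(24, 0), 2.0)
})

test_that("incremental QALYs: flat utility gap and horizon mismatch", {
  # two flat FSS paths whose utility gap is 0.031 over 24 undiscounted months
  mc <- mapping_coefficients(0.832, -0.005)
  f1 <- 43.73; f2 <- f1 - 0.031 / 0.005
  t1 <- fatiguecea:::new_trajectory(c(0, 24), c(f1, f1), f1, 24, "none")
  t2 <- fatiguecea:::new_trajectory(c(0, 24), c(f2, f2), f1, 24, "none")
  expect_equal(incremental_qalys(t2, t1, mc, 0), 0.062, tolerance = 1e-9)
  t3 <- fatiguecea:::new_trajectory(c(0, 15), c(f1, f1), f1, 15, "none")
  expect_error(incremental_qalys(t3, t1, mc, 0), "horizon")
})

test_that("trajectory export evaluates FSS and utility on a grid", {
  s <- timepoint_schedule(3, 5, 12, horizon = 24)
  trajs <- list(usual_care = build_usual_care_trajectory(bl, s),
                pa = build_intervention_trajectory(
                  bl, c(eot = -0.6, st = -0.55, lt = -0.45), s))
  ex <- trajectory_export(trajs, coeffs, step = 1)
  expect_named(ex, c("time_months", "strategy", "fss", "utility"))
  expect_setequal(unique(ex$strategy), c("usual_care", "pa"))
  expect_true(all(ex$utility >= 0 & ex$utility <= 1))
  uc_rows <- ex[ex$strategy == "usual_care", ]
  expect_true(all(uc_rows$fss == 43.73))
})
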