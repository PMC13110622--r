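test_that("effect generator recovers its ground-truth moments", {
  spec <- effect_generator_spec(
    "pa", means = c(eot = -0.6, st = -0.55, lt = -0.45),
    sds = c(eot = 0.12, st = 0.15, lt = 0.18), rho = 0.7, n_draws = 1e5)
  d <- generate_effect_samples(spec, seed = 5)
  wide <- matrix(d$smd, ncol = 3,
                 dimnames = list(NULL, unique(d$timepoint)))
  means <- colMeans(wide)
  # CLT bounds: 4 * sd / sqrt(n)
  expect_true(all(abs(means - c(-0.6, -0.55, -0.45)) <
                    4 * c(0.12, 0.15, 0.18) / sqrt(1e5)))
  expect_equal(unname(apply(wide, 2, sd)), c(0.12, 0.15, 0.18),
               tolerance = 0.02)
  expect_equal(cor(wide[, 1], wide[, 2]), 0.7, tolerance = 0.02)
})

test_that("rho = 0 gives uncorrelated draws; SD 0 gives constant draws", {
  spec0 <- effect_generator_spec("x", means = c(eot = -0.3, lt = -0.2),
                                 sds = c(eot = 0.1, lt = 0.1), rho = 0,
                                 n_draws = 1e5)
  d <- generate_effect_samples(spec0, seed = 2)
  wide <- matrix(d$smd, ncol = 2)
  expect_lt(abs(cor(wide[, 1], wide[, 2])), 0.011)
  degen <- effect_generator_spec("x", means = c(eot = -0.3),
                                 sds = c(eot = 0), n_draws = 50)
  expect_true(all(generate_effect_samples(degen, 1)$smd == -0.3))
})

test_that("missing timepoints are absent and bad correlations rejected", {
  spec <- effect_generator_spec("mind", means = c(eot = -0.65, lt = -0.5),
                                sds = c(eot = 0.15, lt = 0.25),
                                n_draws = 100)
  d <- generate_effect_samples(spec, seed = 1)
  expect_setequal(unique(d$timepoint), c("EOT", "LT"))
  expect_error(effect_generator_spec(
    "x", means = c(eot = 0, st = 0, lt = 0), sds = c(eot = 1, st = 1, lt = 1),
    rho = -0.9), "positive semi-definite")
  expect_error(effect_generator_spec("x", means = c(foo = 1),
                                     sds = c(foo = 1)), "timepoint names")
})

test_that("cost record generator respects ranges; degenerate ranges fixed", {
  rng <- list(sessions = c(4, 8), minutes = c(30, 60), unit_cost = c(35, 55),
              participants = c(8, 12))
  recs <- generate_cost_records("pa_g", "group", 20, rng, seed = 3)
  # interval arithmetic bound on per-patient costs
  min_possible <- 4 * (30 / 60) * 35 * 1 / 12
  max_possible <- 8 * (60 / 60) * 55 * 1 / 8
  cpp <- cost_per_patient(recs)
  expect_true(all(cpp >= min_possible & cpp <= max_possible))
  degen <- generate_cost_records("x", "individual", 5,
                                 list(sessions = c(6, 6), minutes = c(60, 60),
                                      unit_cost = c(50, 50)), seed = 1)
  expect_true(all(cost_per_patient(degen) == 300))
  expect_error(generate_cost_records("x", "individual", 3,
                                     list(sessions = c(5, 2),
                                          minutes = c(30, 60),
                                          unit_cost = c(35, 55))),
               "invalid range")
})

test_that("reference fixture has the seven-strategy structure", {
  fx <- fx_small()
  expect_s3_class(fx, "fatigue_model_inputs")
  expect_equal(nrow(fx$strategies), 7)
  expect_true("usual_care" %in% fx$strategies$strategy)
  # mindfulness-like category lacks ST evidence
  mind <- fx$posterior$base[
    fx$posterior$base$strategy == "mindfulness_group", ]
  expect_setequal(unique(mind$timepoint), c("EOT", "LT"))
  # group mindfulness cost comes from a single study (25% SE rule path)
  cc <- fx$ground_truth$category_costs
  expect_equal(cc$n_studies[cc$strategy == "mindfulness_group"], 1)
  expect_equal(cc$se[cc$strategy == "mindfulness_group"],
               0.25 * cc$median_cost[cc$strategy == "mindfulness_group"])
  # pooled delivery modes share identical posterior draws in the base source
  pa_i <- fx$posterior$base[
    fx$posterior$base$strategy == "physical_activity_individual", "smd"]
  pa_g <- fx$posterior$base[
    fx$posterior$base$strategy == "physical_activity_group", "smd"]
  expect_identical(pa_i, pa_g)
})

test_that("fixture drives a complete deterministic run; QALYs match the stored oracle", {
  fx <- fx_small()
  res <- run_deterministic(fx$config, fx)
  expect_equal(nrow(res), 7)
  expect_true(all(is.finite(res$qalys)))
  # stored expected QALYs were computed with the closed-form integrator
  gt <- fx$ground_truth$expected_qalys
  expect_equal(res$qalys[match(gt$strategy, res$strategy)], gt$qalys,
               tolerance = 1e-6)
})

test_that("bundle regeneration and export are byte-identical for a seed", {
  d1 <- file.path(tempdir(), "bundle1")
  d2 <- file.path(tempdir(), "bundle2")
  write_fixture_bundle(reference_fixture(n_draws = 40, seed = 123), d1)
  write_fixture_bundle(reference_fixture(n_draws = 40, seed = 123), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  # and the bundle reads back into a runnable inputs object
  inputs <- read_model_inputs(d1)
  res <- run_deterministic(inputs$config, inputs)
  expect_equal(nrow(res), 7)
  unlink(c(d1, d2), recursive = TRUE)
})
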