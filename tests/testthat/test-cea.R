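# hand-built PSA output: 2 strategies x n iterations with known draws
mk_psa <- function(uc_q, uc_c, s_q, s_c, strategy = "s") {
  n <- length(uc_q)
  structure(data.frame(
    iteration = rep(seq_len(n), 2),
    strategy = rep(c("usual_care", strategy), each = n),
    cost = c(uc_c, s_c), qalys = c(uc_q, s_q)),
    class = c("psa_output", "data.frame"))
}

test_that("nmb and inmb are the threshold-valued identities", {
  expect_equal(nmb(1.0, 0, 20000), 20000)
  expect_equal(nmb(0, 0, 123), 0)
  expect_error(nmb(1, 0, -5), ">= 0")
  s <- list(qalys = 1.287, cost = 267); uc <- list(qalys = 1.227, cost = 0)
  expect_equal(inmb(s, uc, 20000), 20000 * 0.06 - 267)
  expect_equal(inmb(s, s, 20000), 0)
  expect_equal(inmb(s, uc, 0), -(267))
})

test_that("icer divides or classifies dominance", {
  r <- icer(list(cost = 817, qalys = 0.045), list(cost = 0, qalys = 0))
  expect_equal(r$class, "icer")
  expect_equal(r$value, 817 / 0.045, tolerance = 1e-12)
  expect_lt(r$value, 20000)
  expect_equal(icer(list(cost = 100, qalys = -0.01),
                    list(cost = 0, qalys = 0))$class, "dominated")
  expect_equal(icer(list(cost = -50, qalys = 0.02),
                    list(cost = 0, qalys = 0))$class, "dominant")
  expect_equal(icer(list(cost = 5, qalys = 1e-12),
                    list(cost = 0, qalys = 0))$class, "dominated")
  expect_equal(icer(list(cost = 0, qalys = 0),
                    list(cost = 0, qalys = 0))$class, "undefined")
  expect_equal(icer(list(cost = -10, qalys = -0.05),
                    list(cost = 0, qalys = 0))$class, "southwest")
})

test_that("pairwise probability counts strictly positive INMB", {
  psa <- mk_psa(uc_q = rep(1, 4), uc_c = rep(0, 4),
                s_q = c(1.1, 1.1, 1.1, 1.1), s_c = rep(100, 4))
  expect_equal(pairwise_prob_ce(psa, "s", "usual_care", 20000), 1)
  expect_equal(pairwise_prob_ce(psa, "usual_care", "usual_care", 20000), 0)
  # ties count against the strategy
  tie <- mk_psa(rep(1, 3), rep(0, 3), rep(1, 3), rep(0, 3))
  expect_equal(pairwise_prob_ce(tie, "s", "usual_care", 20000), 0)
  # mismatched iteration counts rejected
  bad <- mk_psa(rep(1, 4), rep(0, 4), rep(1.1, 4), rep(10, 4))
  expect_error(pairwise_prob_ce(bad[-1, ], "s", "usual_care", 2e4),
               "mismatched")
})

test_that("empirical pairwise probability matches the normal CDF", {
  set.seed(21)
  n <- 4000; mu <- 400; sigma <- 900
  # INMB ~ N(mu, sigma): dQ fixed, cost noise normal
  dq <- 0.05; lam <- 20000
  s_c <- lam * dq - rnorm(n, mu, sigma)
  psa <- mk_psa(rep(1, n), rep(0, n), rep(1 + dq, n), s_c)
  expect_equal(pairwise_prob_ce(psa, "s", "usual_care", lam),
               pnorm(mu / sigma), tolerance = 2 / sqrt(n))
})

test_that("multiway CEAC normalises to one and honours limits", {
  fx <- fx_small()
  cfg <- fx$config
  cfg$psa$n_iterations <- 300
  psa <- run_psa(cfg, fx)
  grid <- seq(0, 50000, by = 5000)
  ceac <- multiway_ceac(psa, grid)
  sums <- as.numeric(tapply(ceac$probability, ceac$lambda, sum))
  expect_equal(sums, rep(1, length(grid)), tolerance = 1e-12)
  # lambda = 0: usual care (cost 0) is uniquely cheapest almost surely
  at0 <- ceac[ceac$lambda == 0, ]
  expect_equal(at0$probability[at0$strategy == "usual_care"], 1)
  expect_error(multiway_ceac(psa, numeric(0)), "empty")
})

test_that("a strategy dominant in every iteration has CEAC probability 1", {
  psa <- mk_psa(uc_q = rep(1, 10), uc_c = rep(50, 10),
                s_q = rep(1.2, 10), s_c = rep(10, 10))
  ceac <- multiway_ceac(psa, c(0, 10000, 20000))
  expect_true(all(ceac$probability[ceac$strategy == "s"] == 1))
  # pairwise probability monotone in lambda when dQ > 0 in every iteration
  set.seed(3)
  psa2 <- mk_psa(rep(1, 200), rep(0, 200), 1 + runif(200, 0.01, 0.1),
                 rnorm(200, 500, 300))
  probs <- vapply(seq(0, 4e4, 4e3), function(l)
    pairwise_prob_ce(psa2, "s", "usual_care", l), numeric(1))
  expect_true(all(diff(probs) >= 0))
})

test_that("CEAC splits tie mass equally", {
  # identical strategies tie in every iteration at any lambda
  psa <- mk_psa(rep(1, 8), rep(25, 8), rep(1, 8), rep(25, 8))
  ceac <- multiway_ceac(psa, c(0, 20000))
  expect_true(all(ceac$probability == 0.5))
})

test_that("CE plane export matches the pairwise probability and quadrants", {
  fx <- with_constant_posterior(fx_small())
  cfg <- zero_param_variance(fx$config)
  cfg$psa$n_iterations <- 40
  psa <- run_psa(cfg, fx)
  plane <- ce_plane_export(psa, lambda = cfg$lambda)
  # zero-variance QALYs: points coincide per strategy
  for (s in unique(plane$strategy)) {
    dq <- plane$delta_qalys[plane$strategy == s]
    expect_equal(max(dq) - min(dq), 0, tolerance = 1e-12)
  }
  # indicator fraction equals the pairwise probability
  for (s in unique(plane$strategy)) {
    expect_equal(mean(plane$cost_effective[plane$strategy == s]),
                 pairwise_prob_ce(psa, s, "usual_care", cfg$lambda))
  }
  # constructed dominant strategy: all points in the right half, all CE
  dom <- mk_psa(rep(1, 6), rep(40, 6), rep(1.3, 6), rep(5, 6))
  pl <- ce_plane_export(dom, lambda = 20000)
  expect_true(all(pl$delta_qalys > 0))
  expect_true(all(pl$cost_effective))
})
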