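# Probabilistic sensitivity analysis: Monte Carlo propagation of parameter
# uncertainty. Treatment effects come from (synthetic) posterior draws so
# their cross-timepoint correlation is preserved within a draw; the baseline
# FSS and the mapping coefficients are normal (baseline truncated to the
# instrument range by resampling); intervention costs are gamma.

# Truncated-normal draws by resampling; sd = 0 degenerates to the mean.
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:1000) {
    bad <- x < lo | x > hi
    if (!any(bad)) return(x)
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  stop("truncated-normal resampling did not converge; check the bounds")
}

# Posterior draws table -> per-strategy matrix n_avail x 3 (eot, st, lt),
# NA columns for timepoints without evidence.
posterior_matrices <- function(post, strategies) {
  out <- list()
  for (strat in strategies) {
    p <- post[post$strategy == strat, ]
    if (!nrow(p)) stop("no posterior draws for strategy '", strat, "'")
    n_avail <- max(p$draw)
    m <- matrix(NA_real_, n_avail, 3,
                dimnames = list(NULL, c("eot", "st", "lt")))
    for (tp in unique(p$timepoint)) {
      rows <- p[p$timepoint == tp, ]
      m[rows$draw, tolower(tp)] <- rows$smd
    }
    out[[strat]] <- m
  }
  out
}

#' Sample one set of PSA parameter draws
#'
#' Draws `n` joint parameter sets: per-strategy SMDs taken row-wise from the
#' posterior draws (preserving within-draw correlation across timepoints),
#' baseline FSS from a truncated normal, mapping coefficients from normals
#' (independent unless a covariance is configured and
#' `psa$independent_coefficients` is `FALSE`), and per-strategy costs from
#' gamma distributions matched to the category cost mean and SE.
#'
#' Posterior draws are consumed without replacement: asking for more
#' iterations than there are draws is an error unless
#' `psa$with_replacement` is `TRUE`. With
#' `psa$common_random_numbers = FALSE` the baseline and coefficient draws
#' are made independently per strategy (matrices instead of vectors),
#' increasing comparison variance.
#'
#' @param config Model configuration.
#' @param inputs Model inputs bundle.
#' @param n Number of parameter sets (default `config$psa$n_iterations`).
#' @param seed Integer seed (default `config$psa$seed`); identical seed and
#'   inputs give identical draws.
#' @return List with `baseline`, `intercept`, `slope` (vectors, or `n x
#'   strategy` matrices without common random numbers), `costs` (`n x
#'   strategy` matrix, usual care 0), `smd` (list of `n x 3` matrices) and
#'   bookkeeping fields.
#' @export
sample_parameters <- function(config, inputs,
                              n = config$psa$n_iterations,
                              seed = config$psa$seed) {
  validate_config(config)
  strategies <- inputs$strategies$strategy
  interventions <- setdiff(strategies, "usual_care")
  post <- model_posterior(inputs, config)
  mats <- posterior_matrices(post, interventions)
  n_avail <- unique(vapply(mats, nrow, integer(1)))
  if (length(n_avail) != 1)
    stop("strategies carry different numbers of posterior draws")
  set.seed(seed)
  idx <- if (n <= n_avail) {
    seq_len(n)
  } else if (isTRUE(config$psa$with_replacement)) {
    sample.int(n_avail, n, replace = TRUE)
  } else {
    stop(n, " iterations requested but only ", n_avail, " posterior draws ",
         "are available; set psa$with_replacement = TRUE to bootstrap")
  }

  b <- config$baseline
  m <- config$mapping
  crn <- !isFALSE(config$psa$common_random_numbers)
  n_col <- if (crn) 1L else length(strategies)
  baseline <- matrix(0, n, n_col)
  intercept <- matrix(0, n, n_col)
  slope <- matrix(0, n, n_col)
  for (j in seq_len(n_col)) {
    baseline[, j] <- rtrunc_norm(n, b$mean_fss, b$se_fss,
                                 config$fss_min, config$fss_max)
    if (!is.null(m$covariance) &&
          isFALSE(config$psa$independent_coefficients)) {
      sigma <- matrix(c(m$se_intercept^2, m$covariance,
                        m$covariance, m$se_slope^2), 2, 2)
      cs <- rmvnorm_chol(n, c(m$intercept, m$slope), sigma)
      intercept[, j] <- cs[, 1]; slope[, j] <- cs[, 2]
    } else {
      intercept[, j] <- if (m$se_intercept > 0)
        stats::rnorm(n, m$intercept, m$se_intercept) else rep(m$intercept, n)
      slope[, j] <- if (m$se_slope > 0)
        stats::rnorm(n, m$slope, m$se_slope) else rep(m$slope, n)
    }
  }

  cc <- deterministic_costs(inputs, config)
  costs <- matrix(0, n, length(strategies),
                  dimnames = list(NULL, strategies))
  for (strat in interventions) {
    mu <- cc$cost[[strat]]; se <- cc$se[[strat]]
    costs[, strat] <- if (se > 0) {
      gp <- gamma_params(mu, se)
      stats::rgamma(n, shape = gp$shape, rate = gp$rate)
    } else rep(mu, n)
  }

  smd <- lapply(mats, function(mm) mm[idx, , drop = FALSE])
  list(baseline = baseline, intercept = intercept, slope = slope,
       costs = costs, smd = smd, n = n, strategies = strategies,
       common_random_numbers = crn, draw_index = idx)
}

# Node weights and the linear FSS response of one strategy's trajectory.
# Because interpolation is linear in the knot values and the waning knots sit
# at zero effect, the node-level FSS is affine in the SMD vector:
#   fss(nodes) = baseline + D %*% smd
# with D built by differencing unit-SMD trajectories against the zero-effect
# one. Clamping and the utility mapping are applied after, per draw, so this
# is arithmetic-identical to building each trajectory explicitly.
strategy_linear_map <- function(eff_rows, baseline, config, force_zero) {
  sched <- strategy_schedule(eff_rows, config$horizon_months)
  present <- tolower(eff_rows$timepoint)
  zero <- c(eot = NA_real_, st = NA_real_, lt = NA_real_)
  zero[present] <- 0
  tr0 <- build_intervention_trajectory(baseline, zero, sched,
                                       sd_fss = config$baseline$sd_fss,
                                       waning_mode = config$waning_mode,
                                       force_zero_st = force_zero)
  qw <- quadrature_weights(tr0$knots$time, config$horizon_months,
                           config$quad_step, config$discount_rate,
                           config$discount_method)
  f0 <- trajectory_fss(tr0, qw$nodes)
  D <- matrix(0, length(qw$nodes), 3,
              dimnames = list(NULL, c("eot", "st", "lt")))
  for (tp in present) {
    unit <- zero; unit[tp] <- 1
    tru <- build_intervention_trajectory(baseline, unit, sched,
                                         sd_fss = config$baseline$sd_fss,
                                         waning_mode = config$waning_mode,
                                         force_zero_st = force_zero)
    D[, tp] <- trajectory_fss(tru, qw$nodes) - f0
  }
  list(w = qw$w, f0 = f0, D = D, present = present)
}

#' Run the probabilistic sensitivity analysis
#'
#' Propagates `n_iterations` joint parameter draws through the model. Within
#' an iteration all strategies share the baseline and coefficient draw
#' (common random numbers, the default), so incremental comparisons are
#' within one internally-consistent model realisation.
#'
#' @param config Model configuration (`psa$n_iterations`, `psa$seed` control
#'   the run).
#' @param inputs Model inputs bundle.
#' @param params Optional pre-drawn parameter set from [sample_parameters()];
#'   drawn internally when `NULL`.
#' @return Long data frame `iteration, strategy, cost, qalys`, one row per
#'   iteration and strategy; class `"psa_output"`.
#' @export
#' @examples
#' fx <- reference_fixture(n_draws = 100)
#' fx$config$psa$n_iterations <- 100
#' psa <- run_psa(fx$config, fx)
#' summarize_psa(psa, lambda = fx$config$lambda)
run_psa <- function(config, inputs, params = NULL) {
  validate_config(config)
  if (is.null(params)) params <- sample_parameters(config, inputs)
  strategies <- inputs$strategies$strategy
  eff <- model_effects(inputs, config)
  baseline0 <- config_baseline(config)
  n <- params$n
  m <- config$mapping
  col_of <- function(strat) {
    if (params$common_random_numbers) 1L else match(strat, strategies)
  }
  qmat <- matrix(NA_real_, n, length(strategies),
                 dimnames = list(NULL, strategies))
  # usual care: flat at the sampled baseline
  uc_w <- quadrature_weights(c(0, config$horizon_months),
                             config$horizon_months, config$quad_step,
                             config$discount_rate, config$discount_method)
  for (strat in strategies) {
    j <- col_of(strat)
    bl <- params$baseline[, j]
    itc <- params$intercept[, j]
    slp <- params$slope[, j]
    if (strat == "usual_care") {
      fss <- clamp(bl, config$fss_min, config$fss_max)
      u <- clamp(itc + slp * fss, m$utility_floor, m$utility_ceiling)
      qmat[, strat] <- u * sum(uc_w$w)
      next
    }
    e <- eff[eff$strategy == strat, ]
    lm <- strategy_linear_map(e, baseline0, config,
                              force_zero = strat %in% config$force_zero_st)
    smd <- params$smd[[strat]]
    smd_active <- smd[, lm$present, drop = FALSE]
    fss <- matrix(bl, n, length(lm$w)) +
      smd_active %*% t(lm$D[, lm$present, drop = FALSE])
    fss <- clamp(fss, config$fss_min, config$fss_max)
    u <- clamp(fss * slp + itc, m$utility_floor, m$utility_ceiling)
    qmat[, strat] <- as.vector(u %*% lm$w)
  }
  if (any(!is.finite(qmat)))
    stop("PSA produced non-finite QALYs (",
         sum(!is.finite(qmat)), " cells); check inputs")
  out <- data.frame(
    iteration = rep(seq_len(n), times = length(strategies)),
    strategy = rep(strategies, each = n),
    cost = as.vector(params$costs[, strategies]),
    qalys = as.vector(qmat)
  )
  class(out) <- c("psa_output", class(out))
  out
}

#' Summarise a PSA run
#'
#' Arithmetic means of costs and QALYs over iterations per strategy, with the
#' incremental net monetary benefit computed per iteration and then averaged
#' (identical, by linearity, to the INMB of the means).
#'
#' @param psa_output Output of [run_psa()].
#' @param lambda Willingness-to-pay threshold, GBP per QALY.
#' @param comparator Comparator strategy (default `"usual_care"`).
#' @return Data frame, one row per strategy: `cost`, `qalys`, `inc_cost`,
#'   `inc_qalys`, `nmb`, `inmb`.
#' @export
summarize_psa <- function(psa_output, lambda = 20000,
                          comparator = "usual_care") {
  if (!nrow(psa_output)) stop("empty PSA output")
  strategies <- unique(psa_output$strategy)
  if (!comparator %in% strategies)
    stop("comparator '", comparator, "' not present in the PSA output")
  mean_by <- function(col) {
    v <- tapply(psa_output[[col]], psa_output$strategy, mean)
    v[strategies]
  }
  cost <- mean_by("cost"); qalys <- mean_by("qalys")
  res <- data.frame(strategy = strategies, cost = unname(cost),
                    qalys = unname(qalys))
  res$inc_cost <- res$cost - cost[[comparator]]
  res$inc_qalys <- res$qalys - qalys[[comparator]]
  res$nmb <- nmb(res$qalys, res$cost, lambda)
  res$inmb <- res$nmb - nmb(qalys[[comparator]], cost[[comparator]], lambda)
  res
}
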