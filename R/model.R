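# Deterministic evaluation of the full model: point-estimate SMDs -> FSS
# trajectories -> discounted QALYs, median category costs, NMB/INMB/ICER
# versus usual care.

model_effects <- function(inputs, config) {
  src <- config$effects_source
  eff <- inputs$effects[[src]]
  if (is.null(eff))
    stop("inputs carry no effects table for source '", src, "'")
  eff
}

model_posterior <- function(inputs, config) {
  src <- config$effects_source
  post <- inputs$posterior[[src]]
  if (is.null(post))
    stop("inputs carry no posterior draws for source '", src, "'")
  post
}

# Trajectories for every strategy at given SMD values (named list strategy ->
# c(eot, st, lt)); usual care is flat at the baseline.
model_trajectories <- function(inputs, config, baseline,
                               smds_by_strategy = NULL) {
  eff <- model_effects(inputs, config)
  out <- list()
  for (strat in inputs$strategies$strategy) {
    if (strat == "usual_care") {
      sched <- timepoint_schedule(1, horizon = config$horizon_months)
      out[[strat]] <- build_usual_care_trajectory(baseline, sched)
      next
    }
    e <- eff[eff$strategy == strat, ]
    if (!nrow(e)) stop("no effect estimates for strategy '", strat, "'")
    smds <- if (is.null(smds_by_strategy)) strategy_smds(e)
            else smds_by_strategy[[strat]]
    out[[strat]] <- build_intervention_trajectory(
      baseline, smds, strategy_schedule(e, config$horizon_months),
      sd_fss = config$baseline$sd_fss,
      waning_mode = config$waning_mode,
      force_zero_st = strat %in% config$force_zero_st)
  }
  out
}

# Point-estimate cost per strategy under the configured basis
# (median / low / high); usual care costs nothing.
deterministic_costs <- function(inputs, config) {
  cc <- category_costs(inputs$cost_records, config$price_index)
  col <- switch(config$cost_basis, median = "median_cost", low = "low",
                high = "high")
  costs <- stats::setNames(cc[[col]], cc$strategy)
  ses <- stats::setNames(cc$se, cc$strategy)
  full <- stats::setNames(numeric(nrow(inputs$strategies)),
                          inputs$strategies$strategy)
  full[names(costs)] <- costs
  se_full <- stats::setNames(numeric(nrow(inputs$strategies)),
                             inputs$strategies$strategy)
  se_full[names(ses)] <- ses
  list(cost = full, se = se_full)
}

#' Run the deterministic model
#'
#' Evaluates every strategy at the point estimates: mean SMDs from the active
#' effects source, the mean baseline FSS, the central mapping coefficients
#' and the configured cost basis. Returns the base-case results table with
#' incremental quantities, NMB, INMB and the ICER classification versus
#' usual care.
#'
#' @param config A validated model configuration.
#' @param inputs A `"fatigue_model_inputs"` bundle (see [reference_fixture()]
#'   or [read_model_inputs()]).
#' @return Data frame of class `"cea_results"`: one row per strategy with
#'   `cost`, `qalys`, `inc_cost`, `inc_qalys`, `nmb`, `inmb`, `icer`,
#'   `icer_class`.
#' @export
#' @examples
#' fx <- reference_fixture(n_draws = 10)
#' run_deterministic(fx$config, fx)
run_deterministic <- function(config, inputs) {
  validate_config(config)
  coeffs <- config_mapping(config)
  baseline <- config_baseline(config)
  trajs <- model_trajectories(inputs, config, baseline)
  qalys <- vapply(trajs, function(tr)
    discounted_qalys(tr, coeffs, config$discount_rate, config$quad_step,
                     config$discount_method,
                     config$mapping$utility_floor,
                     config$mapping$utility_ceiling,
                     config$fss_min, config$fss_max),
    numeric(1))
  costs <- deterministic_costs(inputs, config)$cost
  strategies <- inputs$strategies$strategy
  res <- data.frame(
    strategy = strategies,
    delivery = inputs$strategies$delivery,
    cost = unname(costs[strategies]),
    qalys = unname(qalys[strategies])
  )
  uc <- res[res$strategy == "usual_care", ]
  if (!nrow(uc)) stop("inputs must include a 'usual_care' strategy")
  res$inc_cost <- res$cost - uc$cost
  res$inc_qalys <- res$qalys - uc$qalys
  res$nmb <- nmb(res$qalys, res$cost, config$lambda)
  res$inmb <- res$nmb - nmb(uc$qalys, uc$cost, config$lambda)
  ic <- lapply(seq_len(nrow(res)), function(i)
    icer(list(cost = res$cost[i], qalys = res$qalys[i]),
         list(cost = uc$cost, qalys = uc$qalys)))
  res$icer <- vapply(ic, function(x) x$value, numeric(1))
  res$icer_class <- vapply(ic, function(x) x$class, character(1))
  res$icer_class[res$strategy == "usual_care"] <- "comparator"
  class(res) <- c("cea_results", class(res))
  res
}
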