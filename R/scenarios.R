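#' Construct a scenario overlay
#'
#' A scenario is a named set of parameter overrides applied on top of the
#' base configuration; scenarios never contain code, only re-valued
#' parameters, so every analysis variant is auditable from its overlay.
#'
#' @param id Scenario label.
#' @param overrides Named list mapping dotted config paths (see
#'   [config_set()]) to replacement values. May be empty (the base case).
#' @param description Free-text description.
#' @return An object of class `"fatigue_scenario"`.
#' @export
scenario <- function(id, overrides = list(), description = "") {
  stopifnot(is.character(id), length(id) == 1, is.list(overrides))
  if (length(overrides) && is.null(names(overrides)))
    stop("overrides must be a named list of config paths")
  structure(list(id = id, overrides = overrides,
                 description = description),
            class = "fatigue_scenario")
}

#' @export
print.fatigue_scenario <- function(x, ...) {
  cat(sprintf("<scenario '%s'> %s\n", x$id, x$description))
  for (p in names(x$overrides))
    cat("  ", p, " <- ", paste(format(x$overrides[[p]]), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Apply a scenario overlay to a configuration
#'
#' Every override path must exist in the base configuration; an unknown path
#' is an error naming the path. The base config is never modified (R copy
#' semantics; verified by the test suite).
#'
#' @param config Base configuration.
#' @param scn A [scenario()].
#' @return The overlaid configuration.
#' @export
apply_scenario <- function(config, scn) {
  stopifnot(inherits(scn, "fatigue_scenario"))
  for (p in names(scn$overrides))
    config <- config_set(config, p, scn$overrides[[p]])
  validate_config(config)
  config
}

#' Build the standard scenario set
#'
#' Emits the model's scenario analyses as overlays over the base
#' configuration:
#' pessimistic and optimistic persistence of the treatment effect (15- and
#' 48-month horizons and an immediate return to baseline after the last
#' follow-up); an alternative baseline FSS mean and SD; delivery-specific
#' CBT-Fatigue treatment effects; the earliest-LT-follow-up effect set with
#' its adjusted LT timing; forcing the short-term effect of the
#' no-ST-evidence strategies (mindfulness) to zero; lower and upper
#' intervention cost bounds; and 1.5% and 6% discount rates.
#'
#' @param base_config Base configuration; alternative values for the
#'   baseline scenario and the force-zero-ST strategy list are read from its
#'   `scenario` section.
#' @return Named list of [scenario()] objects (11 scenarios).
#' @export
build_scenarios <- function(base_config) {
  validate_config(base_config)
  sc <- base_config$scenario
  scns <- list(
    scenario("horizon_15", list(horizon_months = 15),
             "pessimistic treatment-effect persistence: 15-month horizon"),
    scenario("horizon_48", list(horizon_months = 48),
             "optimistic treatment-effect persistence: 48-month horizon"),
    scenario("waning_immediate", list(waning_mode = "immediate_return"),
             "effect returns to baseline immediately after last follow-up"),
    scenario("alt_baseline",
             list(baseline.mean_fss = sc$alt_baseline_mean_fss,
                  baseline.sd_fss = sc$alt_baseline_sd_fss),
             "alternative baseline FSS mean and SD"),
    scenario("cbt_separate", list(effects_source = "cbt_separate"),
             "delivery-specific treatment effects for CBT-Fatigue"),
    scenario("earliest_lt", list(effects_source = "earliest_lt"),
             "earliest LT follow-up effects with adjusted LT timing"),
    scenario("mindfulness_st_zero",
             list(force_zero_st = sc$force_zero_st_strategies),
             "zero short-term effect where no ST evidence exists"),
    scenario("costs_low", list(cost_basis = "low"),
             "lowest per-study intervention costs"),
    scenario("costs_high", list(cost_basis = "high"),
             "highest per-study intervention costs"),
    scenario("discount_1.5", list(discount_rate = 0.015),
             "1.5% annual discount rate"),
    scenario("discount_6", list(discount_rate = 0.06),
             "6% annual discount rate")
  )
  stats::setNames(scns, vapply(scns, `[[`, "", "id"))
}

#' Run the base case plus a scenario set
#'
#' Evaluates every scenario as a configuration overlay over a single model
#' definition, deterministically or probabilistically, and flags strategies
#' whose INMB sign differs from the base case.
#'
#' @param config Base configuration.
#' @param inputs Model inputs bundle.
#' @param scenarios List of [scenario()] objects; defaults to
#'   [build_scenarios()].
#' @param mode `"deterministic"` or `"probabilistic"`.
#' @return Data frame with one row per scenario and strategy, columns as in
#'   [run_deterministic()] plus `scenario` and `inmb_sign_flip`.
#' @export
run_scenarios <- function(config, inputs,
                          scenarios = build_scenarios(config),
                          mode = c("deterministic", "probabilistic")) {
  mode <- match.arg(mode)
  validate_config(config)
  run_one <- function(cfg, id) {
    res <- tryCatch({
      if (mode == "deterministic") {
        run_deterministic(cfg, inputs)
      } else {
        summarize_psa(run_psa(cfg, inputs), lambda = cfg$lambda)
      }
    }, error = function(e)
      stop("scenario '", id, "': ", conditionMessage(e), call. = FALSE))
    res$scenario <- id
    res
  }
  base <- run_one(config, "base_case")
  rows <- list(base)
  for (scn in scenarios)
    rows[[scn$id]] <- run_one(apply_scenario(config, scn), scn$id)
  out <- do.call(rbind, lapply(rows, as.data.frame))
  rownames(out) <- NULL
  base_sign <- sign(base$inmb)[match(out$strategy, base$strategy)]
  out$inmb_sign_flip <- out$strategy != "usual_care" &
    sign(out$inmb) != base_sign
  out
}
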