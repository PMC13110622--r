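#' Default model configuration
#'
#' Returns the full set of scalar model parameters as a nested list. These are
#' the base-case settings of the cost-utility model: baseline Fatigue Severity
#' Scale (FSS) score and the population SD used to convert standardised mean
#' differences (SMDs) to FSS points, the linear FSS to SF-6D mapping
#' coefficients, the willingness-to-pay threshold, discounting, the model
#' horizon and the treatment-effect waning assumption, and the probabilistic
#' sensitivity analysis (PSA) settings.
#'
#' The mapping coefficients shipped here are a clearly-labelled synthetic
#' placeholder for the published FSS to SF-6D regression (whose coefficients
#' are not reproduced in this package); they are chosen so that the utility at
#' the baseline FSS of 43.73 is about 0.635, a plausible SF-6D value for a
#' population with moderate-to-severe fatigue. Replace them via a config file
#' when the real coefficients are available.
#'
#' @section Key entries:
#' \describe{
#'   \item{baseline}{`mean_fss` (43.73), `se_fss` (15.10, the sampling SD
#'     implied by the reported 95% CI, used in the PSA), `sd_fss` (15.1, the
#'     population SD used for SMD conversion).}
#'   \item{mapping}{`intercept`, `slope` (utility per FSS point, negative),
#'     their standard errors, optional `covariance`, and the utility clamp
#'     `utility_floor`/`utility_ceiling`.}
#'   \item{lambda}{willingness-to-pay threshold, GBP per QALY (20000).}
#'   \item{discount_rate}{annual rate (0.035); `discount_method` is
#'     `"continuous"` (default) or `"annual"` step weights.}
#'   \item{horizon_months}{model horizon (24).}
#'   \item{waning_mode}{`"linear_to_horizon"`, `"immediate_return"` or
#'     `"none_beyond_followup"`.}
#'   \item{psa}{`n_iterations` (5000), `seed`, `with_replacement`,
#'     `common_random_numbers`, `independent_coefficients`.}
#' }
#'
#' @return A named list, class `"fatigue_config"`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$lambda
default_config <- function() {
  cfg <- list(
    baseline = list(mean_fss = 43.73, se_fss = 15.10, sd_fss = 15.1),
    mapping = list(
      intercept = 0.832, slope = -0.0045,
      se_intercept = 0.02, se_slope = 5e-04,
      covariance = NULL,
      utility_floor = 0, utility_ceiling = 1
    ),
    fss_min = 9, fss_max = 63,
    lambda = 20000,
    lambda_grid = seq(0, 50000, by = 1000),
    discount_rate = 0.035,
    discount_method = "continuous",
    horizon_months = 24,
    waning_mode = "linear_to_horizon",
    quad_step = 0.25,
    smd_improves_when_negative = TRUE,
    effects_source = "base",
    cost_basis = "median",
    force_zero_st = character(0),
    price_index = list(target_year = 2023,
                       index = c("2017" = 268.4, "2023" = 319.4)),
    psa = list(n_iterations = 5000, seed = 1L, with_replacement = FALSE,
               common_random_numbers = TRUE, independent_coefficients = TRUE),
    scenario = list(
      alt_baseline_mean_fss = 47.2,
      alt_baseline_sd_fss = 12.6,
      force_zero_st_strategies = c("mindfulness_individual",
                                   "mindfulness_group")
    )
  )
  structure(cfg, class = "fatigue_config")
}

#' Validate a model configuration
#'
#' Checks types, ranges and cross-field consistency of a configuration list.
#' Called by the model runners; exported so hand-edited configs can be checked
#' eagerly.
#'
#' @param config A configuration list, typically from [default_config()] or
#'   [load_config()].
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  stopifnot(is.list(config))
  req <- c("baseline", "mapping", "lambda", "discount_rate", "horizon_months",
           "waning_mode", "quad_step", "fss_min", "fss_max", "psa")
  missing <- setdiff(req, names(config))
  if (length(missing))
    stop("config is missing entries: ", paste(missing, collapse = ", "))
  b <- config$baseline
  if (!is.numeric(b$sd_fss) || b$sd_fss <= 0)
    stop("baseline$sd_fss must be > 0")
  if (b$mean_fss < config$fss_min || b$mean_fss > config$fss_max)
    stop("baseline$mean_fss outside the FSS instrument range [",
         config$fss_min, ", ", config$fss_max, "]")
  if (b$se_fss < 0) stop("baseline$se_fss must be >= 0")
  m <- config$mapping
  if (m$se_intercept < 0 || m$se_slope < 0)
    stop("mapping standard errors must be >= 0")
  if (m$utility_floor >= m$utility_ceiling)
    stop("mapping$utility_floor must be below mapping$utility_ceiling")
  if (config$lambda < 0) stop("lambda must be >= 0")
  if (config$discount_rate < 0) stop("discount_rate must be >= 0")
  if (!config$discount_method %in% c("continuous", "annual"))
    stop("discount_method must be 'continuous' or 'annual'")
  if (config$horizon_months <= 0) stop("horizon_months must be > 0")
  if (!config$waning_mode %in%
        c("linear_to_horizon", "immediate_return", "none_beyond_followup"))
    stop("unknown waning_mode: ", config$waning_mode)
  if (config$quad_step <= 0) stop("quad_step must be > 0")
  if (!config$cost_basis %in% c("median", "low", "high"))
    stop("cost_basis must be one of 'median', 'low', 'high'")
  if (config$psa$n_iterations < 1) stop("psa$n_iterations must be >= 1")
  invisible(config)
}

#' Read a configuration file
#'
#' Loads a JSON configuration and merges it over [default_config()], so a file
#' only needs to state the parameters it changes. Nested sections are merged
#' recursively.
#'
#' @param path Path to a JSON file.
#' @return A validated `"fatigue_config"` list.
#' @export
load_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- utils::modifyList(unclass(default_config()), user)
  if (!is.null(cfg$price_index$index))
    cfg$price_index$index <- unlist(cfg$price_index$index)
  cfg <- structure(cfg, class = "fatigue_config")
  validate_config(cfg)
  cfg
}

#' Write a configuration file
#'
#' @param config A configuration list.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- unclass(config)
  # named atomic vectors lose their names in JSON arrays; keep the price
  # index as an object
  if (!is.null(config$price_index$index))
    config$price_index$index <- as.list(config$price_index$index)
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Set one configuration parameter by dotted path
#'
#' Scenario overlays use this to change a single parameter, e.g.
#' `config_set(cfg, "psa.n_iterations", 1000)` or
#' `config_set(cfg, "discount_rate", 0.015)`. The path must already exist in
#' the base configuration: overlays can re-value parameters but never invent
#' them, which keeps scenarios auditable.
#'
#' @param config A configuration list.
#' @param path Dotted parameter path, e.g. `"baseline.mean_fss"`.
#' @param value Replacement value.
#' @return The modified config.
#' @export
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node))
      stop("config override path not found: '", path, "'")
    node <- node[[k]]
  }
  config[[keys]] <- value
  config
}

#' @export
print.fatigue_config <- function(x, ...) {
  cat("<fatigue_config>\n")
  cat(sprintf("  baseline FSS %.2f (SD %.2f for SMD conversion)\n",
              x$baseline$mean_fss, x$baseline$sd_fss))
  cat(sprintf("  mapping u = %.4f %+.5f * FSS, clamped to [%g, %g]\n",
              x$mapping$intercept, x$mapping$slope,
              x$mapping$utility_floor, x$mapping$utility_ceiling))
  cat(sprintf("  lambda GBP %s/QALY; discount %.1f%% (%s); horizon %g months; waning %s\n",
              format(x$lambda, big.mark = ","), 100 * x$discount_rate,
              x$discount_method, x$horizon_months, x$waning_mode))
  cat(sprintf("  PSA: %d iterations, seed %s\n",
              x$psa$n_iterations, x$psa$seed))
  invisible(x)
}
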