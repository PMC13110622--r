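#' Linear FSS to utility mapping coefficients
#'
#' Container for the intercept and slope of a linear algorithm mapping Fatigue
#' Severity Scale (FSS) total scores to a preference-based utility index
#' (SF-6D), plus their standard errors and an optional intercept-slope
#' covariance used when sampling the coefficients jointly in the PSA.
#'
#' The slope must be negative (more fatigue, lower utility) unless
#' `allow_positive_slope = TRUE` is given, which exists for deliberately
#' degenerate test mappings such as a flat line.
#'
#' @param intercept Utility at FSS = 0.
#' @param slope Utility change per FSS point; `< 0` for a valid fatigue
#'   mapping.
#' @param se_intercept,se_slope Standard errors, `>= 0`.
#' @param covariance Optional intercept-slope covariance. When `NULL` the two
#'   coefficients are treated as independent in the PSA.
#' @param allow_positive_slope Skip the sign check.
#' @return An object of class `"mapping_coefficients"`.
#' @export
#' @examples
#' mc <- mapping_coefficients(0.832, -0.0045)
#' fss_to_utility(43.73, mc)
mapping_coefficients <- function(intercept, slope, se_intercept = 0,
                                 se_slope = 0, covariance = NULL,
                                 allow_positive_slope = FALSE) {
  stopifnot(is.numeric(intercept), is.numeric(slope),
            length(intercept) == 1, length(slope) == 1)
  if (!allow_positive_slope && slope >= 0)
    stop("mapping slope must be negative (higher FSS -> lower utility); ",
         "use allow_positive_slope = TRUE to override")
  if (se_intercept < 0 || se_slope < 0)
    stop("coefficient standard errors must be >= 0")
  if (!is.null(covariance)) {
    stopifnot(is.numeric(covariance), length(covariance) == 1)
    # Cauchy-Schwarz: |cov| cannot exceed the product of the SDs
    if (abs(covariance) > se_intercept * se_slope + 1e-12)
      stop("covariance inconsistent with the stated standard errors")
  }
  structure(list(intercept = intercept, slope = slope,
                 se_intercept = se_intercept, se_slope = se_slope,
                 covariance = covariance),
            class = "mapping_coefficients")
}

#' @export
print.mapping_coefficients <- function(x, ...) {
  cat(sprintf("<mapping_coefficients> u = %.4f %+.5f * FSS  (SEs %.4g, %.4g)\n",
              x$intercept, x$slope, x$se_intercept, x$se_slope))
  invisible(x)
}

#' Baseline fatigue parameters
#'
#' @param mean_fss Mean baseline FSS total score (instrument range 9-63).
#' @param se_fss Sampling SD used when drawing the baseline in the PSA
#'   (truncated normal); `0` fixes the baseline at `mean_fss`.
#' @param sd_fss Population SD of the FSS used to convert SMDs to FSS points.
#' @param fss_min,fss_max Instrument range.
#' @return An object of class `"baseline_fatigue"`.
#' @export
baseline_fatigue <- function(mean_fss, se_fss = 0, sd_fss,
                             fss_min = 9, fss_max = 63) {
  stopifnot(is.numeric(mean_fss), is.numeric(sd_fss))
  if (sd_fss <= 0) stop("sd_fss must be > 0")
  if (se_fss < 0) stop("se_fss must be >= 0")
  if (mean_fss < fss_min || mean_fss > fss_max)
    stop("mean_fss outside the FSS instrument range [", fss_min, ", ",
         fss_max, "]")
  structure(list(mean_fss = mean_fss, se_fss = se_fss, sd_fss = sd_fss,
                 fss_min = fss_min, fss_max = fss_max),
            class = "baseline_fatigue")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Convert an SMD to an FSS difference
#'
#' Treatment effects are pooled on the standardised mean difference scale;
#' multiplying by the population SD of the baseline FSS (15.1 in the base
#' case) re-expresses them in FSS points. The sign convention is that a
#' negative SMD means less fatigue than usual care.
#'
#' @param smd Standardised mean difference(s), dimensionless.
#' @param sd_fss Population SD of baseline FSS, `> 0`.
#' @return FSS point difference(s), same sign as `smd`.
#' @export
#' @examples
#' smd_to_fss_diff(-0.5, 15.1) # -7.55 FSS points
smd_to_fss_diff <- function(smd, sd_fss) {
  if (!is.numeric(sd_fss) || length(sd_fss) != 1 || sd_fss <= 0)
    stop("sd_fss must be a single positive number")
  smd * sd_fss
}

#' Absolute FSS score from baseline and difference
#'
#' `baseline + difference`, clamped to the FSS instrument range. Usual care
#' has difference 0 at every time point.
#'
#' @param baseline_fss Baseline FSS score(s).
#' @param fss_diff FSS difference(s) versus usual care.
#' @param fss_min,fss_max Instrument range for clamping.
#' @return Absolute FSS score(s) within `[fss_min, fss_max]`.
#' @export
absolute_fss <- function(baseline_fss, fss_diff, fss_min = 9, fss_max = 63) {
  clamp(baseline_fss + fss_diff, fss_min, fss_max)
}

#' Map FSS scores to utility
#'
#' Evaluates the linear mapping `intercept + slope * fss` and clamps the
#' result to the configured utility range (default `[0, 1]`).
#'
#' @param fss FSS score(s).
#' @param coeffs A [mapping_coefficients()] object.
#' @param utility_floor,utility_ceiling Clamp range for the utility index.
#' @return Utility value(s).
#' @export
fss_to_utility <- function(fss, coeffs, utility_floor = 0,
                           utility_ceiling = 1) {
  stopifnot(inherits(coeffs, "mapping_coefficients"))
  clamp(coeffs$intercept + coeffs$slope * fss, utility_floor, utility_ceiling)
}

# Internal: build the mapping / baseline objects out of a config list.
config_mapping <- function(config) {
  m <- config$mapping
  mapping_coefficients(m$intercept, m$slope, m$se_intercept, m$se_slope,
                       m$covariance,
                       allow_positive_slope = isTRUE(m$allow_positive_slope))
}

config_baseline <- function(config) {
  b <- config$baseline
  baseline_fatigue(b$mean_fss, b$se_fss, b$sd_fss,
                   fss_min = config$fss_min, fss_max = config$fss_max)
}
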