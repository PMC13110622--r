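#' Validate a table of intervention delivery records
#'
#' A cost record describes how one study arm delivered its intervention: the
#' number of sessions, session length, the hourly unit cost of the staff
#' delivering it, and (for group delivery) the group structure. Several rows
#' may share a `study_id` when more than one staff role was involved; their
#' per-patient costs are summed by [study_cost_per_patient()].
#'
#' @param records Data frame with columns `study_id`, `strategy`, `delivery`
#'   (`"individual"` or `"group"`), `n_sessions`, `session_minutes`,
#'   `staff_unit_cost` (GBP per hour), and optionally `price_year`,
#'   `n_participants`, `n_groups` (default 1) and `staff_per_group`
#'   (default 1).
#' @return The records with defaults filled in, invisibly classed
#'   `"cost_records"`.
#' @export
cost_records <- function(records) {
  req <- c("study_id", "strategy", "delivery", "n_sessions",
           "session_minutes", "staff_unit_cost")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("cost records missing columns: ", paste(missing, collapse = ", "))
  if (!all(records$delivery %in% c("individual", "group")))
    stop("delivery must be 'individual' or 'group'")
  if (any(records$n_sessions < 1)) stop("n_sessions must be >= 1")
  if (any(records$session_minutes <= 0)) stop("session_minutes must be > 0")
  if (any(records$staff_unit_cost <= 0)) stop("staff_unit_cost must be > 0")
  if (is.null(records$n_groups)) records$n_groups <- 1
  records$n_groups[is.na(records$n_groups)] <- 1 # "assumed one if not stated"
  if (is.null(records$staff_per_group)) records$staff_per_group <- 1
  records$staff_per_group[is.na(records$staff_per_group)] <- 1
  if (is.null(records$n_participants)) records$n_participants <- NA_real_
  if (is.null(records$price_year)) records$price_year <- NA_real_
  grp <- records$delivery == "group"
  if (any(grp & (is.na(records$n_participants) | records$n_participants < 1)))
    stop("group records require n_participants >= 1")
  class(records) <- unique(c("cost_records", class(records)))
  records
}

#' Per-patient cost of one delivery record
#'
#' Staff time valued at the hourly unit cost:
#' `n_sessions * (session_minutes / 60) * staff_unit_cost * staff_per_group`,
#' multiplied by `n_groups` and divided by `n_participants` for group
#' delivery (the whole-group staff cost is shared across the people who
#' started the intervention).
#'
#' @param record A one-row data frame (or list) with the [cost_records()]
#'   fields; vectorised over rows when given a multi-row data frame.
#' @return Per-patient cost(s) in GBP.
#' @export
#' @examples
#' cost_per_patient(data.frame(study_id = "s1", strategy = "pa",
#'   delivery = "individual", n_sessions = 6, session_minutes = 60,
#'   staff_unit_cost = 50)) # 300
cost_per_patient <- function(record) {
  record <- cost_records(as.data.frame(record))
  total <- record$n_sessions * (record$session_minutes / 60) *
    record$staff_unit_cost * record$staff_per_group
  grp <- record$delivery == "group"
  total[grp] <- total[grp] * record$n_groups[grp] / record$n_participants[grp]
  unname(total)
}

#' Sum per-patient costs over staff roles within a study arm
#'
#' @param records A [cost_records()] data frame.
#' @return Data frame with one row per `study_id`/`strategy` and the summed
#'   per-patient `cost`.
#' @export
study_cost_per_patient <- function(records) {
  records <- cost_records(as.data.frame(records))
  per_row <- cost_per_patient(records)
  agg <- stats::aggregate(per_row,
                          by = list(study_id = records$study_id,
                                    strategy = records$strategy,
                                    delivery = records$delivery),
                          FUN = sum)
  names(agg)[4] <- "cost"
  agg[order(agg$strategy, agg$study_id), , drop = FALSE]
}

#' Uplift a cost between price years
#'
#' Costs taken from an older unit-cost compendium are inflated to the target
#' price year with a pay-and-prices index: `cost * index_target / index_source`.
#'
#' @param cost Cost(s) in GBP.
#' @param index_source_year Index value in the source price year, `> 0`.
#' @param index_target_year Index value in the target price year, `> 0`.
#' @return Uplifted cost(s).
#' @export
uplift_cost <- function(cost, index_source_year, index_target_year) {
  if (any(index_source_year <= 0) || any(index_target_year <= 0))
    stop("price index values must be > 0")
  cost * index_target_year / index_source_year
}

#' Standard error of a category cost
#'
#' Cost SEs are not reported by the source studies, so they are recovered
#' from the spread of per-study costs: the lowest-to-highest range is treated
#' as a pseudo-95% interval, `SE = (high - low) / 3.92`. With a single study
#' (or a degenerate range) the SE is assumed to be 25% of the expected cost.
#'
#' @param low,high Lowest and highest per-study cost, `low <= high`.
#' @param n_studies Number of contributing study arms.
#' @param mean Expected (point-estimate) cost used by the 25% rule.
#' @return SE in GBP.
#' @export
#' @examples
#' cost_se(100, 492, 3, 200) # 392 / 3.92 = 100
#' cost_se(215, 215, 1, 215) # 0.25 * 215
cost_se <- function(low, high, n_studies, mean) {
  if (low > high) stop("low must not exceed high")
  if (n_studies == 1 || high - low <= 0) 0.25 * mean else (high - low) / 3.92
}

#' Summarise per-study costs into a category cost
#'
#' The deterministic model uses the median cost across the study arms in a
#' category (midpoint of the middle pair for even counts); `low`/`high` are
#' the extremes, and the SE follows [cost_se()].
#'
#' @param costs Numeric vector of per-study per-patient costs.
#' @param strategy,delivery Labels carried into the output.
#' @return One-row data frame: `strategy`, `delivery`, `n_studies`,
#'   `median_cost`, `low`, `high`, `se`; class `"category_cost"`.
#' @export
category_cost <- function(costs, strategy = NA_character_,
                          delivery = NA_character_) {
  if (length(costs) == 0) stop("no per-study costs supplied")
  if (any(!is.finite(costs))) stop("non-finite cost in input")
  med <- stats::median(costs)
  lo <- min(costs); hi <- max(costs)
  out <- data.frame(strategy = strategy, delivery = delivery,
                    n_studies = length(costs), median_cost = med,
                    low = lo, high = hi,
                    se = cost_se(lo, hi, length(costs), med))
  class(out) <- c("category_cost", class(out))
  out
}

#' Category costs for every strategy in a records table
#'
#' Pipeline helper: per-row per-patient costs, summed over staff roles within
#' a study arm, uplifted to the target price year where a `price_year` and a
#' price index are available, then summarised per strategy with
#' [category_cost()].
#'
#' @param records A [cost_records()] data frame.
#' @param price_index Optional list with `target_year` and a named numeric
#'   `index` (year -> index value), as in `default_config()$price_index`.
#' @return Data frame with one row per strategy.
#' @export
category_costs <- function(records, price_index = NULL) {
  records <- cost_records(as.data.frame(records))
  per_study <- study_cost_per_patient(records)
  if (!is.null(price_index)) {
    yr <- records$price_year[match(paste(per_study$study_id,
                                         per_study$strategy),
                                   paste(records$study_id,
                                         records$strategy))]
    idx <- price_index$index
    tgt <- as.character(price_index$target_year)
    if (!tgt %in% names(idx))
      stop("price index has no value for target year ", tgt)
    has_year <- !is.na(yr) & as.character(yr) %in% names(idx)
    per_study$cost[has_year] <- uplift_cost(per_study$cost[has_year],
                                            idx[as.character(yr[has_year])],
                                            idx[[tgt]])
  }
  out <- lapply(split(per_study, per_study$strategy), function(d)
    category_cost(d$cost, strategy = d$strategy[1], delivery = d$delivery[1]))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Method-of-moments gamma parameters
#'
#' The PSA samples intervention costs from gamma distributions matched to the
#' category cost point estimate and SE: `shape = mean^2 / se^2`,
#' `rate = mean / se^2`, which reproduces the given mean and SE exactly.
#'
#' @param mean Expected cost, `> 0`.
#' @param se Standard error, `> 0`.
#' @return List with `shape` and `rate`.
#' @export
#' @examples
#' gamma_params(100, 50) # shape 4, rate 0.04
gamma_params <- function(mean, se) {
  if (mean <= 0 || se <= 0) stop("mean and se must be > 0")
  list(shape = mean^2 / se^2, rate = mean / se^2)
}
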