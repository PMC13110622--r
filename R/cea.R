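#' Net monetary benefit
#'
#' `lambda * qalys - cost`: the health gain valued at the willingness-to-pay
#' threshold minus what it costs.
#'
#' @param qalys QALYs (vectorised).
#' @param cost Cost in GBP.
#' @param lambda Willingness-to-pay threshold, GBP per QALY, `>= 0`.
#' @return NMB in GBP.
#' @export
#' @examples
#' nmb(1.287, 267, 20000)
nmb <- function(qalys, cost, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0")
  lambda * qalys - cost
}

#' Incremental net monetary benefit
#'
#' `nmb(strategy) - nmb(comparator) = lambda * dQ - dC`. Positive at the
#' threshold means the strategy is cost-effective versus the comparator.
#'
#' @param strategy_result,comparator_result Lists (or one-row data frames)
#'   with `qalys` and `cost`.
#' @param lambda Willingness-to-pay threshold.
#' @return INMB in GBP.
#' @export
inmb <- function(strategy_result, comparator_result, lambda) {
  nmb(strategy_result$qalys, strategy_result$cost, lambda) -
    nmb(comparator_result$qalys, comparator_result$cost, lambda)
}

#' ICER with dominance classification
#'
#' Returns the incremental cost-effectiveness ratio `dC / dQ` when the
#' strategy gains QALYs, or a classification instead of a number when a ratio
#' would mislead: `"dominated"` (costs more, gains nothing or less),
#' `"dominant"` (costs no more, gains at least as much, not identical), and
#' `"undefined"` when `|dQ|` is below `tol` (division guard) or the pair is
#' identical.
#'
#' @param strategy_result,comparator_result Lists with `qalys` and `cost`.
#' @param tol QALY difference below which the ratio is not reported.
#' @return List with `value` (GBP/QALY, `NA` unless class is `"icer"`) and
#'   `class`.
#' @export
#' @examples
#' icer(list(cost = 817, qalys = 1.272), list(cost = 0, qalys = 1.227))
icer <- function(strategy_result, comparator_result, tol = 1e-9) {
  dc <- strategy_result$cost - comparator_result$cost
  dq <- strategy_result$qalys - comparator_result$qalys
  if (abs(dq) < tol) {
    cls <- if (abs(dc) < tol) "undefined"
           else if (dc > 0) "dominated" else "dominant"
    return(list(value = NA_real_, class = cls))
  }
  if (dq < 0) {
    # cheaper-and-worse (south-west) pairs get a label, not a ratio: the
    # ratio's decision meaning inverts in that quadrant
    return(list(value = NA_real_,
                class = if (dc > 0) "dominated" else "southwest"))
  }
  if (dc <= 0) return(list(value = NA_real_, class = "dominant"))
  list(value = dc / dq, class = "icer")
}

check_matched_iterations <- function(psa_output, strategies) {
  counts <- table(psa_output$strategy)[strategies]
  if (any(is.na(counts)))
    stop("strategy missing from PSA output: ",
         paste(strategies[is.na(counts)], collapse = ", "))
  if (length(unique(counts)) != 1)
    stop("strategies have mismatched iteration counts")
  invisible(counts[[1]])
}

# iteration-aligned column extraction for one strategy
psa_col <- function(psa_output, strategy, col) {
  rows <- psa_output[psa_output$strategy == strategy, ]
  rows[[col]][order(rows$iteration)]
}

#' Pairwise probability of cost-effectiveness
#'
#' Fraction of PSA iterations in which the strategy's INMB versus the
#' comparator is strictly positive; ties count against the strategy
#' (conservative).
#'
#' @param psa_output Output of [run_psa()].
#' @param strategy,comparator Strategy labels.
#' @param lambda Willingness-to-pay threshold.
#' @return Probability in `[0, 1]`.
#' @export
pairwise_prob_ce <- function(psa_output, strategy, comparator, lambda) {
  check_matched_iterations(psa_output, c(strategy, comparator))
  d_nmb <- nmb(psa_col(psa_output, strategy, "qalys"),
               psa_col(psa_output, strategy, "cost"), lambda) -
           nmb(psa_col(psa_output, comparator, "qalys"),
               psa_col(psa_output, comparator, "cost"), lambda)
  mean(d_nmb > 0)
}

#' Multiway cost-effectiveness acceptability curve
#'
#' For each threshold on the grid, the probability that each strategy attains
#' the maximum NMB among all options. An iteration in which several
#' strategies tie for the maximum contributes equal shares to each, so the
#' probabilities sum to exactly 1 at every threshold.
#'
#' @param psa_output Output of [run_psa()].
#' @param lambda_grid Numeric vector of thresholds (non-empty).
#' @param strategies Strategies to compare; defaults to all in the output.
#' @return Long data frame `lambda, strategy, probability`.
#' @export
multiway_ceac <- function(psa_output, lambda_grid,
                          strategies = unique(psa_output$strategy)) {
  if (!length(lambda_grid)) stop("empty lambda grid")
  n <- check_matched_iterations(psa_output, strategies)
  qm <- vapply(strategies, function(s) psa_col(psa_output, s, "qalys"),
               numeric(n))
  cm <- vapply(strategies, function(s) psa_col(psa_output, s, "cost"),
               numeric(n))
  res <- lapply(lambda_grid, function(lam) {
    nmbm <- lam * qm - cm
    best <- nmbm == matrixStats_rowMax(nmbm)
    shares <- best / rowSums(best)
    data.frame(lambda = lam, strategy = strategies,
               probability = colMeans(shares), row.names = NULL)
  })
  do.call(rbind, res)
}

# row maxima without a matrixStats dependency
matrixStats_rowMax <- function(m) {
  do.call(pmax, as.data.frame(m))
}

#' Cost-effectiveness plane export
#'
#' Per-iteration incremental cost and QALYs of each strategy versus the
#' comparator, with an indicator for falling below the threshold line
#' (INMB > 0), suitable for plotting pairwise CE planes.
#'
#' @param psa_output Output of [run_psa()].
#' @param comparator Comparator strategy (default `"usual_care"`).
#' @param lambda Threshold used for the indicator.
#' @param strategies Strategies to export; defaults to all except the
#'   comparator.
#' @return Data frame `iteration, strategy, delta_cost, delta_qalys,
#'   cost_effective`.
#' @export
ce_plane_export <- function(psa_output, comparator = "usual_care",
                            lambda = 20000,
                            strategies = setdiff(unique(psa_output$strategy),
                                                 comparator)) {
  n <- check_matched_iterations(psa_output, c(strategies, comparator))
  qc <- psa_col(psa_output, comparator, "qalys")
  cc <- psa_col(psa_output, comparator, "cost")
  out <- lapply(strategies, function(s) {
    dq <- psa_col(psa_output, s, "qalys") - qc
    dc <- psa_col(psa_output, s, "cost") - cc
    data.frame(iteration = seq_len(n), strategy = s, delta_cost = dc,
               delta_qalys = dq, cost_effective = lambda * dq - dc > 0)
  })
  do.call(rbind, out)
}
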