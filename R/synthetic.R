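#' Specification for a synthetic posterior-effect generator
#'
#' The real model consumes correlated posterior draws (CODA samples) of the
#' SMD versus usual care at EOT/ST/LT from a network meta-analysis. Those
#' draws are not distributed with this package, so the generator emulates
#' them: multivariate-normal draws over the present timepoints with given
#' means, SDs and a common cross-timepoint correlation (posteriors on the SMD
#' scale are approximately normal, and effects at successive follow-ups are
#' strongly positively correlated).
#'
#' @param strategy Strategy label.
#' @param means Named numeric vector of SMD means; names among
#'   `c("eot", "st", "lt")`. Omit a name (or set `NA`) for timepoints with no
#'   evidence.
#' @param sds Posterior SDs, same names as `means`.
#' @param rho Common cross-timepoint correlation, in `[-1, 1]` (default 0.7).
#' @param n_draws Number of posterior draws.
#' @return An object of class `"effect_generator_spec"`.
#' @export
effect_generator_spec <- function(strategy, means, sds, rho = 0.7,
                                  n_draws = 5000) {
  keep <- !is.na(means)
  means <- means[keep]; sds <- sds[names(means)]
  if (!length(means)) stop("at least one timepoint mean is required")
  if (!all(names(means) %in% c("eot", "st", "lt")))
    stop("timepoint names must be among 'eot', 'st', 'lt'")
  if (any(is.na(sds)) || any(sds < 0)) stop("SDs must be >= 0")
  if (abs(rho) > 1) stop("rho must lie in [-1, 1]")
  k <- length(means)
  R <- matrix(rho, k, k); diag(R) <- 1
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("implied correlation matrix is not positive semi-definite")
  if (n_draws < 1) stop("n_draws must be >= 1")
  structure(list(strategy = strategy, means = means, sds = sds, rho = rho,
                 n_draws = n_draws),
            class = "effect_generator_spec")
}

# n draws from N(mu, Sigma) via Cholesky; tolerates semi-definite Sigma by a
# tiny diagonal jitter when some SD is zero.
rmvnorm_chol <- function(n, mu, sigma) {
  k <- length(mu)
  if (k == 1) return(matrix(stats::rnorm(n, mu, sqrt(sigma[1, 1])), ncol = 1))
  L <- tryCatch(chol(sigma),
                error = function(e) chol(sigma + diag(1e-12, k)))
  z <- matrix(stats::rnorm(n * k), n, k)
  sweep(z %*% L, 2, mu, "+")
}

#' Generate synthetic posterior SMD draws
#'
#' @param spec An [effect_generator_spec()].
#' @param seed Integer seed; identical seed and spec give identical output.
#' @return Long data frame `draw, strategy, timepoint, smd` with timepoints in
#'   upper case (`EOT`, `ST`, `LT`); timepoints without evidence are absent.
#' @export
generate_effect_samples <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "effect_generator_spec"))
  set.seed(seed)
  k <- length(spec$means)
  R <- matrix(spec$rho, k, k); diag(R) <- 1
  sigma <- diag(spec$sds, k) %*% R %*% diag(spec$sds, k)
  draws <- rmvnorm_chol(spec$n_draws, spec$means, sigma)
  data.frame(
    draw = rep(seq_len(spec$n_draws), times = k),
    strategy = spec$strategy,
    timepoint = rep(toupper(names(spec$means)), each = spec$n_draws),
    smd = as.vector(draws)
  )
}

#' Generate synthetic intervention delivery records
#'
#' Emulates study-level costing tables: per-study session counts, durations
#' and staff unit costs drawn uniformly from stated ranges, with group
#' records additionally given participant counts.
#'
#' @param strategy,delivery Labels for the records.
#' @param n_studies Number of study arms to generate.
#' @param ranges List of `c(min, max)` ranges: `sessions`, `minutes`,
#'   `unit_cost`, and for group delivery `participants` (and optionally
#'   `groups`).
#' @param seed Integer seed.
#' @param price_year Price year stamped on the records.
#' @return A [cost_records()] data frame.
#' @export
generate_cost_records <- function(strategy, delivery, n_studies, ranges,
                                  seed = 1L, price_year = 2023) {
  stopifnot(n_studies >= 1, delivery %in% c("individual", "group"))
  for (nm in c("sessions", "minutes", "unit_cost")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2] || r[1] <= 0)
      stop("invalid range for '", nm, "'")
  }
  set.seed(seed)
  # uniform integer draw that is safe for degenerate ranges (sample() on a
  # scalar would sample from 1:x instead)
  rint <- function(n, r) r[1] + sample.int(r[2] - r[1] + 1, n,
                                           replace = TRUE) - 1L
  rec <- data.frame(
    study_id = sprintf("%s_study%02d", strategy, seq_len(n_studies)),
    strategy = strategy,
    delivery = delivery,
    n_sessions = rint(n_studies, ranges$sessions),
    session_minutes = round(stats::runif(n_studies, ranges$minutes[1],
                                         ranges$minutes[2])),
    staff_unit_cost = round(stats::runif(n_studies, ranges$unit_cost[1],
                                         ranges$unit_cost[2]), 2),
    price_year = price_year
  )
  if (delivery == "group") {
    rp <- ranges$participants
    if (is.null(rp)) stop("group delivery needs a 'participants' range")
    rec$n_participants <- rint(n_studies, rp)
    rg <- if (is.null(ranges$groups)) c(1, 1) else ranges$groups
    rec$n_groups <- rint(n_studies, rg)
  }
  cost_records(rec)
}

# Ground-truth SMD summaries for the synthetic reference bundle. All values
# are invented stand-ins with the same *structure* as the evidence base the
# model was designed for: three intervention categories, a strategy with no
# short-term evidence (mindfulness) and a long-term estimate from few studies
# (wide SD), group and individual delivery sharing pooled effects in the base
# analysis. They are not estimates from any published meta-analysis.
fixture_effect_table <- function(source = c("base", "cbt_separate",
                                            "earliest_lt")) {
  source <- match.arg(source)
  base <- list(
    physical_activity = data.frame(
      timepoint = c("EOT", "ST", "LT"), months_from_baseline = c(3, 5, 12),
      smd_mean = c(-0.60, -0.55, -0.45), smd_sd = c(0.12, 0.15, 0.18)),
    cbt_fatigue = data.frame(
      timepoint = c("EOT", "ST", "LT"), months_from_baseline = c(4, 6, 12),
      smd_mean = c(-0.55, -0.30, -0.35), smd_sd = c(0.10, 0.12, 0.14)),
    mindfulness = data.frame(
      timepoint = c("EOT", "LT"), months_from_baseline = c(2, 9),
      smd_mean = c(-0.65, -0.50), smd_sd = c(0.15, 0.25))
  )
  if (source == "earliest_lt") {
    # earliest LT follow-up: less waning has occurred, timing pulled in
    base$physical_activity[3, c("months_from_baseline", "smd_mean")] <-
      c(8, -0.52)
    base$cbt_fatigue[3, c("months_from_baseline", "smd_mean")] <- c(9, -0.40)
    base$mindfulness[2, c("months_from_baseline", "smd_mean")] <- c(7, -0.56)
  }
  per_strategy <- list()
  for (cat in names(base)) {
    for (dl in c("individual", "group")) {
      df <- base[[cat]]
      if (source == "cbt_separate" && cat == "cbt_fatigue") {
        # delivery-specific CBT effects (slightly apart, same pattern)
        df$smd_mean <- if (dl == "individual") c(-0.57, -0.32, -0.36)
                       else c(-0.53, -0.28, -0.33)
      }
      df$strategy <- paste(cat, dl, sep = "_")
      per_strategy[[df$strategy[1]]] <- df
    }
  }
  out <- do.call(rbind, per_strategy)
  rownames(out) <- NULL
  out[, c("strategy", "timepoint", "months_from_baseline", "smd_mean",
          "smd_sd")]
}

fixture_cost_settings <- function() {
  list(
    physical_activity_individual = list(
      n = 3, ranges = list(sessions = c(4, 8), minutes = c(30, 60),
                           unit_cost = c(35, 55)), year = 2023),
    physical_activity_group = list(
      n = 2, ranges = list(sessions = c(6, 10), minutes = c(45, 60),
                           unit_cost = c(35, 55), participants = c(8, 12)),
      year = 2023),
    cbt_fatigue_individual = list(
      n = 10, ranges = list(sessions = c(8, 14), minutes = c(50, 60),
                            unit_cost = c(45, 55)), year = 2017),
    cbt_fatigue_group = list(
      n = 5, ranges = list(sessions = c(8, 12), minutes = c(90, 120),
                           unit_cost = c(45, 55), participants = c(6, 10)),
      year = 2023),
    mindfulness_individual = list(
      n = 2, ranges = list(sessions = c(6, 8), minutes = c(45, 60),
                           unit_cost = c(45, 55)), year = 2023),
    mindfulness_group = list(
      n = 1, ranges = list(sessions = c(8, 8), minutes = c(110, 130),
                           unit_cost = c(45, 55), participants = c(10, 14)),
      year = 2023)
  )
}

#' Synthetic reference input bundle
#'
#' Builds, entirely in code and deterministically for a given seed, every
#' input the pipeline needs: seven strategies (three intervention categories,
#' each delivered individually and in groups, plus usual care), SMD summary
#' tables and matching correlated posterior draws for the base analysis and
#' the two alternative-evidence scenarios, study-level cost records, and a
#' ground-truth block holding the generating parameters and the exact
#' (closed-form) discounted QALYs at those parameters.
#'
#' All numbers are synthetic stand-ins with realistic structure; nothing in
#' the bundle is an estimate from any published meta-analysis or costing
#' supplement.
#'
#' @param n_draws Posterior draws per strategy (default 5000, matching the
#'   default PSA iteration count).
#' @param seed Master seed; sub-generators use offsets derived from it.
#' @param rho Cross-timepoint posterior correlation passed to the generator.
#' @return A list of class `"fatigue_model_inputs"` with elements `config`,
#'   `strategies`, `effects` (list by source), `posterior` (list by source),
#'   `cost_records` and `ground_truth`.
#' @export
#' @examples
#' fx <- reference_fixture(n_draws = 50)
#' fx$strategies
reference_fixture <- function(n_draws = 5000, seed = 1848L, rho = 0.7) {
  config <- default_config()
  strategies <- data.frame(
    strategy = c("usual_care",
                 "physical_activity_individual", "physical_activity_group",
                 "cbt_fatigue_individual", "cbt_fatigue_group",
                 "mindfulness_individual", "mindfulness_group"),
    category = c("usual_care", rep(c("physical_activity", "cbt_fatigue",
                                     "mindfulness"), each = 2)),
    delivery = c(NA, rep(c("individual", "group"), 3))
  )

  sources <- c("base", "cbt_separate", "earliest_lt")
  effects <- lapply(stats::setNames(sources, sources), fixture_effect_table)

  # Posterior draws: one draw stream per category and source, shared by the
  # two delivery modes (pooled effects => identical draws), except under
  # cbt_separate where CBT gets delivery-specific streams.
  posterior <- list()
  for (si in seq_along(sources)) {
    src <- sources[si]
    eff <- effects[[src]]
    tabs <- list()
    done <- character(0)
    for (strat in unique(eff$strategy)) {
      e <- eff[eff$strategy == strat, ]
      cat_nm <- strategies$category[strategies$strategy == strat]
      share_key <- if (src == "cbt_separate" && cat_nm == "cbt_fatigue")
        strat else cat_nm
      if (share_key %in% done) {
        donor <- tabs[[share_key]]
        donor$strategy <- strat
        tabs[[strat]] <- donor
        next
      }
      spec <- effect_generator_spec(
        strat,
        means = stats::setNames(e$smd_mean, tolower(e$timepoint)),
        sds = stats::setNames(e$smd_sd, tolower(e$timepoint)),
        rho = rho, n_draws = n_draws)
      sub_seed <- (seed + 1000L * si +
                     match(share_key, c(unique(strategies$category),
                                        unique(eff$strategy)))) %% .Machine$integer.max
      tabs[[share_key]] <- generate_effect_samples(spec, seed = sub_seed)
      tabs[[share_key]]$strategy <- strat
      names(tabs)[names(tabs) == share_key] <- share_key # keep key
      done <- c(done, share_key)
      tabs[[strat]] <- tabs[[share_key]]
    }
    tabs <- tabs[unique(eff$strategy)]
    posterior[[src]] <- do.call(rbind, tabs)
    rownames(posterior[[src]]) <- NULL
  }

  cost_cfg <- fixture_cost_settings()
  recs <- mapply(function(nm, cc, i) {
    generate_cost_records(nm,
                          delivery = strategies$delivery[
                            strategies$strategy == nm],
                          n_studies = cc$n, ranges = cc$ranges,
                          seed = (seed + 77L * i) %% .Machine$integer.max,
                          price_year = cc$year)
  }, names(cost_cfg), cost_cfg, seq_along(cost_cfg), SIMPLIFY = FALSE)
  cost_tab <- do.call(rbind, recs)
  rownames(cost_tab) <- NULL

  inputs <- structure(list(config = config, strategies = strategies,
                           effects = effects, posterior = posterior,
                           cost_records = cost_records(cost_tab),
                           ground_truth = NULL),
                      class = "fatigue_model_inputs")
  inputs$ground_truth <- fixture_ground_truth(inputs)
  inputs
}

# Exact expected QALYs (closed-form discounting oracle, independent of the
# trapezoid engine) and category costs at the generating parameters.
fixture_ground_truth <- function(inputs) {
  cfg <- inputs$config
  coeffs <- config_mapping(cfg)
  baseline <- config_baseline(cfg)
  eff <- inputs$effects$base
  qalys <- vapply(inputs$strategies$strategy, function(strat) {
    if (strat == "usual_care") {
      sched <- timepoint_schedule(1, horizon = cfg$horizon_months)
      tr <- build_usual_care_trajectory(baseline, sched)
    } else {
      e <- eff[eff$strategy == strat, ]
      tr <- build_intervention_trajectory(
        baseline, strategy_smds(e), strategy_schedule(e, cfg$horizon_months),
        sd_fss = cfg$baseline$sd_fss, waning_mode = cfg$waning_mode)
    }
    exact_discounted_qalys(tr, coeffs, cfg$discount_rate,
                           cfg$mapping$utility_floor,
                           cfg$mapping$utility_ceiling,
                           cfg$fss_min, cfg$fss_max)
  }, numeric(1))
  list(expected_qalys = data.frame(strategy = inputs$strategies$strategy,
                                   qalys = unname(qalys)),
       category_costs = category_costs(inputs$cost_records,
                                       cfg$price_index))
}

# Named SMD vector (eot/st/lt with NAs) and schedule from one strategy's
# rows of an effects table.
strategy_smds <- function(eff_rows) {
  out <- c(eot = NA_real_, st = NA_real_, lt = NA_real_)
  out[tolower(eff_rows$timepoint)] <- eff_rows$smd_mean
  out
}

strategy_schedule <- function(eff_rows, horizon) {
  tp <- stats::setNames(eff_rows$months_from_baseline,
                        tolower(eff_rows$timepoint))
  timepoint_schedule(tp[["eot"]],
                     if ("st" %in% names(tp)) tp[["st"]] else NA_real_,
                     if ("lt" %in% names(tp)) tp[["lt"]] else NA_real_,
                     horizon = horizon)
}

#' Write a model input bundle to delimited files
#'
#' Exports the bundle produced by [reference_fixture()] (or any compatible
#' inputs list) as plain-text tables plus a JSON config, the same formats the
#' readers consume.
#'
#' @param inputs A `"fatigue_model_inputs"` list.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(inputs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(d, f) utils::write.csv(d, file.path(dir, f),
                                          row.names = FALSE, quote = FALSE)
  wcsv(inputs$strategies, "strategies.csv")
  for (src in names(inputs$effects))
    wcsv(inputs$effects[[src]], sprintf("effects_%s.csv", src))
  for (src in names(inputs$posterior))
    wcsv(inputs$posterior[[src]], sprintf("posterior_%s.csv", src))
  wcsv(as.data.frame(inputs$cost_records), "cost_records.csv")
  wcsv(inputs$ground_truth$expected_qalys, "ground_truth_qalys.csv")
  write_config(inputs$config, file.path(dir, "config.json"))
  invisible(dir)
}

#' Read a model input bundle from a directory
#'
#' Counterpart of [write_fixture_bundle()].
#'
#' @param dir Directory containing the bundle files.
#' @return A `"fatigue_model_inputs"` list (without the ground-truth block if
#'   absent).
#' @export
read_model_inputs <- function(dir) {
  rcsv <- function(f) utils::read.csv(file.path(dir, f))
  eff_files <- list.files(dir, pattern = "^effects_.*\\.csv$")
  post_files <- list.files(dir, pattern = "^posterior_.*\\.csv$")
  src_of <- function(f, prefix) sub("\\.csv$", "", sub(prefix, "", f))
  effects <- stats::setNames(lapply(eff_files, rcsv),
                             vapply(eff_files, src_of, "", "effects_"))
  posterior <- stats::setNames(lapply(post_files, rcsv),
                               vapply(post_files, src_of, "", "posterior_"))
  gt <- NULL
  if (file.exists(file.path(dir, "ground_truth_qalys.csv")))
    gt <- list(expected_qalys = rcsv("ground_truth_qalys.csv"))
  structure(list(config = load_config(file.path(dir, "config.json")),
                 strategies = rcsv("strategies.csv"),
                 effects = effects, posterior = posterior,
                 cost_records = cost_records(rcsv("cost_records.csv")),
                 ground_truth = gt),
            class = "fatigue_model_inputs")
}
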