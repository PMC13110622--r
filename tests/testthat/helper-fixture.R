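# Shared fixtures, built once per test run and cached.

.fx_cache <- new.env(parent = emptyenv())

# small synthetic bundle for structural / property tests
fx_small <- function(n_draws = 300, seed = 11L) {
  key <- sprintf("fx_%d_%d", n_draws, seed)
  if (is.null(.fx_cache[[key]]))
    .fx_cache[[key]] <- reference_fixture(n_draws = n_draws, seed = seed)
  .fx_cache[[key]]
}

# full-size bundle at the default PSA iteration count (acceptance tests)
fx_full <- function() {
  if (is.null(.fx_cache$full)) .fx_cache$full <- reference_fixture()
  .fx_cache$full
}

# replace a strategy's evidence with a null effect (mean-zero SMDs and
# matching mean-zero posterior draws) in every source
with_null_effect <- function(inputs, strat, sd = 0.15, seed = 99L) {
  for (src in names(inputs$effects)) {
    eff <- inputs$effects[[src]]
    eff$smd_mean[eff$strategy == strat] <- 0
    eff$smd_sd[eff$strategy == strat] <- sd
    inputs$effects[[src]] <- eff
    p <- inputs$posterior[[src]]
    rows <- p$strategy == strat
    tps <- tolower(unique(p$timepoint[rows]))
    n <- max(p$draw[rows])
    spec <- effect_generator_spec(
      strat,
      means = stats::setNames(rep(0, length(tps)), tps),
      sds = stats::setNames(rep(sd, length(tps)), tps),
      n_draws = n)
    p[rows, ] <- generate_effect_samples(spec, seed = seed)
    inputs$posterior[[src]] <- p
  }
  inputs
}

# set every posterior draw to its strategy's summary mean (degenerate PSA)
with_constant_posterior <- function(inputs) {
  for (src in names(inputs$posterior)) {
    eff <- inputs$effects[[src]]
    p <- inputs$posterior[[src]]
    key <- paste(p$strategy, tolower(p$timepoint))
    ekey <- paste(eff$strategy, tolower(eff$timepoint))
    p$smd <- eff$smd_mean[match(key, ekey)]
    inputs$posterior[[src]] <- p
  }
  inputs
}

# zero out every sampled-parameter variance except the treatment effect
zero_param_variance <- function(config) {
  config$baseline$se_fss <- 0
  config$mapping$se_intercept <- 0
  config$mapping$se_slope <- 0
  config
}
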