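# Shared fixtures, built in code at test time.

# constant-weather series: n hours at fixed T (K) and RH, hourly from a
# given start; anthesis at the first record
const_weather <- function(n = 48, tair = 293.15, rh = 0.6,
                          start = "2015-05-10 00:00:00") {
  t0 <- as.POSIXct(start, tz = "UTC")
  weather_series(t0 + 3600 * (0:(n - 1)), rep(tair, n), rep(rh, n))
}

# packaged default season + default parameters, computed once per test run
season_cache <- new.env(parent = emptyenv())
default_season <- function() {
  if (is.null(season_cache$weather)) season_cache$weather <- synthetic_season()
  season_cache$weather
}
default_run <- function() {
  if (is.null(season_cache$run)) {
    season_cache$run <- simulate_fruit(default_season(), warn_clamp = FALSE)
  }
  season_cache$run
}

# synthetic observations sampled from a run at the standard 8 sampling
# days (10..80 DAA), with optional multiplicative log-normal noise
sample_observations <- function(run, noise_cv = 0, seed = 1) {
  daa <- seq(10, 80, by = 10)
  idx <- daa * 24 + 1
  withr::with_seed(seed, {
    noise <- function(n) {
      if (noise_cv == 0) rep(1, n)
      else exp(stats::rnorm(n, 0, sqrt(log(1 + noise_cv^2))))
    }
    observation_series(data.frame(
      daa = daa,
      dry_mg = run$s[idx] * noise(length(idx)),
      water_mg = run$w[idx] * noise(length(idx)),
      fresh_mg = run$fresh[idx] * noise(length(idx)),
      aba_ug_per_g = run$ABA_conc[idx] * noise(length(idx))))
  })
}

# loose parameter list for unit tests of single operations where the
# cross-parameter invariants of the full set would get in the way
bare_params <- function(...) {
  utils::modifyList(unclass(default_parameters()), list(...))
}

# independent naive implementation of the five fit metrics, kept
# deliberately separate from fit_metrics() as its oracle
naive_metrics <- function(y, yh) {
  n <- length(y)
  mae <- sum(abs(y - yh)) / n
  rmse <- sqrt(sum((y - yh)^2) / n)
  ybar <- sum(y) / n
  sae <- sum(abs(y - yh)); sad <- sum(abs(y - ybar))
  list(MAE = mae, RMSE = rmse, NRMSE = rmse / (max(y) - min(y)),
       d_r = if (sae <= 2 * sad) 1 - sae / (2 * sad) else 2 * sad / sae - 1,
       EF = 1 - sum((y - yh)^2) / sum((y - ybar)^2))
}

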