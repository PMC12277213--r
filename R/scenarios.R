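# Climate what-if scenarios: uniform temperature offsets and shifted
# anthesis dates.

#' Apply a uniform temperature offset to a weather series
#'
#' Adds `offset` K to every hourly temperature, leaving relative humidity
#' untouched.
#'
#' @param weather A [weather_series()].
#' @param offset Temperature offset, K.
#' @return A [weather_series()].
#' @export
offset_weather <- function(weather, offset) {
  weather_series(weather$time, weather$tair + offset, weather$rh,
                 anthesis = anthesis_time(weather))
}

#' Temperature-offset scenario
#'
#' Re-runs the simulation with every hourly temperature shifted by
#' `offset` K and relative humidity held at its baseline values.
#'
#' @param weather Baseline [weather_series()].
#' @param offset Offset, K (e.g. 3 or 5).
#' @param params A `parameter_set`.
#' @param ... Passed to [simulate_fruit()].
#' @return A `simulation_result`.
#' @export
scenario_temperature_offset <- function(weather, offset,
                                        params = default_parameters(), ...) {
  simulate_fruit(offset_weather(weather, offset), params, ...)
}

#' Anthesis-shift scenario
#'
#' Simulates one full season per candidate anthesis date over the same
#' weather record and summarises the fresh mass at the end of the run
#' (by default 80 days after anthesis).
#'
#' @param weather A [weather_series()]; must cover every anthesis date
#'   plus `duration_days`.
#' @param anthesis_dates Vector of POSIXct (or ISO 8601 strings).
#' @param params A `parameter_set`.
#' @param duration_days Days after anthesis per run.
#' @param ... Passed to [simulate_fruit()].
#' @return List with `runs` (one `simulation_result` per date) and
#'   `summary` (data frame: anthesis, dry/water/fresh mass at the final
#'   hour).
#' @export
scenario_anthesis_shift <- function(weather, anthesis_dates,
                                    params = default_parameters(),
                                    duration_days = 80, ...) {
  dates <- as.POSIXct(anthesis_dates, tz = "UTC")
  runs <- lapply(dates, function(d) {
    w <- weather_series(weather$time, weather$tair, weather$rh, anthesis = d)
    simulate_fruit(w, params, duration_days = duration_days, ...)
  })
  names(runs) <- format(dates, "%Y-%m-%d")
  final <- function(r, v) r[[v]][nrow(r)]
  summary <- data.frame(
    anthesis = dates,
    dry = vapply(runs, final, numeric(1), v = "s"),
    water = vapply(runs, final, numeric(1), v = "w"),
    fresh = vapply(runs, final, numeric(1), v = "fresh"),
    row.names = NULL)
  list(runs = runs, summary = summary)
}

#' Times of the ABA and dry-mass peaks of a run
#'
#' Convenience extractor used when comparing warming scenarios: returns
#' the hours since anthesis at which the ABA concentration and the dry
#' mass attain their maxima, and the corresponding maxima.
#'
#' @param result A `simulation_result`.
#' @return Named list: `t_peak_ABA`, `ABA_peak`, `t_peak_dry`, `dry_peak`
#'   (h / ug g^-1 / h / mg).
#' @export
peak_times <- function(result) {
  i_aba <- which.max(result$ABA_conc)
  i_dry <- which.max(result$s)
  list(t_peak_ABA = result$t[i_aba], ABA_peak = result$ABA_conc[i_aba],
       t_peak_dry = result$t[i_dry], dry_peak = result$s[i_dry])
}
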