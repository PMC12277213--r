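# Hourly environmental driver series: ingestion, validation, synthesis,
# and the within-plant boundary drivers (stem water potential, phloem
# sucrose) that force the fruit model.

#' Construct an hourly weather series
#'
#' A `weather_series` is a data frame with columns `time` (POSIXct, UTC,
#' strictly increasing at a fixed 1 h step), `tair` (K) and `rh`
#' (fraction in \[0, 1\]), plus an `anthesis` attribute marking t = 0
#' (0 days after anthesis, DAA).
#'
#' @param time POSIXct vector, hourly, strictly increasing.
#' @param tair Air temperature, K.
#' @param rh Relative humidity, fraction in \[0, 1\].
#' @param anthesis POSIXct scalar; must not lie after the last record.
#' @return A `weather_series` object.
#' @export
weather_series <- function(time, tair, rh, anthesis = time[1]) {
  if (length(time) < 1L) stop("weather_series: needs >= 1 record", call. = FALSE)
  if (length(tair) != length(time) || length(rh) != length(time)) {
    stop("weather_series: time, tair, rh must have equal length", call. = FALSE)
  }
  time <- as.POSIXct(time, tz = "UTC")
  anthesis <- as.POSIXct(anthesis, tz = "UTC")
  validate_hourly_times(time)
  bad_rh <- which(!is.finite(rh) | rh < 0 | rh > 1)
  if (length(bad_rh) > 0L) {
    stop(sprintf("weather_series: RH out of [0, 1] at row %d (value %s)",
                 bad_rh[1], format(rh[bad_rh[1]])), call. = FALSE)
  }
  bad_t <- which(!is.finite(tair) | tair <= 150)
  if (length(bad_t) > 0L) {
    stop(sprintf("weather_series: implausible temperature at row %d (%s K); is the input in Kelvin?",
                 bad_t[1], format(tair[bad_t[1]])), call. = FALSE)
  }
  if (anthesis > time[length(time)]) {
    stop("weather_series: anthesis lies after the last weather record",
         call. = FALSE)
  }
  out <- data.frame(time = time, tair = as.numeric(tair), rh = as.numeric(rh))
  attr(out, "anthesis") <- anthesis
  class(out) <- c("weather_series", "data.frame")
  out
}

validate_hourly_times <- function(time) {
  if (anyNA(time)) {
    stop(sprintf("weather series: unparseable timestamp at row %d",
                 which(is.na(time))[1]), call. = FALSE)
  }
  if (length(time) > 1L) {
    dt <- as.numeric(diff(time), units = "hours")
    bad <- which(abs(dt - 1) > 1e-6)
    if (length(bad) > 0L) {
      stop(sprintf(
        "weather series: timestamps must advance by exactly 1 h; offending step at row %d (delta = %.4g h)",
        bad[1] + 1L, dt[bad[1]]), call. = FALSE)
    }
  }
  invisible(time)
}

#' Anthesis time of a weather series
#' @param series A `weather_series`.
#' @return POSIXct scalar.
#' @export
anthesis_time <- function(series) attr(series, "anthesis")

#' Hours since anthesis for each weather record
#' @param series A `weather_series`.
#' @return Numeric vector, h (negative before anthesis).
#' @export
hours_since_anthesis <- function(series) {
  as.numeric(difftime(series$time, anthesis_time(series), units = "hours"))
}

#' @export
print.weather_series <- function(x, ...) {
  cat(sprintf("<weather_series> %d hourly records, %s .. %s\n",
              nrow(x), format(x$time[1]), format(x$time[nrow(x)])))
  cat(sprintf("  anthesis: %s\n", format(anthesis_time(x))))
  cat(sprintf("  tair: %.2f .. %.2f K;  rh: %.3f .. %.3f\n",
              min(x$tair), max(x$tair), min(x$rh), max(x$rh)))
  invisible(x)
}

#' Read an hourly weather CSV
#'
#' Canonical columns are `timestamp` (ISO 8601), `tair_C` or `tair_K`, and
#' `rh_pct` or `rh_frac`; other layouts are mapped through `dialect`.
#' Units are inferred from the canonical column names (`_C`/`_K`,
#' `_pct`/`_frac`) or declared explicitly in the dialect.
#'
#' @param path Path to the CSV file.
#' @param anthesis Anthesis timestamp (ISO 8601 string or POSIXct).
#'   Defaults to the first record.
#' @param dialect Optional named list remapping columns and declaring
#'   units: elements `timestamp`, `tair`, `rh` (column names in the file),
#'   `tair_unit` ("C" or "K"), `rh_unit` ("pct" or "frac").
#' @param interpolate_gaps If `TRUE`, single missing hours are filled by
#'   linear interpolation; the default `FALSE` fails on any gap, because
#'   silently filled gaps corrupt thermal-time accumulation.
#' @return A [weather_series()].
#' @export
read_weather_csv <- function(path, anthesis = NULL, dialect = NULL,
                             interpolate_gaps = FALSE) {
  if (!file.exists(path)) {
    stop(sprintf("read_weather_csv: file not found: %s", path), call. = FALSE)
  }
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- resolve_weather_dialect(names(raw), dialect)
  time <- parse_iso_time(raw[[cols$timestamp]])
  tair <- as.numeric(raw[[cols$tair]])
  rh <- as.numeric(raw[[cols$rh]])
  if (cols$tair_unit == "C") tair <- celsius_to_kelvin(tair)
  if (cols$rh_unit == "pct") rh <- rh / 100
  bad_rh <- which(!is.finite(rh) | rh < 0 | rh > 1)
  if (length(bad_rh) > 0L) {
    stop(sprintf("read_weather_csv: RH out of range at data row %d of %s",
                 bad_rh[1], path), call. = FALSE)
  }
  if (interpolate_gaps) {
    filled <- fill_single_hour_gaps(time, tair, rh)
    time <- filled$time; tair <- filled$tair; rh <- filled$rh
  }
  if (is.null(anthesis)) anthesis <- time[1]
  if (is.character(anthesis)) anthesis <- parse_iso_time(anthesis)
  weather_series(time, tair, rh, anthesis = anthesis)
}

resolve_weather_dialect <- function(have, dialect) {
  pick <- function(cands, role) {
    hit <- cands[cands %in% have]
    if (length(hit) == 0L) {
      stop(sprintf(
        "weather CSV: cannot resolve a %s column (looked for %s); supply a dialect",
        role, paste(cands, collapse = ", ")), call. = FALSE)
    }
    hit[1]
  }
  if (is.null(dialect)) dialect <- list()
  ts <- dialect$timestamp %||% pick("timestamp", "timestamp")
  ta <- dialect$tair %||% pick(c("tair_K", "tair_C"), "temperature")
  rh <- dialect$rh %||% pick(c("rh_frac", "rh_pct"), "humidity")
  for (col in c(ts, ta, rh)) {
    if (!col %in% have) {
      stop(sprintf("weather CSV: declared column '%s' is missing", col),
           call. = FALSE)
    }
  }
  tu <- dialect$tair_unit %||% (if (grepl("_C$", ta)) "C" else "K")
  ru <- dialect$rh_unit %||% (if (grepl("_pct$", rh)) "pct" else "frac")
  if (!tu %in% c("C", "K")) stop("weather CSV: tair_unit must be 'C' or 'K'",
                                 call. = FALSE)
  if (!ru %in% c("pct", "frac")) stop("weather CSV: rh_unit must be 'pct' or 'frac'",
                                      call. = FALSE)
  list(timestamp = ts, tair = ta, rh = rh, tair_unit = tu, rh_unit = ru)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_iso_time <- function(x) {
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
                                   "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

fill_single_hour_gaps <- function(time, tair, rh) {
  dt <- as.numeric(diff(time), units = "hours")
  wide <- which(dt > 2 + 1e-6)
  if (length(wide) > 0L) {
    stop(sprintf("weather CSV: gap longer than one hour starting at row %d; refusing to interpolate",
                 wide[1]), call. = FALSE)
  }
  gaps <- which(abs(dt - 2) < 1e-6)
  if (length(gaps) == 0L) return(list(time = time, tair = tair, rh = rh))
  full <- seq(time[1], time[length(time)], by = "1 hour")
  tair_f <- stats::approx(as.numeric(time), tair, xout = as.numeric(full))$y
  rh_f <- stats::approx(as.numeric(time), rh, xout = as.numeric(full))$y
  list(time = full, tair = tair_f, rh = rh_f)
}

#' Write a weather series to the canonical CSV dialect
#'
#' Emits columns `timestamp` (ISO 8601), `tair_K`, `rh_frac`.
#'
#' @param series A [weather_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_weather_csv <- function(series, path) {
  out <- data.frame(
    timestamp = format(series$time, "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    tair_K = sprintf("%.6f", series$tair),
    rh_frac = sprintf("%.6f", series$rh)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Smooth asymmetric diurnal shape on [0, 24): -1 at `h_min`, +1 at `h_max`,
# built from two half-cosine arcs so the derivative vanishes at both
# extremes. Used for temperature (min 05:00, max 14:00) and, negated, for
# relative humidity.
diurnal_shape <- function(hour, h_min = 5, h_max = 14) {
  h <- hour %% 24
  rise_len <- (h_max - h_min) %% 24
  fall_len <- 24 - rise_len
  since_min <- (h - h_min) %% 24
  ifelse(since_min <= rise_len,
         -cos(pi * since_min / rise_len),
         cos(pi * (since_min - rise_len) / fall_len))
}

#' Generate a synthetic hourly weather season
#'
#' Deterministic given `random_seed`. Temperature is the sum of a mean
#' level, a seasonal sinusoid (annual cycle peaking on day-of-year 197,
#' mid July), an asymmetric diurnal wave with its minimum at 05:00 and
#' maximum at 14:00 (two half-cosine arcs, peak-to-peak = 2 x diurnal
#' amplitude), and Gaussian noise. Relative humidity runs in anti-phase
#' with the diurnal temperature wave and is clipped to \[0.02, 1\].
#'
#' @param season_start,season_end POSIXct or ISO 8601 strings; the series
#'   covers `season_start` to `season_end` inclusive, hourly.
#' @param T_mean_day Annual-mean temperature level, K.
#' @param T_amplitude_diurnal Half peak-to-peak diurnal amplitude, K.
#' @param T_amplitude_seasonal Amplitude of the annual sinusoid, K.
#' @param RH_mean Mean relative humidity, fraction.
#' @param RH_amplitude Diurnal RH amplitude, fraction.
#' @param noise_sd_T,noise_sd_RH Gaussian noise standard deviations.
#' @param random_seed Integer seed; same seed gives an identical series.
#' @param anthesis Anthesis timestamp; defaults to `season_start`.
#' @return A [weather_series()].
#' @export
generate_synthetic_weather <- function(season_start, season_end,
                                       T_mean_day = 285.15,
                                       T_amplitude_diurnal = 5,
                                       T_amplitude_seasonal = 14,
                                       RH_mean = 0.70,
                                       RH_amplitude = 0.18,
                                       noise_sd_T = 1.2,
                                       noise_sd_RH = 0.04,
                                       random_seed = 20150510L,
                                       anthesis = NULL) {
  season_start <- as.POSIXct(season_start, tz = "UTC")
  season_end <- as.POSIXct(season_end, tz = "UTC")
  if (season_end <= season_start) {
    stop("generate_synthetic_weather: season_end must be after season_start",
         call. = FALSE)
  }
  stopifnot(T_amplitude_diurnal >= 0, T_amplitude_seasonal >= 0,
            RH_amplitude >= 0, noise_sd_T >= 0, noise_sd_RH >= 0)
  time <- seq(season_start, season_end, by = "1 hour")
  hour <- as.numeric(format(time, "%H", tz = "UTC")) +
    as.numeric(format(time, "%M", tz = "UTC")) / 60
  doy <- as.numeric(format(time, "%j", tz = "UTC")) + hour / 24
  seasonal <- -T_amplitude_seasonal * cos(2 * pi * (doy - 15) / 365.25)
  shape <- diurnal_shape(hour)
  noise <- withr_seed_rnorm(random_seed, n = 2L * length(time))
  tair <- T_mean_day + seasonal + T_amplitude_diurnal * shape +
    noise_sd_T * noise[seq_along(time)]
  rh <- RH_mean - RH_amplitude * shape +
    noise_sd_RH * noise[length(time) + seq_along(time)]
  rh <- pmin(1, pmax(0.02, rh))
  if (is.null(anthesis)) anthesis <- season_start
  weather_series(time, tair, rh, anthesis = as.POSIXct(anthesis, tz = "UTC"))
}

# Draw n standard-normal deviates from a private RNG stream without
# touching the global .Random.seed.
withr_seed_rnorm <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  stats::rnorm(n)
}

#' Diurnal stem water potential
#'
#' Sinusoid attaining the (least negative) upper bound pre-dawn at 03:00
#' and the (most negative) lower bound at 15:00, the standard diurnal
#' course of stem water potential under transpirational load.
#'
#' @param hour_of_day Hour of day, 0-24 (fractional allowed, recycled mod 24).
#' @param bounds Length-2 numeric `c(low, high)` in MPa with
#'   `low < high <= 0`; default `c(-1.8, -0.10)`.
#' @return Stem water potential, MPa.
#' @export
stem_water_potential <- function(hour_of_day, bounds = c(-1.8, -0.10)) {
  low <- bounds[1]; high <- bounds[2]
  if (high > 0) stop("stem_water_potential: bounds must be <= 0 MPa",
                     call. = FALSE)
  if (low > high) stop("stem_water_potential: bounds must be c(low, high) with low <= high",
                       call. = FALSE)
  mid <- (low + high) / 2
  amp <- (high - low) / 2
  mid + amp * cos(2 * pi * ((hour_of_day %% 24) - 3) / 24)
}

#' Seasonal phloem sucrose concentration
#'
#' Default profile: half-cosine ramp over the simulated period, rising
#' from the lower bound at anthesis to the upper bound at `period` hours
#' (sucrose delivery strengthens as the canopy matures); bounded within
#' `bounds` for all t.
#'
#' @param t_hours Hours since anthesis.
#' @param bounds Length-2 numeric `c(low, high)`, mM; default `c(15, 100)`.
#' @param period Ramp duration, h; default 80 days.
#' @return Sucrose concentration, mol m^-3 (mM).
#' @export
phloem_sucrose <- function(t_hours, bounds = c(15, 100), period = 80 * 24) {
  low <- bounds[1]; high <- bounds[2]
  if (low > high) stop("phloem_sucrose: bounds must be c(low, high)",
                       call. = FALSE)
  mid <- (low + high) / 2
  amp <- (high - low) / 2
  mid - amp * cos(pi * pmax(0, t_hours) / period)
}

#' Derive the within-plant boundary drivers for a weather series
#'
#' @param series A [weather_series()].
#' @param psi_bounds Stem water potential bounds `c(low, high)`, MPa.
#' @param cp_bounds Phloem sucrose bounds `c(low, high)`, mM.
#' @param cp_period Sucrose seasonal ramp length, h.
#' @return Data frame with columns `psi_stem` (MPa) and `cp_mM`, row-aligned
#'   with `series`.
#' @export
environment_drivers <- function(series, psi_bounds = c(-1.8, -0.10),
                                cp_bounds = c(15, 100), cp_period = 80 * 24) {
  hour <- as.numeric(format(series$time, "%H", tz = "UTC"))
  t_h <- hours_since_anthesis(series)
  data.frame(
    psi_stem = stem_water_potential(hour, psi_bounds),
    cp_mM = phloem_sucrose(t_h, cp_bounds, cp_period)
  )
}
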