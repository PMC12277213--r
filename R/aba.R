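# Thermal time and empirical ABA accumulation.
#
# ABA concentration in the fruit follows a beta-growth curve of
# cumulative growing degree hours (cGDH): negligible below the onset
# region around ABA_m, a rapid sigmoidal rise, a peak of exactly ABA_f at
# cGDH = ABA_e, and a decline beyond the peak, matching the surge-peak-
# decline course measured in non-climacteric fruit. The normalised
# concentration ABA_norm in [0, 1] is the ripening signal consumed by the
# carbon- and water-flux modules.

#' Hourly growing-degree increment
#'
#' max(0, min(T_air, T_o) - T_b) for one hour: the ambient temperature is
#' capped at the optimum T_o and the excess over the base T_b accumulates.
#'
#' @param T_air Air temperature, K (vectorised).
#' @param T_b Base temperature, K.
#' @param T_o Optimal (capping) temperature, K; must exceed `T_b`.
#' @return Degree-hour increment, K h (for a 1 h step).
#' @export
gdh_increment <- function(T_air, T_b, T_o) {
  if (T_b >= T_o) stop("gdh_increment: requires T_b < T_o", call. = FALSE)
  pmax(0, pmin(T_air, T_o) - T_b)
}

#' Cumulative growing degree hours along a weather series
#'
#' Running sum of [gdh_increment()] starting at the anthesis time; hours
#' before anthesis contribute nothing.
#'
#' @param series A [weather_series()].
#' @param params A `parameter_set` (uses `T_b`, `T_o`).
#' @return Numeric vector of cGDH (K h), aligned with the series rows;
#'   non-decreasing from anthesis onward.
#' @export
cumulate_gdh <- function(series, params) {
  inc <- gdh_increment(series$tair, params$T_b, params$T_o)
  inc[hours_since_anthesis(series) < 0] <- 0
  # cGDH at a record is the thermal time accrued over the hours BEFORE it,
  # so the record at anthesis carries exactly 0
  c(0, cumsum(inc))[seq_along(inc)]
}

# Beta-growth shape used for both ABA accumulation (x = cGDH, m = ABA_m,
# e = ABA_e) and the ABA-modulated sugar-uptake factor (x = ABA_norm,
# m = STP_m, e = STP_e): g(x) = (1 + (e - x)/(e - m)) * (x/e)^(e/(e - m)),
# clamped at 0 where the raw form goes negative (x > 2e - m). g(0) = 0,
# g(e) = 1 (the unique maximum), declining beyond e.
beta_growth_shape <- function(x, m, e) {
  if (m >= e) stop("beta growth: requires m < e", call. = FALSE)
  g <- (1 + (e - x) / (e - m)) * (pmax(0, x) / e)^(e / (e - m))
  pmax(0, g)
}

#' ABA concentration from thermal time
#'
#' Empirical beta-growth accumulation: `ABA_0 + (ABA_f - ABA_0) * g(cGDH)`
#' with g peaking at 1 when cGDH = `ABA_e`, so the concentration attains
#' its maximum `ABA_f` there and declines beyond.
#'
#' @param cGDH Cumulative growing degree hours, K h (vectorised).
#' @param params A `parameter_set` (uses `ABA_0`, `ABA_f`, `ABA_m`, `ABA_e`).
#' @return ABA concentration, ug g^-1 dry mass.
#' @export
aba_concentration <- function(cGDH, params) {
  g <- beta_growth_shape(cGDH, params$ABA_m, params$ABA_e)
  params$ABA_0 + (params$ABA_f - params$ABA_0) * g
}

#' Normalised ABA concentration
#'
#' Linear map of the concentration onto \[0, 1\] with `ABA_0 -> 0` and
#' `ABA_f -> 1`, clamped; this is the dimensionless ripening signal used
#' by the flux equations.
#'
#' @param ABA_conc ABA concentration, ug g^-1 dry mass (vectorised).
#' @param params A `parameter_set` (uses `ABA_0`, `ABA_f`).
#' @return Dimensionless value in \[0, 1\].
#' @export
aba_normalize <- function(ABA_conc, params) {
  if (params$ABA_f == params$ABA_0) {
    stop("aba_normalize: ABA_f must differ from ABA_0", call. = FALSE)
  }
  pmin(1, pmax(0, (ABA_conc - params$ABA_0) / (params$ABA_f - params$ABA_0)))
}
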