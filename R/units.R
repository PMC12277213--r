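# Physical constants and unit conversions.
#
# Internal units throughout the package: temperature K, relative humidity
# as a fraction, water potential / pressure MPa, solute concentration
# mol m^-3 (numerically equal to mM), mass mg, time h, fluxes mg h^-1.
# All conversions from user-facing units (degC, %RH) happen at the I/O
# boundary, never inside the model core.

#' Physical constants used by the model
#'
#' @format A named list:
#' \describe{
#'   \item{R_gas}{Universal gas constant, J mol^-1 K^-1.}
#'   \item{M_water}{Molar mass of water, g mol^-1.}
#'   \item{M_sucrose}{Molar mass of sucrose, g mol^-1.}
#'   \item{zero_C}{0 degC in K.}
#' }
#' @keywords internal
bf_constants <- list(
  R_gas     = 8.314,
  M_water   = 18.015,
  M_sucrose = 342.30,
  zero_C    = 273.15
)

#' Convert degrees Celsius to Kelvin
#' @param x Temperature in degC.
#' @return Temperature in K.
#' @export
celsius_to_kelvin <- function(x) x + bf_constants$zero_C

#' Convert Kelvin to degrees Celsius
#' @param x Temperature in K.
#' @return Temperature in degC.
#' @export
kelvin_to_celsius <- function(x) x - bf_constants$zero_C

#' Saturation vapour pressure over liquid water
#'
#' Magnus-type formula with the Alduchov-Eskridge coefficients
#' (6.1094 hPa, 17.625, 243.04 degC), accurate to a fraction of a percent
#' over the physiological range.
#'
#' @param T_air Air temperature, K.
#' @return Saturation vapour pressure, Pa.
#' @export
saturation_vapor_pressure <- function(T_air) {
  Tc <- kelvin_to_celsius(T_air)
  610.94 * exp(17.625 * Tc / (Tc + 243.04))
}

#' Saturated water-vapour density of air
#'
#' The temperature-dependent coefficient that converts a relative-humidity
#' gradient into a mass flux of water vapour in the transpiration equation.
#' Computed from the Magnus saturation pressure and the ideal gas law,
#' alpha = M_w P_sat(T) / (R T).
#'
#' @param T_air Air temperature, K. Must lie in \[250, 330\] K.
#' @return Saturated vapour density, g cm^-3.
#' @examples
#' vapor_concentration(293.15) # ~1.73e-5 g cm^-3 at 20 degC
#' @export
vapor_concentration <- function(T_air) {
  if (any(!is.finite(T_air)) || any(T_air < 250) || any(T_air > 330)) {
    stop("vapor_concentration: T_air must be finite and within [250, 330] K",
         call. = FALSE)
  }
  p_sat <- saturation_vapor_pressure(T_air)          # Pa
  rho_kg_m3 <- bf_constants$M_water * 1e-3 * p_sat /
    (bf_constants$R_gas * T_air)                     # kg m^-3
  rho_kg_m3 * 1e-3                                   # g cm^-3
}

#' Van't Hoff osmotic pressure
#'
#' pi = R T C with C in mol m^-3, returned in MPa (1 Pa = 1e-6 MPa).
#'
#' @param C Total solute concentration, mol m^-3 (= mM).
#' @param T_air Temperature, K.
#' @return Osmotic pressure, MPa.
#' @export
osmotic_pressure <- function(C, T_air) {
  if (any(C < 0)) stop("osmotic_pressure: concentration must be >= 0",
                       call. = FALSE)
  bf_constants$R_gas * T_air * C * 1e-6
}

#' Convert a sucrose concentration from mM to a mass fraction
#'
#' The carbon-flux equations express sugar concentrations as mass fractions
#' (mg sugar per mg of solution water). 1 mM sucrose = 342.3 g m^-3 =
#' 342.3e-6 g per g water (dilute-solution approximation).
#'
#' @param C_mM Sucrose concentration, mM (mol m^-3).
#' @return Dimensionless mass fraction.
#' @export
sucrose_mM_to_fraction <- function(C_mM) {
  C_mM * bf_constants$M_sucrose * 1e-6
}

#' Convert a sugar mass fraction to molarity
#'
#' Inverse bookkeeping of [sucrose_mM_to_fraction()] used for the fruit
#' osmotic pressure: mg sugar per mg water times water density over the
#' sucrose molar mass.
#'
#' @param frac Mass fraction, mg sugar per mg water.
#' @return Concentration, mol m^-3.
#' @export
sucrose_fraction_to_mM <- function(frac) {
  frac * 1e6 / bf_constants$M_sucrose
}
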