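# Water flux: geometry, pressures, ABA-modulated conductivity and skin
# permeability, transpiration, the Lockhart turgor closure, and uptake.
#
# The fruit is one big cell behind a composite membrane. Boundary
# conditions: the xylem runs at the stem water potential with negligible
# osmotic content (P_x = psi_stem, pi_x ~ 0); the phloem is in
# water-potential equilibrium with the stem, so its hydrostatic pressure
# is P_p = psi_stem + pi_p(C_p). A single hydraulic conductivity L serves
# both pathways. Volume change is plastic (Lockhart) only; the elastic
# component and the dry-matter contribution to dV/dt are neglected in the
# turgor closure, where water dominates volume change.

#' Fruit volume from dry and water mass
#'
#' @param s Dry mass, mg.
#' @param w Water mass, mg.
#' @param params A `parameter_set` (uses `rho_water`, `rho_dry`).
#' @return Volume, cm^3.
#' @export
fruit_volume <- function(s, w, params) {
  w / params$rho_water + s / params$rho_dry
}

#' Fruit surface area from fresh mass
#'
#' Allometric scaling `A_f = c_area * (fresh/1000)^(2/3)` (fresh mass in
#' g inside the power law); the composite membrane area is
#' `A_m = a_mem * A_f`.
#'
#' @param fresh_mass Fresh mass, mg.
#' @param params A `parameter_set` (uses `c_area`).
#' @return Surface area, cm^2.
#' @export
fruit_surface_area <- function(fresh_mass, params) {
  params$c_area * (pmax(0, fresh_mass) / 1000)^(2 / 3)
}

#' Fruit osmotic pressure
#'
#' Van't Hoff pressure of the soluble-sugar pool (`ssr * s / w` converted
#' to molarity) plus a fixed non-sugar contribution `osm_other`
#' (organic acids, ions).
#'
#' @param s,w Dry and water mass, mg; `w > 0`.
#' @param T_air Temperature, K.
#' @param params A `parameter_set`.
#' @return Osmotic pressure, MPa.
#' @export
fruit_osmotic_pressure <- function(s, w, T_air, params) {
  C_sugar <- sucrose_fraction_to_mM(params$ssr * s / w)
  osmotic_pressure(C_sugar, T_air) + params$osm_other
}

#' ABA-modulated membrane hydraulic conductivity
#'
#' `L = L_max * exp(-k_L * ABA_norm)`: conductivity is maximal in the
#' absence of ABA and decays exponentially as the ripening signal rises.
#'
#' @param ABA_norm Normalised ABA signal in \[0, 1\] (vectorised).
#' @param params A `parameter_set` (uses `L_max`, `k_L`).
#' @return Conductivity, mg cm^-2 MPa^-1 h^-1.
#' @export
hydraulic_conductivity <- function(ABA_norm, params) {
  params$L_max * exp(-params$k_L * ABA_norm)
}

#' ABA-modulated fruit-skin permeability
#'
#' `rho = rho_min + rho_0 * exp(-k_p * ABA_norm)`: ABA thickens the
#' cuticular barrier, driving the permeability down towards `rho_min`.
#'
#' @param ABA_norm Normalised ABA signal in \[0, 1\] (vectorised).
#' @param params A `parameter_set` (uses `rho_min`, `rho_0`, `k_p`).
#' @return Skin permeability, cm h^-1.
#' @export
skin_permeability <- function(ABA_norm, params) {
  params$rho_min + params$rho_0 * exp(-params$k_p * ABA_norm)
}

#' Fruit transpiration
#'
#' `T_f = A_f * alpha(T) * rho(ABA_norm) * max(0, H_f - H_a) * 1000`
#' (g -> mg): proportional to surface area and to the humidity gradient
#' between the saturated internal air space (`H_f`) and the atmosphere;
#' condensation (H_a > H_f) is clamped to zero.
#'
#' @param A_f Fruit surface area, cm^2.
#' @param T_air Air temperature, K.
#' @param H_a Ambient relative humidity, fraction.
#' @param ABA_norm Normalised ABA signal.
#' @param params A `parameter_set`.
#' @return Transpiration, mg h^-1 (>= 0).
#' @export
transpiration <- function(A_f, T_air, H_a, ABA_norm, params) {
  if (any(H_a < 0 | H_a > 1)) {
    stop("transpiration: H_a must lie in [0, 1]", call. = FALSE)
  }
  A_f * vapor_concentration(T_air) * skin_permeability(ABA_norm, params) *
    pmax(0, params$H_f - H_a) * 1000
}

#' Cell-wall extensibility
#'
#' Logistic decay over developmental time,
#' `phi(t) = phi_max / (1 + exp((t - t_phi) / s_phi))`: walls stiffen as
#' the fruit matures, halving the extensibility at `t_phi`.
#'
#' @param t Hours since anthesis (vectorised).
#' @param params A `parameter_set` (uses `phi_max`, `t_phi`, `s_phi`).
#' @return Extensibility, MPa^-1 h^-1.
#' @export
extensibility <- function(t, params) {
  if (params$s_phi <= 0) stop("extensibility: s_phi must be > 0", call. = FALSE)
  params$phi_max * stats::plogis(-(t - params$t_phi) / params$s_phi)
}

#' Solve the Lockhart turgor closure
#'
#' Balances net membrane water inflow against plastic volume growth:
#' `A_m L [(P_x - P_f - sigma_x (pi_x - pi_f)) + (P_p - P_f - sigma_p (pi_p - pi_f))]
#'  - T_f = rho_water V phi (P_f - Y)`,
#' linear in the fruit turgor `P_f` (fluxes in mg h^-1; the right side
#' converts the volumetric growth rate with the water density). When the
#' solution exceeds the yield threshold `Y` the fruit grows plastically
#' at `V phi (P_f - Y)` cm^3 h^-1; otherwise the wall does not yield,
#' the growth term is dropped, and `P_f` (clamped at >= 0) simply sets
#' the net water exchange. The two branches meet continuously at
#' `P_f = Y`.
#'
#' @param V Fruit volume, cm^3 (> 0).
#' @param A_m Composite membrane area, cm^2.
#' @param L Hydraulic conductivity, mg cm^-2 MPa^-1 h^-1.
#' @param P_x,pi_x Xylem hydrostatic and osmotic pressure, MPa.
#' @param P_p,pi_p Phloem hydrostatic and osmotic pressure, MPa.
#' @param pi_f Fruit osmotic pressure, MPa.
#' @param T_f Transpiration, mg h^-1.
#' @param phi Cell-wall extensibility, MPa^-1 h^-1.
#' @param params A `parameter_set` (uses `Y`, `sigma_x`, `sigma_p`,
#'   `rho_water`).
#' @return List with `P_f` (MPa), `growth_rate` (plastic volume growth,
#'   cm^3 h^-1, 0 on the non-yielding branch) and `yielding` (logical).
#' @export
solve_turgor <- function(V, A_m, L, P_x, pi_x, P_p, pi_p, pi_f, T_f, phi,
                         params) {
  AL <- A_m * L                              # mg h^-1 MPa^-1 per pathway
  C <- (P_x - params$sigma_x * (pi_x - pi_f)) +
       (P_p - params$sigma_p * (pi_p - pi_f))
  k_growth <- params$rho_water * V * phi     # mg h^-1 MPa^-1
  if (AL <= 0) {
    # membrane closed: no uptake, the wall cannot be pressurised
    out <- list(P_f = 0, growth_rate = 0, yielding = FALSE)
  } else {
    P_f <- (AL * C - T_f + k_growth * params$Y) / (2 * AL + k_growth)
    if (is.finite(P_f) && P_f > params$Y) {
      out <- list(P_f = P_f, growth_rate = V * phi * (P_f - params$Y),
                  yielding = TRUE)
    } else {
      P_f <- max(0, (AL * C - T_f) / (2 * AL))
      out <- list(P_f = P_f, growth_rate = 0, yielding = FALSE)
    }
  }
  if (!is.finite(out$P_f)) {
    stop(sprintf(
      "solve_turgor: non-finite turgor (V=%g, A_m=%g, L=%g, C=%g, T_f=%g, phi=%g)",
      V, A_m, L, C, T_f, phi), call. = FALSE)
  }
  out
}

#' Water uptake through the xylem and phloem pathways
#'
#' `U_x = A_m L (P_x - P_f - sigma_x (pi_x - pi_f))` and analogously for
#' the phloem. Either pathway may individually run backwards (negative
#' uptake, e.g. midday xylem backflow).
#'
#' @param P_f Fruit turgor, MPa.
#' @param pi_f Fruit osmotic pressure, MPa.
#' @param P_x,pi_x,P_p,pi_p Boundary pressures, MPa.
#' @param A_m Membrane area, cm^2.
#' @param L Hydraulic conductivity, mg cm^-2 MPa^-1 h^-1.
#' @param params A `parameter_set` (uses `sigma_x`, `sigma_p`).
#' @return List with `U_x`, `U_p`, mg h^-1.
#' @export
water_uptake <- function(P_f, pi_f, P_x, pi_x, P_p, pi_p, A_m, L, params) {
  AL <- A_m * L
  list(U_x = AL * (P_x - P_f - params$sigma_x * (pi_x - pi_f)),
       U_p = AL * (P_p - P_f - params$sigma_p * (pi_p - pi_f)))
}

#' Water-mass rate
#'
#' The water balance `dw/dt = U_x + U_p - T_f`, exactly.
#'
#' @param U_x,U_p Water uptake from xylem and phloem, mg h^-1.
#' @param T_f Transpiration, mg h^-1.
#' @return Rate of water-mass change, mg h^-1.
#' @export
water_mass_rate <- function(U_x, U_p, T_f) {
  U_x + U_p - T_f
}
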