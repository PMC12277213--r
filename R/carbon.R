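# Carbon flux: sugar uptake (active + mass flow + diffusion), respiration
# (growth + maintenance + ripening) and the dry-mass rate.
#
# Sugar concentrations on the carbon side are dimensionless mass
# fractions (mg sugar per mg water); the mM phloem driver is converted
# with the sucrose molar mass (see sucrose_mM_to_fraction). The ripening
# respiration term q_r * ABA_norm enters in mg h^-1 directly (unscaled by
# dry mass), matching the printed unit of q_r.

#' ABA-modulated sugar uptake factor
#'
#' `k_ABA * B(u)` with B the beta-growth shape in the normalised ABA
#' signal u, anchored at the thresholds `STP_m` (below which ABA barely
#' promotes uptake) and `STP_e` (the optimum, where the factor peaks at
#' `k_ABA`, declining beyond).
#'
#' @param ABA_norm Normalised ABA signal in \[0, 1\] (vectorised).
#' @param params A `parameter_set` (uses `k_ABA`, `STP_m`, `STP_e`).
#' @return Dimensionless factor >= 0.
#' @export
aba_sugar_factor <- function(ABA_norm, params) {
  if (params$STP_e <= params$STP_m) {
    stop("aba_sugar_factor: requires STP_m < STP_e", call. = FALSE)
  }
  params$k_ABA * beta_growth_shape(ABA_norm, params$STP_m, params$STP_e)
}

#' Inhibitor activity of active sugar transport
#'
#' Logistic decay `1 / (1 + exp((t - t_star) / tau))`: near 1 early in
#' development, 0.5 at `t_star`, and approaching 0 late, switching the
#' active transport machinery off towards the end of the season.
#'
#' @param t Hours since anthesis (vectorised).
#' @param t_star Midpoint time, h.
#' @param tau Time constant, h; must be > 0.
#' @return Dimensionless activity in (0, 1).
#' @export
inhibitor_activity <- function(t, t_star, tau) {
  if (tau <= 0) stop("inhibitor_activity: tau must be > 0", call. = FALSE)
  stats::plogis(-(t - t_star) / tau)
}

#' Active sugar uptake through the apoplastic pathway
#'
#' Multiplicative structure: ABA factor x Michaelis-Menten saturation in
#' the phloem sugar concentration x dry mass x inhibitor activity,
#' `U_a = aba_sugar_factor(u) * v_m * s * C_p / (K_m + C_p) * inhibitor(t)`.
#'
#' @param s Dry mass, mg.
#' @param C_p Phloem sugar concentration as a mass fraction.
#' @param t Hours since anthesis.
#' @param ABA_norm Normalised ABA signal.
#' @param params A `parameter_set`.
#' @return Active uptake, mg h^-1 (>= 0).
#' @export
active_sugar_uptake <- function(s, C_p, t, ABA_norm, params) {
  aba_sugar_factor(ABA_norm, params) * params$v_m * s *
    C_p / (params$K_m + C_p) *
    inhibitor_activity(t, params$t_star, params$tau)
}

#' Passive sugar fluxes: mass flow and diffusion
#'
#' Mass flow carries sugar with the phloem water stream,
#' `U_mf = max(0, U_p) * C_p` (no reverse sugar flow from fruit to
#' phloem); diffusion across the composite membrane is
#' `U_diff = max(0, p_s * A_m * (C_p - C_f))` with the fruit sugar
#' concentration `C_f = ssr * s / w`.
#'
#' @param U_p Phloem water uptake, mg h^-1 (may be negative; clamped).
#' @param C_p Phloem sugar mass fraction.
#' @param s,w Dry and water mass, mg; `w` must be > 0.
#' @param A_m Composite membrane area, cm^2.
#' @param params A `parameter_set` (uses `p_s`, `ssr`).
#' @return List with `U_mf`, `U_diff` (mg h^-1, both >= 0) and `C_f`.
#' @export
passive_sugar_fluxes <- function(U_p, C_p, s, w, A_m, params) {
  if (any(w <= 0)) {
    stop("passive_sugar_fluxes: water mass must be > 0 to form C_f",
         call. = FALSE)
  }
  C_f <- params$ssr * s / w
  list(U_mf = pmax(0, U_p) * C_p,
       U_diff = pmax(0, params$p_s * A_m * (C_p - C_f)),
       C_f = C_f)
}

#' Temperature-dependent maintenance respiration coefficient
#'
#' Q10 scaling: `q_m_ref * Q10^((T_air - T_ref) / 10)`.
#'
#' @param T_air Air temperature, K (vectorised).
#' @param params A `parameter_set` (uses `q_m_ref`, `Q10`, `T_ref`).
#' @return Maintenance coefficient, h^-1.
#' @export
maintenance_coeff <- function(T_air, params) {
  params$q_m_ref * params$Q10^((T_air - params$T_ref) / 10)
}

#' Dry-mass rate and respiration
#'
#' Respiration `R_f = q_g * max(0, ds/dt) + q_m(T) * s + q_r * ABA_norm`
#' is coupled to the growth rate it feeds on; solving the linear coupling
#' with `ds/dt = U_s - R_f` gives
#' `ds/dt = (U_s - q_m s - q_r ABA_norm) / (1 + q_g)` when that is
#' non-negative, and `ds/dt = U_s - q_m s - q_r ABA_norm` otherwise
#' (growth respiration is not charged on shrinkage). The returned pair
#' satisfies `ds_dt = U_s - R_f` exactly.
#'
#' @param U_s Total sugar uptake, mg h^-1.
#' @param s Dry mass, mg.
#' @param T_air Air temperature, K.
#' @param ABA_norm Normalised ABA signal.
#' @param params A `parameter_set`.
#' @return List with `ds_dt` and `R_f`, mg h^-1.
#' @export
dry_mass_rate <- function(U_s, s, T_air, ABA_norm, params) {
  base <- U_s - maintenance_coeff(T_air, params) * s - params$q_r * ABA_norm
  ds_dt <- ifelse(base >= 0, base / (1 + params$q_g), base)
  list(ds_dt = ds_dt, R_f = U_s - ds_dt)
}
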