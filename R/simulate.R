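# Hourly integration of the coupled dry-mass / water-mass system.
#
# Fixed-step explicit Euler at the weather resolution (1 h), with
# optional integer substepping; drivers are held constant within each
# hour. cGDH, ABA and every purely time/weather-dependent quantity are
# precomputed as vectors; only the state-dependent fluxes run in the
# sequential loop.

#' Initial fruit state
#'
#' @param s_0 Initial dry mass, mg (> 0).
#' @param w_0 Initial water mass, mg (> 0).
#' @param params A `parameter_set` (for the initial ABA concentration).
#' @return A list with `t` (h), `s`, `w`, `fresh` (mg), `cGDH` (K h),
#'   `ABA_conc` (ug g^-1), `ABA_norm`.
#' @export
initialize_state <- function(s_0, w_0, params = default_parameters()) {
  if (s_0 <= 0 || w_0 <= 0) {
    stop("initialize_state: s_0 and w_0 must be > 0", call. = FALSE)
  }
  list(t = 0, s = s_0, w = w_0, fresh = s_0 + w_0, cGDH = 0,
       ABA_conc = aba_concentration(0, params),
       ABA_norm = aba_normalize(aba_concentration(0, params), params))
}

# All fluxes and diagnostics at a given state under given environmental
# conditions. `t` is hours since anthesis; `cGDH` the thermal time already
# accumulated.
compute_fluxes <- function(s, w, t, tair, rh, psi_stem, cp_mM, cGDH, params) {
  ABA_conc <- aba_concentration(cGDH, params)
  ABA_norm <- aba_normalize(ABA_conc, params)

  V <- fruit_volume(s, w, params)
  fresh <- s + w
  A_f <- fruit_surface_area(fresh, params)
  A_m <- params$a_mem * A_f

  pi_f <- fruit_osmotic_pressure(s, w, tair, params)
  pi_p <- osmotic_pressure(cp_mM, tair)
  P_x <- psi_stem; pi_x <- 0
  P_p <- psi_stem + pi_p                      # phloem equilibrated with stem

  L <- hydraulic_conductivity(ABA_norm, params)
  rho_skin <- skin_permeability(ABA_norm, params)
  T_f <- transpiration(A_f, tair, rh, ABA_norm, params)
  phi <- extensibility(t, params)

  turgor <- solve_turgor(V, A_m, L, P_x, pi_x, P_p, pi_p, pi_f, T_f, phi,
                         params)
  up <- water_uptake(turgor$P_f, pi_f, P_x, pi_x, P_p, pi_p, A_m, L, params)
  dw_dt <- water_mass_rate(up$U_x, up$U_p, T_f)

  C_p <- sucrose_mM_to_fraction(cp_mM)
  inhib <- inhibitor_activity(t, params$t_star, params$tau)
  U_a <- active_sugar_uptake(s, C_p, t, ABA_norm, params)
  passive <- passive_sugar_fluxes(up$U_p, C_p, s, w, A_m, params)
  U_s <- U_a + passive$U_mf + passive$U_diff
  carbon <- dry_mass_rate(U_s, s, tair, ABA_norm, params)

  # residual of the flux-balance equation solve_turgor was built from
  AL <- A_m * L
  C_drive <- (P_x - params$sigma_x * (pi_x - pi_f)) +
             (P_p - params$sigma_p * (pi_p - pi_f))
  residual <- if (turgor$yielding) {
    AL * (C_drive - 2 * turgor$P_f) - T_f -
      params$rho_water * V * phi * (turgor$P_f - params$Y)
  } else if (AL > 0 && turgor$P_f > 0) {
    AL * (C_drive - 2 * turgor$P_f) - T_f
  } else 0

  list(ABA_conc = ABA_conc, ABA_norm = ABA_norm, V = V, A_f = A_f, A_m = A_m,
       pi_f = pi_f, pi_p = pi_p, P_f = turgor$P_f, L = L,
       rho_skin = rho_skin, phi = phi, inhibitor = inhib,
       growth_rate = turgor$growth_rate, yielding = turgor$yielding,
       turgor_residual = residual,
       U_x = up$U_x, U_p = up$U_p, T_f = T_f, dw_dt = dw_dt,
       U_a = U_a, U_mf = passive$U_mf, U_diff = passive$U_diff,
       U_s = U_s, R_f = carbon$R_f, ds_dt = carbon$ds_dt)
}

#' Advance the fruit state by one time step
#'
#' Explicit-Euler update of dry and water mass under environmental
#' conditions held constant over the step; thermal time advances by
#' `gdh_increment * dt` and ABA is recomputed from the new cGDH. Masses
#' are clamped at zero (water at a hair above, so concentrations stay
#' defined) with a warning when clamping fires.
#'
#' @param state State list as from [initialize_state()].
#' @param record List or one-row data frame with `tair` (K) and `rh`.
#' @param drivers List with `psi_stem` (MPa) and `cp_mM`.
#' @param params A `parameter_set`.
#' @param dt Step length, h (> 0).
#' @return List with elements `state` (advanced) and `diagnostics`
#'   (fluxes and pressures evaluated at the incoming state).
#' @export
step_fruit <- function(state, record, drivers, params, dt = 1) {
  if (dt <= 0) stop("step: dt must be > 0", call. = FALSE)
  fl <- compute_fluxes(state$s, state$w, state$t, record$tair, record$rh,
                       drivers$psi_stem, drivers$cp_mM, state$cGDH, params)
  if (!all(is.finite(c(fl$ds_dt, fl$dw_dt)))) {
    stop(sprintf("step: non-finite flux at t=%g h (s=%g, w=%g)",
                 state$t, state$s, state$w), call. = FALSE)
  }
  s_new <- state$s + fl$ds_dt * dt
  w_new <- state$w + fl$dw_dt * dt
  if (s_new < 0 || w_new < 1e-9) {
    warning(sprintf("step: state clamped at t=%g h (s=%.4g, w=%.4g)",
                    state$t + dt, s_new, w_new), call. = FALSE)
    s_new <- max(0, s_new)
    w_new <- max(1e-9, w_new)
  }
  cGDH_new <- state$cGDH + gdh_increment(record$tair, params$T_b, params$T_o) * dt
  ABA_new <- aba_concentration(cGDH_new, params)
  state_new <- list(t = state$t + dt, s = s_new, w = w_new,
                    fresh = s_new + w_new, cGDH = cGDH_new,
                    ABA_conc = ABA_new,
                    ABA_norm = aba_normalize(ABA_new, params))
  list(state = state_new, diagnostics = fl)
}

#' Simulate fruit growth over a season
#'
#' Integrates the coupled state hourly from anthesis for
#' `duration_days`, returning one row per hour (duration_days * 24 + 1
#' rows) with the full state, flux and pressure diagnostics.
#' Deterministic given its inputs.
#'
#' @param weather A [weather_series()] covering anthesis to
#'   anthesis + duration.
#' @param params A `parameter_set`; defaults to the packaged set.
#' @param duration_days Simulated span, days after anthesis.
#' @param substeps Integer >= 1; Euler substeps per hour (drivers held
#'   constant within the hour).
#' @param psi_bounds Stem water potential bounds, MPa.
#' @param cp_bounds Phloem sucrose bounds, mM.
#' @param cp_period Sucrose seasonal ramp, h; defaults to the simulated span.
#' @param warn_clamp Warn if state clamping at zero fires.
#' @return A `simulation_result` data frame.
#' @export
simulate_fruit <- function(weather, params = default_parameters(),
                           duration_days = 80, substeps = 1L,
                           psi_bounds = c(-1.8, -0.10),
                           cp_bounds = c(15, 100),
                           cp_period = max(1, duration_days * 24),
                           warn_clamp = TRUE) {
  stopifnot(duration_days >= 0, substeps >= 1L)
  params <- validate_parameters(params)
  n_hours <- round(duration_days * 24)

  t_rel <- hours_since_anthesis(weather)
  i0 <- which(abs(t_rel) < 1e-6)
  if (length(i0) != 1L) {
    stop(sprintf("simulate_fruit: weather has no record at anthesis (%s)",
                 format(anthesis_time(weather))), call. = FALSE)
  }
  if (i0 + n_hours > nrow(weather)) {
    stop(sprintf(
      "simulate_fruit: weather ends %s but coverage to %s is required",
      format(weather$time[nrow(weather)]),
      format(anthesis_time(weather) + n_hours * 3600)), call. = FALSE)
  }
  idx <- i0:(i0 + n_hours)                  # hour nodes 0..n_hours
  tair_h <- weather$tair[idx]
  rh_h <- weather$rh[idx]
  time <- weather$time[idx]
  hour_of_day <- as.numeric(format(time, "%H", tz = "UTC"))
  psi_h <- stem_water_potential(hour_of_day, psi_bounds)
  inc <- gdh_increment(tair_h, params$T_b, params$T_o)
  cGDH_h <- c(0, cumsum(inc[-length(inc)])) # thermal time accrued before node i

  # substep grid: m = n_hours * substeps + 1 nodes; hourly weather is held
  # constant within the hour, time-continuous quantities use the sub-time
  dt_sub <- 1 / substeps
  m <- n_hours * substeps + 1L
  hr <- pmin(n_hours, (seq_len(m) - 1L) %/% substeps) + 1L  # hour row index
  hr[m] <- n_hours + 1L
  t_g <- (seq_len(m) - 1L) * dt_sub
  frac <- t_g - (hr - 1L)                   # hours into the current hour
  frac[m] <- 0
  cGDH_g <- cGDH_h[hr] + inc[hr] * frac
  cGDH_g[m] <- cGDH_h[n_hours + 1L]
  tair <- tair_h[hr]; rh <- rh_h[hr]; psi_stem <- psi_h[hr]
  cp_mM <- phloem_sucrose(t_g, cp_bounds, cp_period)

  # precompute every state-independent coefficient on the substep grid
  ABA_conc <- aba_concentration(cGDH_g, params)
  ABA_norm <- aba_normalize(ABA_conc, params)
  Lv <- hydraulic_conductivity(ABA_norm, params)
  rho_skin <- skin_permeability(ABA_norm, params)
  trans_coef <- vapor_concentration(tair) * rho_skin *
    pmax(0, params$H_f - rh) * 1000         # T_f = A_f * trans_coef
  phi_v <- extensibility(t_g, params)
  inhib <- inhibitor_activity(t_g, params$t_star, params$tau)
  pi_p <- osmotic_pressure(cp_mM, tair)
  P_x <- psi_stem
  P_p <- psi_stem + pi_p
  C_p <- sucrose_mM_to_fraction(cp_mM)
  act_coef <- aba_sugar_factor(ABA_norm, params) * params$v_m *
    C_p / (params$K_m + C_p) * inhib        # U_a = act_coef * s
  q_m <- maintenance_coeff(tair, params)
  qr_term <- params$q_r * ABA_norm
  pif_coef <- bf_constants$R_gas * tair * params$ssr /
    bf_constants$M_sucrose                  # pi_f = pif_coef*s/w + osm_other

  rw <- params$rho_water; rd <- params$rho_dry
  sx <- params$sigma_x; sp <- params$sigma_p
  Y <- params$Y; q_g <- params$q_g; p_s <- params$p_s; ssr <- params$ssr
  a_mem <- params$a_mem; c_area <- params$c_area; osm_o <- params$osm_other

  n <- n_hours + 1L
  diag_names <- c("ABA_conc", "ABA_norm", "V", "A_f", "A_m", "pi_f", "pi_p",
                  "P_f", "L", "rho_skin", "phi", "inhibitor", "growth_rate",
                  "turgor_residual", "U_x", "U_p", "T_f", "dw_dt",
                  "U_a", "U_mf", "U_diff", "U_s", "R_f", "ds_dt")
  rec <- matrix(NA_real_, nrow = n, ncol = length(diag_names),
                dimnames = list(NULL, diag_names))
  yielding <- logical(n)
  s_out <- numeric(n); w_out <- numeric(n)

  s <- params$s_0; w <- params$w_0
  clamped <- FALSE
  for (j in seq_len(m)) {
    V <- w / rw + s / rd
    fresh <- s + w
    A_f <- c_area * (fresh / 1000)^(2 / 3)
    A_m <- a_mem * A_f
    pi_f <- pif_coef[j] * s / w + osm_o
    T_f <- A_f * trans_coef[j]
    AL <- A_m * Lv[j]
    C_drive <- (P_x[j] - sx * (0 - pi_f)) + (P_p[j] - sp * (pi_p[j] - pi_f))
    k_growth <- rw * V * phi_v[j]
    if (AL <= 0) {
      P_f <- 0; growth <- 0; yld <- FALSE
    } else {
      P_f <- (AL * C_drive - T_f + k_growth * Y) / (2 * AL + k_growth)
      if (is.finite(P_f) && P_f > Y) {
        growth <- V * phi_v[j] * (P_f - Y); yld <- TRUE
      } else {
        P_f <- max(0, (AL * C_drive - T_f) / (2 * AL))
        growth <- 0; yld <- FALSE
      }
    }
    U_x <- AL * (P_x[j] - P_f - sx * (0 - pi_f))
    U_p <- AL * (P_p[j] - P_f - sp * (pi_p[j] - pi_f))
    dw_dt <- U_x + U_p - T_f
    U_a <- act_coef[j] * s
    C_f <- ssr * s / w
    U_mf <- max(0, U_p) * C_p[j]
    U_diff <- max(0, p_s * A_m * (C_p[j] - C_f))
    U_s <- U_a + U_mf + U_diff
    base <- U_s - q_m[j] * s - qr_term[j]
    ds_dt <- if (base >= 0) base / (1 + q_g) else base
    R_f <- U_s - ds_dt

    if (!is.finite(ds_dt) || !is.finite(dw_dt)) {
      stop(sprintf("simulate_fruit: non-finite flux at t=%g h (s=%g, w=%g)",
                   t_g[j], s, w), call. = FALSE)
    }
    at_node <- (j - 1L) %% substeps == 0L
    if (at_node) {
      i <- (j - 1L) %/% substeps + 1L
      s_out[i] <- s; w_out[i] <- w
      residual <- if (yld) {
        AL * (C_drive - 2 * P_f) - T_f - k_growth * (P_f - Y)
      } else if (AL > 0 && P_f > 0) {
        AL * (C_drive - 2 * P_f) - T_f
      } else 0
      rec[i, ] <- c(ABA_conc[j], ABA_norm[j], V, A_f, A_m, pi_f, pi_p[j],
                    P_f, Lv[j], rho_skin[j], phi_v[j], inhib[j], growth,
                    residual, U_x, U_p, T_f, dw_dt,
                    U_a, U_mf, U_diff, U_s, R_f, ds_dt)
      yielding[i] <- yld
    }
    if (j == m) break
    s_new <- s + ds_dt * dt_sub
    w_new <- w + dw_dt * dt_sub
    if (s_new < 0 || w_new < 1e-9) {
      clamped <- TRUE
      s_new <- max(0, s_new)
      w_new <- max(1e-9, w_new)
    }
    s <- s_new; w <- w_new
  }
  if (clamped && warn_clamp) {
    warning("simulate_fruit: state clamping at zero fired during the run",
            call. = FALSE)
  }

  t_h <- 0:n_hours
  node <- (t_h * substeps) + 1L
  cols <- c(list(time = time, t = t_h, DAA = floor(t_h / 24),
                 tair = tair_h, rh = rh_h, psi_stem = psi_h,
                 cp_mM = cp_mM[node], cGDH = cGDH_h,
                 s = s_out, w = w_out, fresh = s_out + w_out),
            lapply(seq_along(diag_names), function(k) rec[, k]),
            list(yielding = yielding))
  names(cols) <- c("time", "t", "DAA", "tair", "rh", "psi_stem", "cp_mM",
                   "cGDH", "s", "w", "fresh", diag_names, "yielding")
  out <- structure(cols, row.names = seq_len(n),
                   class = "data.frame")
  attr(out, "anthesis") <- anthesis_time(weather)
  attr(out, "params") <- params
  attr(out, "substeps") <- substeps
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' @export
print.simulation_result <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("<simulation_result> %d hourly rows, 0..%d DAA\n",
              n, max(x$DAA)))
  cat(sprintf("  final: dry %.1f mg, water %.1f mg, fresh %.1f mg\n",
              x$s[n], x$w[n], x$fresh[n]))
  cat(sprintf("  ABA peak: %.2f ug/g at %.0f DAA\n",
              max(x$ABA_conc), x$DAA[which.max(x$ABA_conc)]))
  invisible(x)
}

#' Aggregate fruit masses over a harvest window
#'
#' @param result A `simulation_result`.
#' @param window Length-2 vector of POSIXct/Date (or strings) giving the
#'   inclusive window bounds, or a month-day string `"MM-DD:MM-DD"`
#'   resolved in the simulated year.
#' @return Data frame with one row per variable (dry, water, fresh):
#'   mean, min, max over the hourly rows inside the window.
#' @export
harvest_summary <- function(result, window = "07-25:08-31") {
  if (is.character(window) && length(window) == 1L && grepl(":", window)) {
    parts <- strsplit(window, ":", fixed = TRUE)[[1]]
    year <- format(result$time[1], "%Y", tz = "UTC")
    window <- as.POSIXct(paste0(year, "-", parts, c(" 00:00:00", " 23:00:00")),
                         tz = "UTC")
  } else {
    window <- as.POSIXct(window, tz = "UTC")
  }
  sel <- result$time >= window[1] & result$time <= window[2]
  if (!any(sel)) {
    stop(sprintf("harvest_summary: window %s..%s does not overlap the run",
                 format(window[1]), format(window[2])), call. = FALSE)
  }
  vars <- c(dry = "s", water = "w", fresh = "fresh")
  data.frame(
    variable = names(vars),
    mean = vapply(vars, function(v) mean(result[[v]][sel]), numeric(1)),
    min = vapply(vars, function(v) min(result[[v]][sel]), numeric(1)),
    max = vapply(vars, function(v) max(result[[v]][sel]), numeric(1)),
    n_hours = sum(sel), row.names = NULL, stringsAsFactors = FALSE)
}

#' Packaged synthetic growing season
#'
#' Convenience wrapper bundling the default synthetic weather (temperate
#' continental season, anthesis 10 May) used by the examples and tests.
#'
#' @param duration_days Days after anthesis to cover.
#' @param random_seed Seed for the weather noise.
#' @param ... Passed to [generate_synthetic_weather()].
#' @return A [weather_series()].
#' @export
synthetic_season <- function(duration_days = 80, random_seed = 20150510L, ...) {
  anthesis <- as.POSIXct("2015-05-10 00:00:00", tz = "UTC")
  generate_synthetic_weather(
    season_start = anthesis,
    season_end = anthesis + (duration_days * 24 + 1) * 3600,
    random_seed = random_seed, anthesis = anthesis, ...)
}
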