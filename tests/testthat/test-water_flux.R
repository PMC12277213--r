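# Geometry, pressures, ABA-modulated water transport and the turgor solve.

test_that("volume and surface area follow the documented closures", {
  p <- bare_params(rho_water = 1000, rho_dry = 1600, c_area = 4.84)
  expect_equal(fruit_volume(0, 1000, p), 1.0)
  expect_equal(fruit_volume(160, 0, p), 0.1)
  expect_equal(fruit_volume(160, 840, p), 0.94)
  expect_equal(fruit_surface_area(1000, p), 4.84)
  expect_equal(fruit_surface_area(8000, p), 4 * fruit_surface_area(1000, p))
  expect_equal(fruit_surface_area(0, p), 0)
})

test_that("van't Hoff osmotic pressure is linear in concentration", {
  expect_equal(osmotic_pressure(0, 293.15), 0)
  expect_equal(osmotic_pressure(100, 293.15), 8.314 * 293.15 * 100 * 1e-6,
               tolerance = 1e-12)
  expect_equal(round(osmotic_pressure(100, 293.15), 4), 0.2437)
  expect_equal(osmotic_pressure(200, 293.15), 2 * osmotic_pressure(100, 293.15))
  expect_error(osmotic_pressure(-1, 293.15), ">= 0")
})

test_that("conductivity and skin permeability decay with the ABA signal", {
  p <- bare_params(L_max = 2, k_L = 1, rho_min = 20, rho_0 = 100, k_p = 2)
  expect_equal(hydraulic_conductivity(0, p), 2)
  expect_equal(hydraulic_conductivity(1, p), 2 * exp(-1), tolerance = 1e-12)
  u <- seq(0, 1, by = 0.01)
  expect_true(all(diff(hydraulic_conductivity(u, p)) < 0))
  expect_equal(skin_permeability(0, p), 120)
  expect_equal(skin_permeability(0.5, p), 20 + 100 * exp(-1), tolerance = 1e-12)
  expect_equal(round(skin_permeability(0.5, p), 2), 56.79)
  pinf <- bare_params(rho_min = 20, rho_0 = 100, k_p = 1e6)
  expect_equal(skin_permeability(0.5, pinf), 20, tolerance = 1e-6)
  expect_true(all(diff(skin_permeability(u, p)) < 0))
})

test_that("transpiration is proportional to area and the humidity gradient", {
  p <- bare_params(H_f = 0.9, rho_min = 100, rho_0 = 0, k_p = 1)
  expect_equal(transpiration(5, 293.15, 0.9, 0, p), 0)      # H_a = H_f
  t1 <- transpiration(5, 293.15, 0.5, 0, p)
  expect_equal(transpiration(10, 293.15, 0.5, 0, p), 2 * t1)
  expect_equal(t1, 5 * vapor_concentration(293.15) * 100 * 0.4 * 1000,
               tolerance = 1e-12)
  expect_equal(transpiration(5, 293.15, 0.95, 0, p), 0)     # condensation clamp
  # non-increasing in the ABA signal at fixed geometry and weather
  pfull <- bare_params()
  u <- seq(0, 1, by = 0.05)
  tf <- vapply(u, function(x) transpiration(5, 293.15, 0.5, x, pfull),
               numeric(1))
  expect_true(all(diff(tf) <= 0))
})

test_that("extensibility is a decaying logistic with documented anchors", {
  p <- bare_params(phi_max = 0.04, t_phi = 900, s_phi = 250)
  expect_equal(extensibility(-1e9, p), 0.04)
  expect_equal(extensibility(900, p), 0.02)
  expect_equal(extensibility(900 + 250 * log(9), p), 0.004, tolerance = 1e-12)
  expect_error(extensibility(0, bare_params(s_phi = 0)), "s_phi")
})

test_that("turgor solve balances fluxes and handles both branches", {
  # worked linear case: AL = 1 per pathway, effective potentials 0.2/0.4,
  # transpiration equivalent 0.1, V phi = 1 (rho_water folded to 1), Y = 0.1
  p <- list(Y = 0.1, sigma_x = 1, sigma_p = 1, rho_water = 1)
  sol <- solve_turgor(V = 1, A_m = 1, L = 1, P_x = 0.2, pi_x = 0,
                      P_p = 0.4, pi_p = 0, pi_f = 0, T_f = 0.1, phi = 1,
                      params = p)
  expect_equal(sol$P_f, 0.2, tolerance = 1e-12)
  expect_equal(sol$growth_rate, 0.1, tolerance = 1e-12)
  expect_true(sol$yielding)
  # flux balance: net inflow 0.2 - transpiration 0.1 = growth 0.1
  net_in <- 1 * (0.2 - sol$P_f) + 1 * (0.4 - sol$P_f) - 0.1
  expect_equal(net_in, sol$growth_rate, tolerance = 1e-12)

  # equilibrium: no transpiration, equal potentials, rigid wall
  sol_eq <- solve_turgor(1, 1, 1, P_x = 0.3, pi_x = 0, P_p = 0.3, pi_p = 0,
                         pi_f = 0, T_f = 0, phi = 0, params = p)
  expect_equal(sol_eq$P_f, 0.3, tolerance = 1e-12)
  up <- water_uptake(sol_eq$P_f, 0, 0.3, 0, 0.3, 0, 1, 1, p)
  expect_equal(up$U_x + up$U_p, 0, tolerance = 1e-12)

  # closed membrane: volume loss at the transpiration rate
  sol_cl <- solve_turgor(1, 1, 0, 0.3, 0, 0.3, 0, 0, T_f = 0.5, phi = 1,
                         params = p)
  expect_equal(sol_cl$P_f, 0)
  expect_equal(sol_cl$growth_rate, 0)

  # continuity across the yield boundary: nudge the drive through the
  # point where P_f = Y and check the solution moves continuously
  drive <- seq(0.05, 0.25, by = 1e-3)
  pf <- vapply(drive, function(d) {
    solve_turgor(1, 1, 1, P_x = d, pi_x = 0, P_p = d, pi_p = 0, pi_f = 0,
                 T_f = 0, phi = 1, params = p)$P_f
  }, numeric(1))
  expect_lt(max(abs(diff(pf))), 2e-3)
})

test_that("water uptake responds to pressure and osmotic gradients", {
  p <- list(sigma_x = 0.9, sigma_p = 0.9)
  # boundary pressure chosen so the effective gradient vanishes
  up0 <- water_uptake(0.3, 0.5, P_x = 0.3 + 0.9 * (0 - 0.5), pi_x = 0,
                      P_p = 0.3 + 0.9 * (0 - 0.5), pi_p = 0,
                      A_m = 1, L = 1, p)
  expect_equal(up0$U_x, 0, tolerance = 1e-12)
  expect_equal(up0$U_p, 0, tolerance = 1e-12)
  up <- water_uptake(0.2, 0, P_x = 0.3, pi_x = 0, P_p = 0, pi_p = 0,
                     A_m = 10, L = 1, p)
  expect_equal(up$U_x, 1.0, tolerance = 1e-12)
  # raising pi_f raises both uptakes when sigma > 0
  up_hi <- water_uptake(0.2, 0.4, 0.3, 0, 0, 0, 10, 1, p)
  expect_gt(up_hi$U_x, up$U_x)
  expect_gt(up_hi$U_p, up$U_p)
  expect_equal(water_mass_rate(0, 0, 0), 0)
  expect_equal(water_mass_rate(3, 2, 1), 4)
})

test_that("a heat-and-dry spike costs less water when the skin seals faster", {
  w <- default_season()
  # splice a 24 h heat/dry spike (hot afternoon, RH 0.24) late in the season
  spike <- w
  sel <- which(w$time >= as.POSIXct("2015-07-15", tz = "UTC") &
               w$time < as.POSIXct("2015-07-16", tz = "UTC"))
  spike$tair[sel] <- spike$tair[sel] + 12
  spike$rh[sel] <- 0.24
  spike <- weather_series(spike$time, spike$tair, spike$rh,
                          anthesis = anthesis_time(w))
  p_slow <- default_parameters()
  p_fast <- perturb(p_slow, "k_p", 1.0)     # doubled ABA sealing rate
  base <- simulate_fruit(w, p_slow, warn_clamp = FALSE)
  r_slow <- simulate_fruit(spike, p_slow, warn_clamp = FALSE)
  r_fast <- simulate_fruit(spike, p_fast, warn_clamp = FALSE)
  i <- max(sel)
  drop_slow <- base$w[i] - r_slow$w[i]
  base_fast <- simulate_fruit(w, p_fast, warn_clamp = FALSE)
  drop_fast <- base_fast$w[i] - r_fast$w[i]
  expect_gt(drop_slow, 0)                   # the spike costs water
  expect_lt(drop_fast, drop_slow)           # sealing mitigates the loss
})
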