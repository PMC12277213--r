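# Integration of the coupled state and the scenario machinery.

test_that("initial state carries zero thermal time and the baseline ABA", {
  p <- default_parameters()
  st <- initialize_state(10, 40, p)
  expect_equal(st$fresh, 50)
  expect_equal(st$cGDH, 0)
  expect_equal(st$ABA_conc, p$ABA_0)
  expect_equal(st$ABA_norm, 0)
  expect_error(initialize_state(0, 40, p), "> 0")
})

test_that("a single step advances mass by rate times dt", {
  p <- default_parameters()
  st <- initialize_state(10, 40, p)
  rec <- list(tair = 293.15, rh = 0.6)
  drv <- list(psi_stem = -0.5, cp_mM = 50)
  out <- step_fruit(st, rec, drv, p, dt = 1)
  expect_equal(out$state$t, 1)
  expect_equal(out$state$s, st$s + out$diagnostics$ds_dt)
  expect_equal(out$state$w, st$w + out$diagnostics$dw_dt)
  expect_equal(out$state$cGDH, gdh_increment(293.15, p$T_b, p$T_o))
  expect_equal(out$state$fresh, out$state$s + out$state$w)
})

test_that("two half-steps approach one full step at second order", {
  p <- default_parameters()
  rec <- list(tair = 295.15, rh = 0.55)
  drv <- list(psi_stem = -0.4, cp_mM = 60)
  err <- vapply(c(1, 0.5, 0.25), function(dt) {
    st <- initialize_state(50, 400, p)
    st$t <- 500; st$cGDH <- 8000          # mid-season, smooth regime
    n <- round(1 / dt)
    for (k in seq_len(n)) st <- step_fruit(st, rec, drv, p, dt = dt)$state
    st$w
  }, numeric(1))
  # Richardson: halving dt halves the difference to the finer solution
  d1 <- abs(err[1] - err[3])
  d2 <- abs(err[2] - err[3])
  expect_lt(d2, d1)
})

test_that("simulation conserves mass identities at every row", {
  r <- default_run()
  expect_equal(nrow(r), 80 * 24 + 1)
  expect_identical(r$fresh, r$s + r$w)
  expect_true(all(abs(r$ds_dt + r$R_f - r$U_s) <=
                  1e-12 * pmax(1, abs(r$U_s))))
  expect_true(all(abs(r$dw_dt - (r$U_x + r$U_p - r$T_f)) <=
                  1e-12 * pmax(1, abs(r$dw_dt))))
  expect_false(anyNA(as.data.frame(r)))
})

test_that("recorded diagnostics equal the flux-module composition", {
  # the simulator's vectorised fast path must reproduce what the exported
  # module functions compute step by step at the same state
  r <- default_run()
  p <- attr(r, "params")
  for (i in c(1L, 500L, 1200L, 1900L)) {
    st <- list(t = r$t[i], s = r$s[i], w = r$w[i], cGDH = r$cGDH[i])
    out <- step_fruit(st, list(tair = r$tair[i], rh = r$rh[i]),
                      list(psi_stem = r$psi_stem[i], cp_mM = r$cp_mM[i]), p)
    for (nm in c("P_f", "pi_f", "U_x", "U_p", "T_f", "U_a", "U_mf",
                 "U_diff", "U_s", "R_f", "ds_dt", "dw_dt")) {
      expect_equal(out$diagnostics[[nm]], r[[nm]][i], tolerance = 1e-12,
                   label = sprintf("%s at row %d", nm, i))
    }
  }
})

test_that("a zero-duration run returns the single initial row", {
  w <- const_weather(n = 3)
  r <- simulate_fruit(w, duration_days = 0)
  expect_equal(nrow(r), 1L)
  expect_equal(r$s, default_parameters()$s_0)
})

test_that("runs are deterministic and a zero offset is the identity", {
  w <- default_season()
  a <- simulate_fruit(w, warn_clamp = FALSE)
  b <- simulate_fruit(w, warn_clamp = FALSE)
  expect_identical(as.data.frame(a), as.data.frame(b))
  z <- scenario_temperature_offset(w, 0, warn_clamp = FALSE)
  expect_identical(z$fresh, a$fresh)
})

test_that("simulation fails loudly on missing weather coverage", {
  w <- const_weather(n = 48)
  expect_error(simulate_fruit(w, duration_days = 10), "coverage")
  w2 <- weather_series(w$time, w$tair, w$rh,
                       anthesis = w$time[1] + 1800)   # between records
  expect_error(simulate_fruit(w2, duration_days = 1), "no record at anthesis")
})

test_that("dry mass on the packaged season peaks before the end then declines", {
  r <- default_run()
  i_peak <- which.max(r$s)
  expect_lt(i_peak, nrow(r))
  expect_gt(r$t[i_peak], 24 * 30)          # peak well inside the season
  expect_lt(r$s[nrow(r)], r$s[i_peak])     # post-peak decline
})

test_that("substepping changes the trajectory only slightly", {
  w <- default_season()
  r1 <- simulate_fruit(w, substeps = 1L, warn_clamp = FALSE)
  r2 <- simulate_fruit(w, substeps = 2L, warn_clamp = FALSE)
  expect_equal(nrow(r2), nrow(r1))
  rel <- abs(r2$fresh[nrow(r2)] - r1$fresh[nrow(r1)]) / r1$fresh[nrow(r1)]
  expect_lt(rel, 0.01)
})

test_that("anthesis shifts are translation-invariant under aseasonal weather", {
  t0 <- as.POSIXct("2015-05-01", tz = "UTC")
  n <- 40 * 24
  hours <- as.numeric(format(t0 + 3600 * (0:n), "%H"))
  tair <- 290 + 4 * sin(2 * pi * (hours - 8) / 24)   # pure diurnal cycle
  w <- weather_series(t0 + 3600 * (0:n), tair, rep(0.6, n + 1))
  res <- scenario_anthesis_shift(w, c("2015-05-02", "2015-05-05"),
                                 duration_days = 20, warn_clamp = FALSE)
  expect_equal(res$summary$fresh[1], res$summary$fresh[2], tolerance = 1e-9)
  expect_error(
    scenario_anthesis_shift(w, "2015-07-01", duration_days = 20),
    "coverage|anthesis")
})

test_that("harvest summary equals a brute-force aggregate of the rows", {
  r <- default_run()
  win <- c("2015-06-20 00:00:00", "2015-07-05 23:00:00")
  hs <- harvest_summary(r, win)
  sel <- r$time >= as.POSIXct(win[1], tz = "UTC") &
         r$time <= as.POSIXct(win[2], tz = "UTC")
  expect_equal(hs$mean[hs$variable == "fresh"], mean(r$fresh[sel]))
  expect_equal(hs$min[hs$variable == "dry"], min(r$s[sel]))
  expect_equal(hs$max[hs$variable == "water"], max(r$w[sel]))
  one <- harvest_summary(r, c(r$time[100], r$time[100]))
  expect_equal(one$mean, one$min)
  expect_equal(one$mean, one$max)
  expect_error(harvest_summary(r, c("2030-01-01", "2030-01-02")),
               "overlap")
})
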