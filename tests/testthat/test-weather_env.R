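# Weather ingestion, synthesis and environmental drivers.

test_that("weather CSV reading normalises units and validates ranges", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,tair_C,rh_pct",
               "2015-05-10T00:00:00,20,50",
               "2015-05-10T01:00:00,21,55",
               "2015-05-10T02:00:00,22,60"), f)
  w <- read_weather_csv(f)
  expect_equal(w$tair, c(293.15, 294.15, 295.15))
  expect_equal(w$rh, c(0.50, 0.55, 0.60))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,tair_C,rh_pct",
               "2015-05-10T00:00:00,20,50",
               "2015-05-10T01:00:00,21,105"), bad)
  expect_error(read_weather_csv(bad), "row 2")

  gap <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,tair_C,rh_pct",
               "2015-05-10T00:00:00,20,50",
               "2015-05-10T03:00:00,21,55"), gap)
  expect_error(read_weather_csv(gap), "1 h")

  nocol <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,temperature,rh_pct",
               "2015-05-10T00:00:00,20,50"), nocol)
  expect_error(read_weather_csv(nocol), "dialect")
  w2 <- read_weather_csv(nocol, dialect = list(tair = "temperature",
                                               tair_unit = "C"))
  expect_equal(w2$tair, 293.15)
})

test_that("weather CSV writer round-trips to 6 decimals", {
  w <- generate_synthetic_weather("2015-05-10", "2015-05-12",
                                  random_seed = 7L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w, f)
  w2 <- read_weather_csv(f)
  expect_equal(w2$tair, w$tair, tolerance = 1e-6)
  expect_equal(w2$rh, w$rh, tolerance = 1e-6)
  expect_equal(w2$time, w$time)
  # normalisation is idempotent: a second round trip is exact
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_weather_csv(w2, f2)
  w3 <- read_weather_csv(f2)
  expect_identical(w3$tair, w2$tair)
  expect_identical(w3$rh, w2$rh)
})

test_that("single-hour gaps interpolate only behind the explicit flag", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,tair_K,rh_frac",
               "2015-05-10T00:00:00,290,0.5",
               "2015-05-10T02:00:00,292,0.6"), f)
  expect_error(read_weather_csv(f), "1 h")
  w <- read_weather_csv(f, interpolate_gaps = TRUE)
  expect_equal(nrow(w), 3L)
  expect_equal(w$tair[2], 291)
  expect_equal(w$rh[2], 0.55)
})

test_that("synthetic weather is deterministic and degenerates to a constant", {
  flat <- generate_synthetic_weather("2015-05-10", "2015-05-12",
    T_mean_day = 291, T_amplitude_diurnal = 0, T_amplitude_seasonal = 0,
    RH_mean = 0.7, RH_amplitude = 0, noise_sd_T = 0, noise_sd_RH = 0)
  expect_true(all(flat$tair == 291))
  expect_true(all(flat$rh == 0.7))

  a <- generate_synthetic_weather("2015-05-10", "2015-06-10", random_seed = 99L)
  b <- generate_synthetic_weather("2015-05-10", "2015-06-10", random_seed = 99L)
  expect_identical(a$tair, b$tair)
  expect_identical(a$rh, b$rh)
  expect_true(all(a$rh >= 0.02 & a$rh <= 1))
})

test_that("noise-free diurnal wave spans exactly twice its amplitude", {
  w <- generate_synthetic_weather("2015-06-01", "2015-06-05",
    T_mean_day = 291, T_amplitude_diurnal = 6, T_amplitude_seasonal = 0,
    noise_sd_T = 0, noise_sd_RH = 0)
  day <- format(w$time, "%d")
  for (d in unique(day)[2:4]) {
    rng <- range(w$tair[day == d])
    expect_equal(diff(rng), 12, tolerance = 1e-6)
  }
  # documented phase: minimum at 05:00, maximum at 14:00
  hours <- as.numeric(format(w$time, "%H"))
  one_day <- w$tair[day == unique(day)[2]]
  h_one <- hours[day == unique(day)[2]]
  expect_equal(h_one[which.min(one_day)], 5)
  expect_equal(h_one[which.max(one_day)], 14)
})

test_that("stem water potential attains its bounds at the documented phases", {
  expect_equal(stem_water_potential(3), -0.10)   # pre-dawn maximum
  expect_equal(stem_water_potential(15), -1.8)   # mid-afternoon minimum
  expect_equal(stem_water_potential(8, c(-1, -1)), -1)
  expect_error(stem_water_potential(8, c(-1, 0.5)), "<= 0")
  h <- seq(0, 24, by = 0.01)
  psi <- stem_water_potential(h)
  expect_true(all(psi >= -1.8 - 1e-12 & psi <= -0.10 + 1e-12))
})

test_that("phloem sucrose stays within bounds on a dense scan", {
  t <- seq(0, 4000, by = 0.5)
  cp <- phloem_sucrose(t)
  expect_true(all(is.finite(cp)))
  expect_true(all(cp >= 15 - 1e-12 & cp <= 100 + 1e-12))
  expect_equal(phloem_sucrose(0), 15)
  expect_equal(phloem_sucrose(80 * 24), 100)
  expect_true(all(phloem_sucrose(t, c(50, 50)) == 50))
})

test_that("saturated vapour density matches the Magnus/ideal-gas oracle", {
  # independent recomputation: Magnus pressure + ideal gas at 20 and 0 degC
  oracle <- function(Tc) {
    p <- 610.94 * exp(17.625 * Tc / (Tc + 243.04))
    0.018015 * p / (8.314 * (Tc + 273.15)) * 1e-3
  }
  expect_equal(vapor_concentration(293.15), oracle(20), tolerance = 1e-12)
  expect_equal(vapor_concentration(293.15), 1.73e-5, tolerance = 0.01)
  expect_equal(vapor_concentration(273.15), 4.85e-6, tolerance = 0.01)
  grid <- seq(250, 330, by = 0.1)
  expect_true(all(diff(vapor_concentration(grid)) > 0))
  expect_error(vapor_concentration(200), "250")
})

test_that("environment drivers align with the weather series", {
  w <- const_weather(n = 49)
  drv <- environment_drivers(w)
  expect_equal(nrow(drv), 49L)
  expect_true(all(drv$psi_stem >= -1.8 & drv$psi_stem <= -0.10))
  expect_true(all(drv$cp_mM >= 15 & drv$cp_mM <= 100))
})
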