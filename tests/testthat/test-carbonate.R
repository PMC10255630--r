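test_that("equilibrium constants are ordered and smooth over the freshwater range", {
  temps <- seq(0, 30, by = 1)
  k <- carbonate_constants(temps)
  expect_true(all(k$K1 > k$K2))
  expect_true(all(k$K2 > 0))
  # monotone in temperature over this range
  expect_true(all(diff(k$K1) > 0))
  expect_true(all(diff(k$Kw) > 0))
  expect_error(carbonate_constants(45), "temperature")
})

test_that("closed-form speciation agrees with the DIC root-finder oracle to 1e-9", {
  grid <- expand.grid(temperature = c(0, 5, 15, 25),
                      pH = seq(6.5, 9.5, by = 0.1),
                      alkalinity = c(0.3, 0.5, 1.2, 1.5) * 1e-3)
  st <- co2_from_ph_alk(grid$temperature, grid$pH, grid$alkalinity)
  ref <- mapply(oracle_co2, grid$temperature, grid$pH, grid$alkalinity)
  expect_lt(max(abs(st$co2_aq - ref) / ref), 1e-9)
  # alkalinity identity holds at the returned speciation
  k <- carbonate_constants(grid$temperature)
  H <- 10^(-grid$pH)
  alk_back <- st$hco3 + 2 * st$co3 + k$Kw / H - H
  expect_lt(max(abs(alk_back - grid$alkalinity)), 1e-12)
  expect_true(all(st$co2_aq >= 0 & st$hco3 >= 0 & st$co3 >= 0))
})

test_that("CO2 is monotone: decreasing in pH, increasing in alkalinity", {
  for (T in c(0, 5, 15, 25)) {
    for (alk in c(0.3, 0.5, 1.2, 1.5) * 1e-3) {
      co2 <- co2_from_ph_alk(T, seq(6.5, 9.5, by = 0.1), alk)$co2_aq
      expect_true(all(diff(co2) < 0))
    }
    for (pH in c(6.5, 7.5, 8.5, 9.5)) {
      co2 <- co2_from_ph_alk(T, pH, c(0.3, 0.5, 1.2, 1.5) * 1e-3)$co2_aq
      expect_true(all(diff(co2) > 0))
    }
  }
})

test_that("pH <-> CO2 round trip is the identity to 1e-6", {
  grid <- expand.grid(temperature = c(0, 15, 25),
                      pH = seq(6.5, 9.5, by = 0.25),
                      alkalinity = c(0.3, 1.2) * 1e-3)
  co2 <- co2_from_ph_alk(grid$temperature, grid$pH, grid$alkalinity)$co2_aq
  back <- ph_from_alk_co2(grid$temperature, grid$alkalinity, co2)
  expect_lt(max(abs(back - grid$pH)), 1e-6)
  # worked case: CO2 at (25 degC, pH 8.3, alk 1.2 mM) inverts to pH 8.3
  c0 <- co2_from_ph_alk(25, 8.3, 1.2e-3)$co2_aq
  expect_equal(c0, oracle_co2(25, 8.3, 1.2e-3), tolerance = 1e-9)
  expect_equal(ph_from_alk_co2(25, 1.2e-3, c0), 8.3, tolerance = 1e-6)
  # more CO2 at fixed alkalinity means lower pH
  expect_lt(ph_from_alk_co2(25, 1.2e-3, 2 * c0), 8.3)
})

test_that("infeasible chemistry is an explicit error", {
  # pH 11 with microscopic alkalinity: hydroxide alone exceeds the alkalinity
  expect_error(co2_from_ph_alk(25, 11, 1e-6), "infeasible")
  expect_error(ph_from_alk_co2(25, -1e-3, 1e-5), "positive")
  expect_error(co2_from_ph_alk(25, 13, 1e-3), "pH")
})

test_that("pairing rule keeps only alkalinity/conductivity pairs within the gap", {
  t0 <- as.POSIXct("2016-06-06 10:00:00", tz = "UTC")
  alk <- data.frame(timestamp = t0 + c(0, 7, 14) * 86400, value = c(0.9, 1.0, 1.1))
  cond <- data.frame(timestamp = t0 + c(1, 7 * 24 + 5, 14 * 24 + 7) * 3600,
                     value = c(26, 28, 30))
  fit <- fit_alkalinity_conductivity(alk, cond, max_gap_hours = 6)
  expect_equal(fit$n_pairs, 2)
  expect_error(fit_alkalinity_conductivity(alk, cond, max_gap_hours = 0.5),
               ">= 2")
})

test_that("nearest-in-time pairing breaks ties toward the earlier observation", {
  t0 <- as.POSIXct("2016-06-06 12:00:00", tz = "UTC")
  alk <- data.frame(timestamp = t0 + c(0, 7 * 86400), value = c(0.9, 1.1))
  cond <- data.frame(timestamp = c(t0 - 3600, t0 + 3600,
                                   t0 + 7 * 86400 - 1800, t0 + 7 * 86400 + 1800),
                     value = c(10, 20, 30, 40))
  fit <- fit_alkalinity_conductivity(alk, cond, max_gap_hours = 6)
  expect_equal(fit$pairs$conductivity, c(10, 30))
})

test_that("collinear pairs recover the exact slope; noisy fit matches the OLS oracle", {
  t0 <- as.POSIXct("2016-01-04 10:00:00", tz = "UTC")
  cond_v <- seq(22, 32, length.out = 20)
  alk_v <- 0.05 * cond_v - 0.4
  ts <- t0 + (0:19) * 7 * 86400
  fit <- fit_alkalinity_conductivity(
    data.frame(timestamp = ts, value = alk_v),
    data.frame(timestamp = ts + 60, value = cond_v))
  expect_equal(fit$slope, 0.05, tolerance = 1e-12)
  expect_equal(fit$intercept, -0.4, tolerance = 1e-10)

  set.seed(91)
  n <- 100
  cond_v <- runif(n, 22, 32)
  alk_v <- 0.05 * cond_v - 0.4 + rnorm(n, 0, 0.02)
  ts <- t0 + (seq_len(n) - 1) * 7 * 86400
  fit <- fit_alkalinity_conductivity(
    data.frame(timestamp = ts, value = alk_v),
    data.frame(timestamp = ts, value = cond_v))
  # normal-equations oracle with closed-form standard error
  Xm <- cbind(1, cond_v)
  beta <- solve(t(Xm) %*% Xm, t(Xm) %*% alk_v)
  resid <- alk_v - Xm %*% beta
  s2 <- sum(resid^2) / (n - 2)
  se <- sqrt(s2 * solve(t(Xm) %*% Xm)[2, 2])
  expect_equal(fit$slope, beta[2], tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(abs(fit$slope - 0.05), 4 * se)
})

test_that("co2_series maps constant sensors to constant CO2 and flags infeasible points", {
  t0 <- as.POSIXct("2016-06-06 00:00:00", tz = "UTC")
  ts <- t0 + (0:49) * 3600
  ser <- make_series(rep(ts, 3),
                     rep(c("pH", "temperature", "conductivity"), each = 50),
                     c(rep(8.2, 50), rep(10, 50), rep(27, 50)))
  fit <- structure(list(slope = 0.05, intercept = -0.4, residual_sd = 0,
                        n_pairs = 10, max_pairing_gap = 6), class = "alk_cond_fit")
  out <- co2_series(ser, fit)
  expect_equal(nrow(out), 50)
  expect_lt(diff(range(out$value)), 1e-15)
  expect_equal(out$value[1],
               co2_from_ph_alk(10, 8.2, (0.05 * 27 - 0.4) * 1e-3)$co2_aq)

  # k infeasible points (conductivity implying negative alkalinity) are
  # excluded and reported, not silently dropped
  ser$value[ser$factor == "conductivity"][1:5] <- 1
  out2 <- co2_series(ser, fit)
  expect_equal(nrow(out2), 45)
  expect_equal(nrow(attr(out2, "infeasible")), 5)
  expect_error(co2_series(ser[ser$factor != "pH", ], fit), "pH")
})

test_that("planted CO2 is recovered through the fitted regression when the conductivity link is exact", {
  cfg <- scenario_config(start_year = 2016, end_year = 2017, seed = 5,
                         alk_cond_params = c(20, 8, 0))
  ser <- generate_scenario(cfg, sensors = FALSE)
  sub <- function(f) {
    d <- ser[ser$factor == f, c("timestamp", "value")]
    rownames(d) <- NULL
    d
  }
  fit <- fit_alkalinity_conductivity(sub("alkalinity"), sub("conductivity"))
  out <- co2_series(ser, fit)
  planted <- sub("co2")
  m <- merge(out[c("timestamp", "value")], planted, by = "timestamp")
  expect_equal(nrow(m), nrow(planted))
  expect_lt(max(abs(m$value.x - m$value.y) / m$value.y), 1e-6)
})
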