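#' Scenario configuration for the synthetic lake generator
#'
#' Encodes the study conditions the generator emulates: multi-year series
#' with weekly lab sampling and sub-daily sensors, seasonal water
#' temperature, summer algal blooms gated on lagged temperature, a linear
#' alkalinity-conductivity coupling, and pH produced from carbonate
#' equilibrium under photosynthetic CO2 drawdown. Defaults mirror the
#' observed sensor bands of the source-water intake the package models:
#' pH 7.2-9.3, temperature 0-12.5 degC, conductivity 20-35 mS/m, turbidity
#' 0-30 FTU, 5-minute sensor acquisition.
#'
#' @param start_year,end_year calendar years covered (inclusive).
#' @param weekly_points_per_year lab sampling points per year (default 52).
#' @param sensor_interval sensor acquisition interval in minutes (default 5).
#' @param temp_params `c(mean, amplitude, noise_sd)` of water temperature in
#'   degC: seasonal sinusoid plus AR(1) noise.
#' @param temp_trend slow warming trend in degC per year (default 0.1,
#'   about a degree per decade). Because bloom amplitude is gated on lagged
#'   temperature, the trend shifts the algae regime between early and late
#'   years - the "changing background conditions" a date-only model cannot
#'   track across a training/application gap.
#' @param bloom_params `c(blooms_per_year, peak_cells, width_weeks,
#'   temp_threshold)`: Gaussian bloom pulses in log10-cell space, amplitude
#'   gated on whether temperature `bloom_lag_weeks` earlier exceeded the
#'   threshold (degC).
#' @param baseline_cells off-bloom algae level, cells/L.
#' @param bloom_lag_weeks temperature lag driving the bloom gate (weeks).
#' @param algae_noise_sd multiplicative lognormal noise, sd in log10 units.
#' @param alk_params `c(mean, sd, ar)` of the slow AR(1) alkalinity process, mM.
#' @param alk_cond_params `c(slope, intercept, noise_sd)`:
#'   conductivity = slope * alkalinity + intercept + noise (mS/m per mM, mS/m).
#' @param co2_baseline baseline dissolved CO2, mol/L.
#' @param co2_drawdown CO2 removed per unit normalized algae (mol/L).
#' @param co2_noise_sd additive CO2 noise sd, mol/L.
#' @param co2_floor lower bound kept strictly above zero, mol/L.
#' @param decoy_factors number of extra irrelevant AR(1) channels
#'   (`decoy1`, `decoy2`, ...) beyond the optical channels.
#' @param couple_optics if `TRUE`, turbidity and the UV254 DOM proxy are
#'   weakly coupled to algae; by default they are independent noise, standing
#'   in as decoys the subset scanner must reject.
#' @param ph_band,cond_band,turb_band plausibility bands used by generation
#'   checks.
#' @param sensor_noise_sd named additive noise for sensor channels.
#' @param seed integer seed; the generator is a pure function of
#'   (config, seed).
#' @return an object of class `scenario_config` (a named list).
#' @export
scenario_config <- function(start_year = 2015, end_year = 2022,
                            weekly_points_per_year = 52,
                            sensor_interval = 5,
                            temp_params = c(mean = 6.0, amplitude = 5.5, noise_sd = 1.0),
                            temp_trend = 0.1,
                            bloom_params = c(blooms_per_year = 1, peak_cells = 4e6,
                                             width_weeks = 3, temp_threshold = 10.2),
                            baseline_cells = 1e5,
                            bloom_lag_weeks = 3,
                            algae_noise_sd = 0.12,
                            alk_params = c(mean = 0.95, sd = 0.02, ar = 0.9),
                            alk_cond_params = c(slope = 20, intercept = 8, noise_sd = 0.35),
                            co2_baseline = 2.8e-5,
                            co2_drawdown = 1.4e-5,
                            co2_noise_sd = 4e-7,
                            co2_floor = 2e-6,
                            decoy_factors = 0,
                            couple_optics = FALSE,
                            ph_band = c(7.2, 9.3),
                            cond_band = c(20, 35),
                            turb_band = c(0, 30),
                            sensor_noise_sd = c(temperature = 0.05, pH = 0.02,
                                                conductivity = 0.15, turbidity = 0.3,
                                                dom_uv254 = 0.15),
                            seed = 1L) {
  if (end_year < start_year) stop("end_year must be >= start_year", call. = FALSE)
  sds <- c(temp_params[3], alk_params[2], alk_cond_params[3], algae_noise_sd,
           co2_noise_sd, sensor_noise_sd)
  if (any(sds < 0)) stop("all noise sds must be >= 0", call. = FALSE)
  cfg <- list(start_year = start_year, end_year = end_year,
              weekly_points_per_year = weekly_points_per_year,
              sensor_interval = sensor_interval,
              temp_params = unname(temp_params),
              temp_trend = temp_trend,
              bloom_params = unname(bloom_params),
              baseline_cells = baseline_cells,
              bloom_lag_weeks = bloom_lag_weeks,
              algae_noise_sd = algae_noise_sd,
              alk_params = unname(alk_params),
              alk_cond_params = unname(alk_cond_params),
              co2_baseline = co2_baseline, co2_drawdown = co2_drawdown,
              co2_noise_sd = co2_noise_sd, co2_floor = co2_floor,
              decoy_factors = decoy_factors, couple_optics = couple_optics,
              ph_band = ph_band, cond_band = cond_band, turb_band = turb_band,
              sensor_noise_sd = sensor_noise_sd,
              seed = as.integer(seed))
  class(cfg) <- "scenario_config"
  cfg
}

ar1 <- function(n, mean, sd, phi) {
  if (sd == 0) return(rep(mean, n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in 2:n) x[i] <- phi * x[i - 1] + innov[i]
  mean + x
}

# Deterministic weekly skeleton: seasonal curves and bloom pulse shape.
# Week-of-year runs 1..weekly_points_per_year on a fixed 7-day grid anchored
# at the first Monday of start_year.
scenario_skeleton <- function(cfg) {
  n_years <- cfg$end_year - cfg$start_year + 1
  wpy <- cfg$weekly_points_per_year
  n <- n_years * wpy
  anchor <- first_monday(cfg$start_year)
  week_start <- anchor + 7 * (seq_len(n) - 1)
  woy <- ((seq_len(n) - 1) %% wpy) + 1
  doy <- as.numeric(week_start - as.Date(sprintf("%d-01-01",
                                                 as.integer(format(week_start, "%Y")))))
  years_in <- as.numeric(week_start - anchor) / 365.25
  temp_det <- cfg$temp_params[1] + cfg$temp_trend * years_in +
    cfg$temp_params[2] * cos(2 * pi * (doy - 225) / 365.25)
  nb <- cfg$bloom_params[1]
  centers <- if (nb <= 1) 31 else seq(24, 38, length.out = nb)
  sigma <- cfg$bloom_params[3]
  pulse <- rowSums(outer(woy, centers, function(w, c0) exp(-(w - c0)^2 / (2 * sigma^2))))
  list(n = n, week_start = week_start, woy = woy, temp_det = temp_det, pulse = pulse)
}

#' Generate a synthetic multi-year lake observation series
#'
#' Produces a long-format observation table with a planted dependency
#' structure: algae blooms depend on the date and on 3-week-lagged
#' temperature, photosynthetic CO2 drawdown follows algae, and pH is solved
#' from carbonate equilibrium given (alkalinity, CO2, temperature) - so
#' \{temperature, pH\} and \{temperature, CO2\} are the recoverable closed
#' systems, while turbidity, the DOM proxy and any extra decoy channels are
#' independent noise (unless `couple_optics`). Conductivity tracks the slow
#' alkalinity process, not algae.
#'
#' Weekly lab factors (algae, alkalinity) are point samples on a fixed
#' weekday (Monday 10:00 UTC); sensor factors are generated on the
#' `sensor_interval` grid by interpolating the weekly process and adding
#' high-frequency noise.
#'
#' @param config a [scenario_config()].
#' @param sensors if `FALSE`, only weekly-cadence channels are generated
#'   (the weekly modelling grid is all the scanning pipeline needs); if
#'   `TRUE`, sub-daily sensor channels are included.
#' @param noise_free if `TRUE`, all noise sds are forced to zero (reference
#'   run used by tests and drift checks).
#' @return an object of class `observation_series`: data frame with columns
#'   `timestamp` (POSIXct UTC), `factor`, `value`, `unit`, `cadence`, with
#'   the generating config in attribute `config`.
#' @export
generate_scenario <- function(config, sensors = TRUE, noise_free = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  if (noise_free) {
    cfg$temp_params[3] <- 0; cfg$alk_params[2] <- 0
    cfg$alk_cond_params[3] <- 0; cfg$algae_noise_sd <- 0
    cfg$co2_noise_sd <- 0; cfg$sensor_noise_sd[] <- 0
  }
  set.seed(cfg$seed)
  sk <- scenario_skeleton(cfg)
  n <- sk$n

  # slow temperature anomalies (warm/cold spells persisting for weeks) on top
  # of the seasonal cycle; these, not the calendar, modulate bloom amplitude
  temp <- pmax(sk$temp_det + ar1(n, 0, cfg$temp_params[3], 0.85), 0.05)
  lag <- cfg$bloom_lag_weeks
  temp_lagged <- c(rep(temp[1], lag), temp[seq_len(n - lag)])
  # smooth gate: bloom amplitude rises with how far lagged temperature
  # exceeds the threshold (logistic, 0.8 degC scale), floored at 0.25
  gate <- 0.25 + 0.75 * stats::plogis((temp_lagged - cfg$bloom_params[4]) / 0.8)
  log_base <- log10(cfg$baseline_cells)
  log_amp <- log10(cfg$bloom_params[2]) - log_base
  log_algae <- log_base + log_amp * gate * sk$pulse +
    stats::rnorm(n, 0, cfg$algae_noise_sd)
  algae <- 10^log_algae

  alk <- ar1(n, cfg$alk_params[1], cfg$alk_params[2], cfg$alk_params[3]) # mM
  cond <- cfg$alk_cond_params[1] * alk + cfg$alk_cond_params[2] +
    stats::rnorm(n, 0, cfg$alk_cond_params[3])

  a_norm <- pmin(1, pmax(0, (log_algae - log_base) / log_amp))
  co2 <- cfg$co2_baseline - cfg$co2_drawdown * a_norm +
    stats::rnorm(n, 0, cfg$co2_noise_sd)
  co2 <- pmax(co2, cfg$co2_floor)
  ph <- tryCatch(ph_from_alk_co2(temp, alk * 1e-3, co2),
                 error = function(e) {
                   stop(sprintf("infeasible chemistry while generating pH: %s",
                                conditionMessage(e)), call. = FALSE)
                 })

  # weakly autocorrelated noise channels: no causal link to algae, and little
  # self-predictability for the scanner to reward
  turb <- pmax(0, ar1(n, 3, 1.2, 0.35))
  dom <- pmax(0, ar1(n, 8, 1.0, 0.35))
  if (cfg$couple_optics) {
    turb <- turb + 2.5 * a_norm
    dom <- dom + 1.5 * a_norm
  }
  decoys <- if (cfg$decoy_factors > 0)
    lapply(seq_len(cfg$decoy_factors), function(i) ar1(n, 0, 1, 0.35)) else list()

  week_ts <- as.POSIXct(paste(sk$week_start, "10:00:00"), tz = "UTC")
  units <- c(algae = "cells/L", alkalinity = "mM", temperature = "degC",
             pH = "pH", conductivity = "mS/m", turbidity = "FTU",
             dom_uv254 = "1/m", co2 = "mol/L")
  weekly_vals <- list(algae = algae, alkalinity = alk, temperature = temp,
                      pH = ph, conductivity = cond, turbidity = turb,
                      dom_uv254 = dom, co2 = co2)
  for (i in seq_along(decoys)) {
    nm <- sprintf("decoy%d", i)
    weekly_vals[[nm]] <- decoys[[i]]
    units[nm] <- "au"
  }

  lab_factors <- c("algae", "alkalinity")
  sensor_factors <- setdiff(names(weekly_vals), lab_factors)

  rows <- list()
  for (f in names(weekly_vals)) {
    cad <- if (f %in% lab_factors || !sensors) "weekly" else "weekly"
    rows[[f]] <- data.frame(timestamp = week_ts, factor = f,
                            value = weekly_vals[[f]], unit = unname(units[f]),
                            cadence = if (f %in% lab_factors) "weekly" else
                              if (sensors) "sensor_weekly_anchor" else "weekly",
                            stringsAsFactors = FALSE)
  }

  if (sensors) {
    ts_grid <- seq(week_ts[1], week_ts[n], by = cfg$sensor_interval * 60)
    tnum <- as.numeric(ts_grid); wnum <- as.numeric(week_ts)
    for (f in sensor_factors) {
      base <- stats::approx(wnum, weekly_vals[[f]], xout = tnum, rule = 2)$y
      nsd <- if (noise_free) 0 else unname(cfg$sensor_noise_sd[f])
      if (is.na(nsd)) nsd <- 0
      vals <- base + stats::rnorm(length(base), 0, nsd)
      if (f == "turbidity") vals <- pmax(vals, 0)
      if (f == "co2") vals <- pmax(vals, cfg$co2_floor)
      rows[[f]] <- data.frame(timestamp = ts_grid, factor = f, value = vals,
                              unit = unname(units[f]), cadence = "sensor",
                              stringsAsFactors = FALSE)
    }
  }

  out <- do.call(rbind, rows)
  out <- out[order(out$factor, out$timestamp), ]
  rownames(out) <- NULL
  class(out) <- c("observation_series", "data.frame")
  attr(out, "config") <- cfg
  out
}

#' @export
print.observation_series <- function(x, ...) {
  facs <- table(x$factor)
  cat(sprintf("observation_series: %d rows, %d factors, %s .. %s\n",
              nrow(x), length(facs),
              format(min(x$timestamp)), format(max(x$timestamp))))
  for (f in names(facs)) {
    cad <- x$cadence[match(f, x$factor)]
    cat(sprintf("  %-12s %6d obs  [%s]\n", f, facs[[f]], cad))
  }
  invisible(x)
}

#' Remove a span of years and optionally add post-gap drift
#'
#' Emulates the temporal gap between model training and real-world
#' application: all observations whose calendar year falls in `gap_years`
#' are removed, and a slow additive drift can be applied to observations
#' after the gap to mimic changing background conditions.
#'
#' @param series an `observation_series`.
#' @param gap_years integer vector of calendar years to remove (may be
#'   empty, in which case the series is returned unchanged).
#' @param drift named numeric vector: additive shift per factor applied to
#'   all observations after the gap (e.g. `c(pH = 0.1)`).
#' @return the filtered (and possibly drifted) `observation_series`.
#' @export
inject_gap <- function(series, gap_years, drift = NULL) {
  stopifnot(inherits(series, "observation_series"))
  if (length(gap_years) == 0) return(series)
  yr <- as.integer(format(series$timestamp, "%Y"))
  span <- range(yr)
  if (any(gap_years < span[1] | gap_years > span[2]))
    stop("gap must lie inside the series span", call. = FALSE)
  keep <- !(yr %in% gap_years)
  if (!any(keep)) stop("gap would remove the whole series", call. = FALSE)
  out <- series[keep, ]
  if (!is.null(drift)) {
    post <- as.integer(format(out$timestamp, "%Y")) > max(gap_years)
    for (f in names(drift)) {
      sel <- post & out$factor == f
      out$value[sel] <- out$value[sel] + drift[[f]]
    }
  }
  rownames(out) <- NULL
  cfg <- attr(series, "config")
  class(out) <- c("observation_series", "data.frame")
  attr(out, "config") <- cfg
  out
}
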