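# Shared fixtures: all built in code at test time.

# brute-force speciation oracle: root-find total DIC so that the
# charge-balance alkalinity matches, then take the CO2 fraction.
# Independent of the closed-form path in the package.
oracle_co2 <- function(temperature, pH, alkalinity) {
  k <- carbonate_constants(temperature)
  H <- 10^(-pH)
  f <- function(DIC) {
    a_denom <- 1 + k$K1 / H + k$K1 * k$K2 / H^2
    a1 <- (k$K1 / H) / a_denom
    a2 <- (k$K1 * k$K2 / H^2) / a_denom
    DIC * (a1 + 2 * a2) + k$Kw / H - H - alkalinity
  }
  DIC <- stats::uniroot(f, c(1e-12, 1), tol = 1e-16)$root
  a0 <- 1 / (1 + k$K1 / H + k$K1 * k$K2 / H^2)
  a0 * DIC
}

# long-format series builder for hand-made fixtures
make_series <- function(timestamp, factor, value, cadence = "sensor",
                        unit = "au") {
  df <- data.frame(timestamp = timestamp, factor = factor, value = value,
                   unit = unit, cadence = cadence, stringsAsFactors = FALSE)
  df <- df[order(df$factor, df$timestamp), ]
  class(df) <- c("observation_series", "data.frame")
  df
}

# a small weekly table of n consecutive weeks with given factor columns
make_weekly <- function(n, factors = list(algae = NULL), start = as.Date("2015-01-05")) {
  wk <- start + 7 * (seq_len(n) - 1)
  out <- data.frame(week_start = wk,
                    year = as.integer(format(wk, "%Y")),
                    month = as.integer(format(wk, "%m")),
                    day = as.integer(format(wk, "%d")))
  for (f in names(factors))
    out[[f]] <- if (is.null(factors[[f]])) seq_len(n) else factors[[f]]
  class(out) <- c("weekly_table", "data.frame")
  attr(out, "units") <- stats::setNames(rep("au", length(factors)), names(factors))
  out
}

# hand-built window_set (bypasses weekly-table plumbing for model unit tests)
make_window_set <- function(X, Y, subset = character(0)) {
  structure(list(X = X, Y = Y,
                 target_week = as.Date("2015-01-05") + 7 * seq_len(nrow(X)),
                 subset = subset, factors = colnames(X), targets = colnames(Y),
                 W = 1, h = 1),
            class = "window_set")
}

# a compact 3-year scenario + scan used by several scanning tests
small_scan <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cfg <- scenario_config(start_year = 2015, end_year = 2017, seed = 33)
    w <- to_weekly(generate_scenario(cfg, sensors = FALSE))
    sp <- split_spec(training = 2015:2016, validation = 2017, application = integer(0))
    g <- scan_grid(candidates = c("temperature", "pH"), neurons = 1:2,
                   replicates = 2, base_seed = 7)
    cache <<- list(weekly = w, split = sp, grid = g,
                   result = run_scan(g, w, sp, control = fnn_control(maxit = 60)))
    cache
  }
})
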