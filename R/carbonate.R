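#' Temperature-dependent carbonate equilibrium constants
#'
#' Dissociation constants of carbonic acid (K1, K2) and the ion product of
#' water (Kw) for dilute freshwater, as functions of temperature. K1 and K2
#' follow the Plummer & Busenberg (1982) expressions; Kw follows Harned &
#' Owen. Activity corrections are deliberately omitted: at the conductivity
#' of the waters modelled here (20-35 mS/m) the ionic strength is low enough
#' that molal and molar scales coincide to well under the other uncertainties
#' of the calculation.
#'
#' @param temperature water temperature in degrees Celsius, vectorised.
#' @return a list with numeric vectors `K1`, `K2`, `Kw` (molar scale).
#' @export
#' @examples
#' k <- carbonate_constants(25)
#' -log10(k$K1) # ~6.35
carbonate_constants <- function(temperature) {
  if (any(!is.finite(temperature)) || any(temperature < -0.5 | temperature > 40))
    stop("temperature must be finite and within [-0.5, 40] degC", call. = FALSE)
  TK <- temperature + 273.15
  log10K1 <- -356.3094 - 0.06091964 * TK + 21834.37 / TK +
    126.8339 * log10(TK) - 1684915 / TK^2
  log10K2 <- -107.8871 - 0.03252849 * TK + 5151.79 / TK +
    38.92561 * log10(TK) - 563713.9 / TK^2
  pKw <- 4470.99 / TK - 6.0875 + 0.01706 * TK
  list(K1 = 10^log10K1, K2 = 10^log10K2, Kw = 10^(-pKw))
}

# Core speciation given H+ activity; shared by the public solvers.
# alkalinity here is charge-balance alkalinity in mol/L:
#   Alk = [HCO3-] + 2[CO3--] + [OH-] - [H+]
speciate <- function(temperature, pH, alkalinity) {
  k <- carbonate_constants(temperature)
  H <- 10^(-pH)
  hco3 <- (alkalinity - k$Kw / H + H) / (1 + 2 * k$K2 / H)
  co3 <- k$K2 * hco3 / H
  co2 <- H * hco3 / k$K1
  data.frame(temperature = temperature, pH = pH, alkalinity = alkalinity,
             co2_aq = co2, hco3 = hco3, co3 = co3)
}

#' Dissolved CO2 from pH, temperature and alkalinity
#'
#' Solves the dilute carbonate system in closed form. With `H = 10^-pH`,
#' bicarbonate follows from the charge-balance alkalinity
#' `Alk = [HCO3-] + 2[CO3--] + [OH-] - [H+]`, carbonate from the second
#' dissociation, and CO2(aq) from the first:
#' `hco3 = (Alk - Kw/H + H) / (1 + 2 K2/H)`, `co3 = K2 hco3 / H`,
#' `co2 = H hco3 / K1`. This is the calculation a geochemical speciation
#' code performs for this system, reduced to the species that matter in
#' calcite-metastable lake water; the organic-acid contribution to
#' alkalinity is not modelled.
#'
#' @param temperature degrees Celsius, in `[-0.5, 40]`.
#' @param pH unitless, in `[4, 12]`.
#' @param alkalinity charge-balance alkalinity in mol/L, positive.
#' @return an object of class `carbonate_state`: a data frame with columns
#'   `temperature`, `pH`, `alkalinity`, `co2_aq`, `hco3`, `co3` (mol/L).
#' @seealso [ph_from_alk_co2()] for the inverse, [co2_series()] to apply
#'   this pointwise to sensor series.
#' @export
#' @examples
#' co2_from_ph_alk(25, 8.3, 1.2e-3)$co2_aq
co2_from_ph_alk <- function(temperature, pH, alkalinity) {
  if (any(pH < 4 | pH > 12)) stop("pH out of supported range [4, 12]", call. = FALSE)
  if (any(alkalinity <= 0)) stop("alkalinity must be positive (mol/L)", call. = FALSE)
  st <- speciate(temperature, pH, alkalinity)
  if (any(st$hco3 < 0))
    stop("chemistry infeasible: alkalinity inconsistent with pH (hco3 < 0)",
         call. = FALSE)
  class(st) <- c("carbonate_state", "data.frame")
  st
}

#' pH from alkalinity and dissolved CO2
#'
#' Inverts [co2_from_ph_alk()] by root-finding on pH in `[4, 12]`. CO2(aq) is
#' strictly decreasing in pH at fixed alkalinity, so the root is unique. The
#' solver is a fully vectorised bisection run to machine-level tolerance,
#' which keeps long planted-CO2 series cheap to invert.
#'
#' @param temperature degrees Celsius.
#' @param alkalinity mol/L, positive.
#' @param co2_aq mol/L, positive.
#' @param tol absolute pH tolerance (default 1e-10).
#' @return numeric vector of pH values.
#' @export
ph_from_alk_co2 <- function(temperature, alkalinity, co2_aq, tol = 1e-10) {
  if (any(alkalinity <= 0)) stop("alkalinity must be positive", call. = FALSE)
  if (any(co2_aq <= 0)) stop("co2_aq must be positive", call. = FALSE)
  n <- max(length(temperature), length(alkalinity), length(co2_aq))
  temperature <- rep_len(temperature, n)
  alkalinity <- rep_len(alkalinity, n)
  co2_aq <- rep_len(co2_aq, n)
  f <- function(pH) speciate(temperature, pH, alkalinity)$co2_aq - co2_aq
  lo <- rep(4, n); hi <- rep(12, n)
  flo <- f(lo); fhi <- f(hi)
  bad <- flo < 0 | fhi > 0
  if (any(bad))
    stop(sprintf("no pH in [4, 12] matches the given (alkalinity, co2_aq) for %d point(s); first index %d",
                 sum(bad), which(bad)[1]), call. = FALSE)
  for (i in seq_len(ceiling(log2(8 / tol)))) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    pos <- fm > 0 # co2 too high -> pH too low -> move lower bound up
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
  }
  (lo + hi) / 2
}

#' Alkalinity-from-conductivity regression with timed pairing
#'
#' In high-alkalinity lake water, conductivity tracks alkalinity closely, so
#' weekly lab alkalinity can be regressed on sensor conductivity and the fit
#' used to predict alkalinity at sensor resolution. Each lab value is paired
#' with the nearest-in-time conductivity observation (ties broken toward the
#' earlier observation) and pairs further apart than `max_gap_hours` are
#' discarded - including more distant sensor readings demonstrably worsens
#' the correlation.
#'
#' @param weekly_alk data frame with columns `timestamp` (POSIXct) and
#'   `value` (alkalinity, mM).
#' @param conductivity data frame with columns `timestamp` and `value`
#'   (mS/m).
#' @param max_gap_hours maximum pairing gap in hours (default 6).
#' @return an object of class `alk_cond_fit`: list with `slope` (mM per
#'   mS/m), `intercept` (mM), `residual_sd`, `n_pairs`, `max_pairing_gap`,
#'   and the retained `pairs`.
#' @export
fit_alkalinity_conductivity <- function(weekly_alk, conductivity, max_gap_hours = 6) {
  stopifnot(all(c("timestamp", "value") %in% names(weekly_alk)),
            all(c("timestamp", "value") %in% names(conductivity)))
  ct <- as.numeric(conductivity$timestamp)
  ord <- order(ct)
  ct <- ct[ord]; cv <- conductivity$value[ord]
  at <- as.numeric(weekly_alk$timestamp)

  idx <- findInterval(at, ct)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(ct))
  dlo <- abs(at - ct[lo]); dhi <- abs(at - ct[hi])
  # nearest in absolute time; tie -> earlier observation
  pick <- ifelse(dhi < dlo, hi, lo)
  gap_h <- abs(at - ct[pick]) / 3600
  keep <- gap_h <= max_gap_hours
  if (sum(keep) < 2)
    stop(sprintf("need >= 2 alkalinity/conductivity pairs within %g h; got %d",
                 max_gap_hours, sum(keep)), call. = FALSE)
  pairs <- data.frame(alk_time = weekly_alk$timestamp[keep],
                      alkalinity = weekly_alk$value[keep],
                      conductivity = cv[pick][keep],
                      gap_hours = gap_h[keep])
  fit <- stats::lm(alkalinity ~ conductivity, data = pairs)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              residual_sd = stats::sigma(fit),
              n_pairs = nrow(pairs),
              max_pairing_gap = max_gap_hours,
              pairs = pairs)
  class(out) <- "alk_cond_fit"
  out
}

#' @export
print.alk_cond_fit <- function(x, ...) {
  cat("Alkalinity ~ conductivity fit\n")
  cat(sprintf("  slope     %.5f mM per mS/m\n", x$slope))
  cat(sprintf("  intercept %.4f mM\n", x$intercept))
  cat(sprintf("  residual sd %.4g mM; n = %d pairs (gap <= %g h)\n",
              x$residual_sd, x$n_pairs, x$max_pairing_gap))
  invisible(x)
}

#' Predict alkalinity (mM) from conductivity with a fitted pairing regression
#' @param fit an `alk_cond_fit`.
#' @param conductivity numeric vector, mS/m.
#' @return numeric vector of alkalinity, mM.
#' @export
predict_alkalinity <- function(fit, conductivity) {
  stopifnot(inherits(fit, "alk_cond_fit"))
  fit$intercept + fit$slope * conductivity
}

#' High-resolution dissolved CO2 series from sensor data
#'
#' Predicts alkalinity from conductivity through an [fit_alkalinity_conductivity()]
#' regression, then applies the carbonate solver pointwise at every timestamp
#' where pH, temperature and conductivity are all observed. Chemically
#' infeasible points (e.g. a pH/alkalinity combination implying negative
#' bicarbonate, or predicted alkalinity <= 0) are excluded from the output and
#' reported in the `infeasible` attribute rather than silently dropped.
#'
#' @param sensor_series an `observation_series` containing factors `pH`,
#'   `temperature` and `conductivity`.
#' @param fit an `alk_cond_fit`.
#' @return an `observation_series` of factor `co2` (mol/L) with attribute
#'   `infeasible`: data frame of excluded timestamps and reasons.
#' @export
co2_series <- function(sensor_series, fit) {
  stopifnot(inherits(fit, "alk_cond_fit"))
  need <- c("pH", "temperature", "conductivity")
  have <- unique(sensor_series$factor)
  if (length(miss <- setdiff(need, have))) stop_names(miss, "sensor series")
  wide <- NULL
  for (f in need) {
    sub <- sensor_series[sensor_series$factor == f, c("timestamp", "value")]
    names(sub)[2] <- f
    wide <- if (is.null(wide)) sub else merge(wide, sub, by = "timestamp")
  }
  wide <- wide[order(wide$timestamp), ]
  alk_mM <- predict_alkalinity(fit, wide$conductivity)
  alk <- alk_mM * 1e-3
  ok <- alk > 0 & wide$pH >= 4 & wide$pH <= 12
  st <- speciate(wide$temperature[ok], wide$pH[ok], alk[ok])
  feas <- st$hco3 >= 0 & st$co2_aq >= 0
  reasons <- character(0); bad_ts <- wide$timestamp[0]
  if (any(!ok)) {
    bad_ts <- wide$timestamp[!ok]
    reasons <- rep("alkalinity or pH out of solver domain", sum(!ok))
  }
  if (any(!feas)) {
    bad_ts <- c(bad_ts, wide$timestamp[ok][!feas])
    reasons <- c(reasons, rep("negative bicarbonate (pH/alkalinity inconsistent)",
                              sum(!feas)))
  }
  out <- data.frame(timestamp = wide$timestamp[ok][feas],
                    factor = "co2",
                    value = st$co2_aq[feas],
                    unit = "mol/L",
                    cadence = "sensor",
                    stringsAsFactors = FALSE)
  class(out) <- c("observation_series", "data.frame")
  attr(out, "infeasible") <- data.frame(timestamp = bad_ts, reason = reasons)
  out
}
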