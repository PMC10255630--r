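#' Training/validation/application year split
#'
#' @param training,validation,application disjoint integer year vectors.
#'   Defaults follow the study design: train 2015-2019, validate 2020,
#'   apply 2022 (leaving a gap year between validation and application).
#' @return an object of class `split_spec`.
#' @export
split_spec <- function(training = 2015:2019, validation = 2020, application = 2022) {
  all <- c(training, validation, application)
  if (anyDuplicated(all)) stop("split year sets must be disjoint", call. = FALSE)
  structure(list(training = training, validation = validation,
                 application = application), class = "split_spec")
}

#' Collapse a mixed-cadence observation series onto a weekly grid
#'
#' Sensor-cadence factors are averaged within each ISO week; weekly lab
#' factors contribute the week's point value. The representative day of a
#' week is its Monday, from which the `year`, `month` and `day` date fields
#' are taken. Weeks left incomplete after the missing-value policy are
#' dropped and recorded.
#'
#' @param series an `observation_series`.
#' @param policy missing-week handling: `"interpolate"` fills runs of up to
#'   `max_interp` consecutive missing weeks per factor linearly;
#'   `"drop"` drops incomplete weeks outright.
#' @param max_interp longest interpolated run, in weeks (default 2).
#' @return an object of class `weekly_table`: data frame with `week_start`
#'   (Date, Monday), `year`, `month`, `day`, then one column per factor.
#'   Attributes: `policy`, `dropped_weeks`, `units`.
#' @export
to_weekly <- function(series, policy = c("interpolate", "drop"), max_interp = 2) {
  stopifnot(inherits(series, "observation_series"))
  policy <- match.arg(policy)
  if (nrow(series) == 0) stop("empty observation series", call. = FALSE)
  monday <- iso_monday(as.Date(series$timestamp, tz = "UTC"))
  factors <- unique(series$factor)
  weeks <- sort(unique(monday))
  grid <- seq(weeks[1], weeks[length(weeks)], by = 7)
  out <- data.frame(week_start = grid)
  units <- character(0)
  for (f in factors) {
    sel <- series$factor == f
    cad <- series$cadence[sel][1]
    units[f] <- series$unit[sel][1]
    agg <- if (cad == "weekly") {
      # lab point value: first observation of the week
      m <- monday[sel]; k <- !duplicated(m)
      stats::setNames(series$value[sel][k], as.character(m[k]))
    } else {
      tapply(series$value[sel], as.character(monday[sel]), mean)
    }
    out[[f]] <- unname(agg[as.character(grid)])
  }
  if (policy == "interpolate") {
    for (f in factors) {
      v <- out[[f]]
      if (sum(!is.na(v)) < 2) next
      filled <- stats::approx(seq_along(v)[!is.na(v)], v[!is.na(v)],
                              xout = seq_along(v), rule = 1)$y
      runs <- rle(is.na(v))
      pos <- cumsum(c(1, runs$lengths))
      for (i in seq_along(runs$lengths)) {
        if (runs$values[i] && runs$lengths[i] <= max_interp) {
          idx <- pos[i]:(pos[i] + runs$lengths[i] - 1)
          v[idx] <- filled[idx]
        }
      }
      out[[f]] <- v
    }
  }
  complete <- stats::complete.cases(out[factors])
  dropped <- out$week_start[!complete]
  out <- out[complete, ]
  if (nrow(out) == 0) stop("no complete weeks after applying policy", call. = FALSE)
  out$year <- as.integer(format(out$week_start, "%Y"))
  out$month <- as.integer(format(out$week_start, "%m"))
  out$day <- as.integer(format(out$week_start, "%d"))
  out <- out[c("week_start", "year", "month", "day", factors)]
  rownames(out) <- NULL
  class(out) <- c("weekly_table", "data.frame")
  attr(out, "policy") <- list(policy = policy, max_interp = max_interp)
  attr(out, "dropped_weeks") <- dropped
  attr(out, "units") <- units
  out
}

#' @export
print.weekly_table <- function(x, ...) {
  cat(sprintf("weekly_table: %d weeks (%s .. %s), factors: %s\n",
              nrow(x), min(x$week_start), max(x$week_start),
              paste(setdiff(names(x), c("week_start", "year", "month", "day")),
                    collapse = ", ")))
  invisible(x)
}

date_fields <- c("year", "month", "day")

weekly_factors <- function(table) setdiff(names(table), c("week_start", date_fields))

#' Min-max normalization fitted on training years only
#'
#' Per-factor (min, max) are taken exclusively from rows whose year belongs
#' to the training split, so later periods cannot leak into the scaling.
#' Applying the spec maps training values into `[0, 1]`; validation and
#' application values may fall outside and are deliberately not clipped.
#'
#' @param table a `weekly_table`.
#' @param split a [split_spec()].
#' @param columns columns to normalize (default: date fields plus every
#'   factor column).
#' @param log10_factors factors transformed to log10 before scaling
#'   (cell counts span orders of magnitude and bloom noise is
#'   multiplicative, so algae is modelled on the log scale by the scanning
#'   pipeline; values must be positive).
#' @return an object of class `normalizer`.
#' @export
fit_normalizer <- function(table, split, columns = NULL,
                           log10_factors = character(0)) {
  stopifnot(inherits(table, "weekly_table"), inherits(split, "split_spec"))
  columns <- columns %||% c(date_fields, weekly_factors(table))
  log10_factors <- intersect(log10_factors, columns)
  tr <- table[table$year %in% split$training, columns, drop = FALSE]
  if (nrow(tr) == 0) stop("no training rows for normalizer", call. = FALSE)
  for (f in log10_factors) {
    if (any(tr[[f]] <= 0))
      stop(sprintf("factor '%s' must be positive for a log10 transform", f),
           call. = FALSE)
    tr[[f]] <- log10(tr[[f]])
  }
  mins <- vapply(tr, min, numeric(1))
  maxs <- vapply(tr, max, numeric(1))
  const <- names(tr)[maxs <= mins]
  if (length(const))
    stop(sprintf("constant factor(s) in training period: %s",
                 paste(const, collapse = ", ")), call. = FALSE)
  structure(list(columns = columns, min = mins, max = maxs,
                 log10_factors = log10_factors, method = "minmax"),
            class = "normalizer")
}

#' @rdname fit_normalizer
#' @param norm a `normalizer`.
#' @export
apply_normalizer <- function(norm, table) {
  stopifnot(inherits(norm, "normalizer"))
  for (f in norm$columns) {
    v <- table[[f]]
    if (f %in% norm$log10_factors) v <- log10(v)
    table[[f]] <- (v - norm$min[[f]]) / (norm$max[[f]] - norm$min[[f]])
  }
  table
}

#' @rdname fit_normalizer
#' @export
invert_normalizer <- function(norm, table) {
  stopifnot(inherits(norm, "normalizer"))
  for (f in intersect(norm$columns, names(table))) {
    v <- table[[f]] * (norm$max[[f]] - norm$min[[f]]) + norm$min[[f]]
    if (f %in% norm$log10_factors) v <- 10^v
    table[[f]] <- v
  }
  table
}

# de-normalization scale (max - min) for one factor
norm_scale <- function(norm, factor) norm$max[[factor]] - norm$min[[factor]]

#' Sliding-window multi-output samples from a weekly table
#'
#' Builds one sample per valid window position: the input is a `W`-week by
#' `F`-factor block flattened in fixed (week-lag major, factor minor) order -
#' oldest week first - and the target is the vector of non-date factors
#' (always including algae) `h` weeks after the last input week. Windows
#' must be strictly consecutive weeks; any window or target crossing a data
#' gap is excluded.
#'
#' @param table a `weekly_table` (normalized or raw).
#' @param subset character vector of optional companion factors (possibly
#'   empty - the date+algae-only baseline).
#' @param W input window length in weeks (default 7).
#' @param h forecast horizon in weeks (default 1).
#' @param target_factor the always-present forecast factor (default
#'   `"algae"`).
#' @return an object of class `window_set`: list with input matrix `X`
#'   (n x W*F, colnames `wk<lag>_<factor>`), target matrix `Y`
#'   (n x outputs), `target_week`, and metadata (`subset`, `factors`,
#'   `targets`, `W`, `h`).
#' @export
build_windows <- function(table, subset = character(0), W = 7, h = 1,
                          target_factor = "algae") {
  stopifnot(inherits(table, "weekly_table"))
  subset <- setdiff(subset, target_factor)
  avail <- weekly_factors(table)
  if (length(miss <- setdiff(c(target_factor, subset), avail)))
    stop_names(miss, "weekly table")
  n <- nrow(table)
  if (n < W + h)
    stop(sprintf("need at least W + h = %d rows; got %d", W + h, n), call. = FALSE)
  in_factors <- c(date_fields, target_factor, subset)
  targets <- c(target_factor, subset)
  # valid start positions: weeks i .. i+W-1 and target week i+W-1+h all
  # consecutive (7-day spacing throughout)
  gaps <- diff(as.numeric(table$week_start)) == 7
  span <- W + h - 1
  starts <- which(vapply(seq_len(n - span), function(i)
    all(gaps[i:(i + span - 1)]), logical(1)))
  if (length(starts) == 0)
    stop("no contiguous window positions available", call. = FALSE)
  M <- as.matrix(table[in_factors])
  Ym <- as.matrix(table[targets])
  X <- matrix(NA_real_, length(starts), W * length(in_factors))
  colnames(X) <- as.vector(t(outer(seq_len(W), in_factors,
                                   function(l, f) sprintf("wk%d_%s", l, f))))
  for (j in seq_len(W)) {
    cols <- (j - 1) * length(in_factors) + seq_along(in_factors)
    X[, cols] <- M[starts + j - 1, , drop = FALSE]
  }
  Y <- Ym[starts + W - 1 + h, , drop = FALSE]
  colnames(Y) <- targets
  structure(list(X = X, Y = Y,
                 target_week = table$week_start[starts + W - 1 + h],
                 subset = subset, factors = in_factors, targets = targets,
                 W = W, h = h),
            class = "window_set")
}

#' @export
print.window_set <- function(x, ...) {
  cat(sprintf("window_set: %d samples, W=%d h=%d, inputs %d (%s), targets %s\n",
              nrow(x$X), x$W, x$h, ncol(x$X),
              paste(x$factors, collapse = ","),
              paste(x$targets, collapse = ",")))
  invisible(x)
}

# restrict a window_set to samples whose target week falls in given years
filter_windows <- function(ws, years) {
  keep <- as.integer(format(ws$target_week, "%Y")) %in% years
  ws$X <- ws$X[keep, , drop = FALSE]
  ws$Y <- ws$Y[keep, , drop = FALSE]
  ws$target_week <- ws$target_week[keep]
  ws
}
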