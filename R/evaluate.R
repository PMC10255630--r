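#' Chlorophyll-a equivalent of an algal cell count
#'
#' Linear conversion anchored on the empirical relationship that 4e6
#' cells/L corresponds to roughly 30-40 ug/L chlorophyll-a; the default
#' factor uses the midpoint, 35 ug/L per 4e6 cells.
#'
#' @param cells_per_L non-negative cell counts.
#' @param factor ug/L chlorophyll per cell (default `35 / 4e6`).
#' @return chlorophyll-a equivalent, ug/L.
#' @export
#' @examples
#' cells_to_chlorophyll(4e6) # 35
cells_to_chlorophyll <- function(cells_per_L, factor = 35 / 4e6) {
  if (any(cells_per_L < 0)) stop("cell counts must be >= 0", call. = FALSE)
  cells_per_L * factor
}

#' Risk band of a chlorophyll-a equivalent
#'
#' Recreational-water guidance bands: below 10 ug/L is regarded safe,
#' 10-50 ug/L carries a moderate probability of adverse health effects, and
#' above 50 ug/L a high probability. The guidance's separate "low" band
#' (>10 ug/L with cyanobacteria dominance) is folded into "moderate"
#' because taxonomic dominance is not an available input. The upper band is
#' closed below: exactly 50 ug/L classifies as high.
#'
#' @param chlorophyll_eq ug/L, non-negative.
#' @return factor with levels `safe`, `moderate`, `high`.
#' @export
classify_risk <- function(chlorophyll_eq) {
  if (any(chlorophyll_eq < 0)) stop("chlorophyll must be >= 0", call. = FALSE)
  cut(chlorophyll_eq, breaks = c(-Inf, 10, 50, Inf),
      labels = c("safe", "moderate", "high"), right = FALSE)
}

#' Per-factor evaluation report across periods
#'
#' Evaluates each supplied model on the training, validation and
#' application periods of a weekly table, reporting per-factor R^2 and RMSE
#' in native units plus the pooled integrated metrics, in the same layout
#' as a method x factor x period results table. Factors absent from a
#' model's closed system appear as explicit not-applicable rows rather than
#' being silently missing. The application period exercises the
#' temporal-gap scenario when the table was generated with a gap between
#' validation and application years.
#'
#' @param models named list of `fnn` or `closed_system` objects (e.g.
#'   `list(SP = ..., BP = ..., DATH = ...)`).
#' @param weekly a `weekly_table` covering all periods.
#' @param split a [split_spec()].
#' @param normalizer the [fit_normalizer()] spec the models were trained
#'   under.
#' @param W,h window length and horizon (must match the models).
#' @return an object of class `evaluation_report`: data frame with columns
#'   `method`, `period`, `factor`, `r2`, `rmse`, `rmse_norm`, `n`,
#'   `applicable`; integrated rows use factor `"(integrated)"`.
#' @export
evaluate_models <- function(models, weekly, split, normalizer, W = 7, h = 1) {
  stopifnot(is.list(models), length(names(models)) == length(models),
            inherits(split, "split_spec"))
  ntab <- apply_normalizer(normalizer, weekly)
  periods <- list(training = split$training, validation = split$validation,
                  application = split$application)
  all_factors <- unique(unlist(lapply(models, function(m) {
    mm <- if (inherits(m, "closed_system")) m$model else m
    mm$output_names
  })))
  rows <- list()
  for (meth in names(models)) {
    model <- models[[meth]]
    if (inherits(model, "closed_system")) model <- model$model
    stopifnot(inherits(model, "fnn"))
    ws <- build_windows(ntab, model$condition$subset, W = W, h = h)
    if (!identical(colnames(ws$X), model$input_names))
      stop(sprintf("model '%s' does not match the weekly table's factors", meth),
           call. = FALSE)
    for (per in names(periods)) {
      sub <- filter_windows(ws, periods[[per]])
      if (nrow(sub$X) == 0) next
      sc <- integrated_score(predict(model, sub), sub$Y, normalizer)
      pf <- sc$per_factor
      rows[[length(rows) + 1]] <- data.frame(
        method = meth, period = per,
        factor = c(pf$factor, "(integrated)"),
        r2 = c(pf$r2, sc$integrated_r2),
        rmse = c(pf$rmse_native, NA),
        rmse_norm = c(pf$rmse_norm, sqrt(sc$integrated_mse)),
        n = nrow(sub$X),
        applicable = TRUE, stringsAsFactors = FALSE)
      na_fac <- setdiff(all_factors, pf$factor)
      if (length(na_fac))
        rows[[length(rows) + 1]] <- data.frame(
          method = meth, period = per, factor = na_fac,
          r2 = NA_real_, rmse = NA_real_, rmse_norm = NA_real_,
          n = nrow(sub$X), applicable = FALSE, stringsAsFactors = FALSE)
    }
  }
  rep <- do.call(rbind, rows)
  rownames(rep) <- NULL
  class(rep) <- c("evaluation_report", "data.frame")
  attr(rep, "split") <- split
  rep
}

#' @export
print.evaluation_report <- function(x, digits = 3, ...) {
  for (per in unique(x$period)) {
    cat(sprintf("\n== %s period ==\n", per))
    sub <- x[x$period == per & x$factor != "(integrated)", ]
    facs <- unique(sub$factor)
    header <- sprintf("%-10s", "method")
    for (f in facs) header <- paste0(header, sprintf(" | %14s R2 / RMSE", f))
    cat(header, "\n")
    for (m in unique(sub$method)) {
      line <- sprintf("%-10s", m)
      for (f in facs) {
        r <- sub[sub$method == m & sub$factor == f, ]
        cell <- if (nrow(r) == 0 || !r$applicable[1]) sprintf("%25s", "-")
        else sprintf("%12.3f / %9.3g", r$r2[1], r$rmse[1])
        line <- paste0(line, " | ", cell)
      }
      cat(line, "\n")
    }
  }
  invisible(x)
}
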