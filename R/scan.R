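#' Enumerate all non-empty factor subsets
#'
#' All `2^k - 1` non-empty subsets of the candidate factors, in a
#' deterministic order: by subset size, then lexicographically. Six
#' candidates give the 63 combinations the full scan explores.
#'
#' @param candidates character vector of distinct factor names (1 to 12).
#' @return list of character vectors, each in candidate order.
#' @export
#' @examples
#' length(enumerate_subsets(c("a", "b", "c"))) # 7
enumerate_subsets <- function(candidates) {
  k <- length(candidates)
  if (k < 1 || k > 12) stop("need 1 to 12 candidate factors", call. = FALSE)
  if (anyDuplicated(candidates)) stop("duplicate candidate names", call. = FALSE)
  masks <- seq_len(2^k - 1)
  subsets <- lapply(masks, function(m) candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  keys <- vapply(subsets, function(s) paste(sort(s), collapse = ","), character(1))
  sizes <- lengths(subsets)
  subsets[order(sizes, keys)]
}

subset_key <- function(subset) {
  if (length(subset) == 0) "SP" else paste(subset, collapse = "+")
}

#' Scan grid: subsets x neuron counts x replicates
#'
#' The default grid reproduces the full study design: the 6 candidate
#' factors (63 subsets), hidden-layer sizes 1-10, and 10 seeded replicates
#' per condition (630 conditions, 6300 trainings). The empty subset - the
#' date+algae-only "simple process" (SP) baseline - is appended as an
#' ordinary grid member so the Granger retention rule has a reference for
#' singleton subsets; the full subset is the "blind process" (BP) baseline.
#'
#' @param candidates candidate factor names.
#' @param neurons integer vector of hidden-layer sizes.
#' @param replicates replicates per condition.
#' @param base_seed base seed; every training's seed is derived from it with
#'   [condition_seed()].
#' @param include_sp include the empty subset (SP baseline).
#' @return an object of class `scan_grid`.
#' @export
scan_grid <- function(candidates = c("temperature", "pH", "conductivity",
                                     "turbidity", "dom_uv254", "co2"),
                      neurons = 1:10, replicates = 10, base_seed = 1,
                      include_sp = TRUE) {
  subsets <- enumerate_subsets(candidates)
  if (include_sp) subsets <- c(list(character(0)), subsets)
  structure(list(candidates = candidates, subsets = subsets,
                 neurons = as.integer(neurons),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed)),
            class = "scan_grid")
}

#' @export
print.scan_grid <- function(x, ...) {
  n_sub <- length(x$subsets)
  cat(sprintf("scan_grid: %d subsets (of %d candidates) x %d neuron counts x %d replicates = %d trainings\n",
              n_sub, length(x$candidates), length(x$neurons), x$replicates,
              n_sub * length(x$neurons) * x$replicates))
  invisible(x)
}

#' Integrated and per-factor fit metrics
#'
#' Per-factor `R^2 = 1 - SSE/SST` plus RMSE; the integrated metrics pool all
#' normalized (prediction, target) pairs across output factors, with the
#' total sum of squares taken about each factor's own mean
#' (`R^2 = 1 - sum_f SSE_f / sum_f SST_f`), so one number summarizes the
#' whole multi-output fit without between-factor level differences counting
#' as explained variance. A zero-variance target factor has no defined R^2;
#' it is flagged, excluded from pooling, and a warning is raised.
#'
#' @param predictions,targets numeric matrices in normalized space, same
#'   shape, columns named by factor.
#' @param normalizer optional [fit_normalizer()] spec; when supplied,
#'   per-factor RMSE is also reported on the de-normalized (native) scale.
#' @return list with `integrated_r2`, `integrated_mse`, and `per_factor`
#'   data frame (`factor`, `r2`, `rmse_norm`, `rmse_native`, `flagged`).
#' @export
integrated_score <- function(predictions, targets, normalizer = NULL) {
  stopifnot(all(dim(predictions) == dim(targets)))
  factors <- colnames(targets)
  per <- data.frame(factor = factors, r2 = NA_real_, rmse_norm = NA_real_,
                    rmse_native = NA_real_, flagged = FALSE)
  for (i in seq_along(factors)) {
    y <- targets[, i]; yh <- predictions[, i]
    sst <- sum((y - mean(y))^2)
    per$rmse_norm[i] <- sqrt(mean((y - yh)^2))
    if (!is.null(normalizer) && factors[i] %in% names(normalizer$min))
      per$rmse_native[i] <- per$rmse_norm[i] * norm_scale(normalizer, factors[i])
    if (sst == 0) {
      per$flagged[i] <- TRUE
      warning(sprintf("target factor '%s' has zero variance; R^2 undefined, excluded from pooling",
                      factors[i]), call. = FALSE)
    } else {
      per$r2[i] <- 1 - sum((y - yh)^2) / sst
    }
  }
  use <- which(!per$flagged)
  sse <- sum((targets[, use, drop = FALSE] - predictions[, use, drop = FALSE])^2)
  sst <- sum(vapply(use, function(i) sum((targets[, i] - mean(targets[, i]))^2),
                    numeric(1)))
  list(integrated_r2 = 1 - sse / sst,
       integrated_mse = sse / (nrow(targets) * length(use)),
       per_factor = per)
}

#' Run the scanning process over a weekly table
#'
#' Trains `|subsets| x |neurons| x replicates` networks on the training
#' years, scores each on training and validation years with
#' [integrated_score()], and records one ledger row per training. Seeds are
#' derived deterministically from the base seed and the condition key, so a
#' scan is exactly reproducible and resumable: with `ledger_file` set,
#' completed rows are re-read on restart and their trainings skipped. A
#' diverged training is recorded in the ledger, never aborts the scan.
#'
#' @param grid a [scan_grid()].
#' @param weekly a `weekly_table` covering training and validation years.
#' @param split a [split_spec()].
#' @param W,h window length and horizon in weeks.
#' @param control an [fnn_control()].
#' @param log10_factors factors modelled on the log10 scale (default
#'   algae; see [fit_normalizer()]).
#' @param ledger_file optional CSV path for the persistent run ledger.
#' @param verbose print per-subset progress.
#' @return an object of class `scan_result`: `ledger` (one row per
#'   training), `conditions` (per-condition mean/sd summaries),
#'   `per_factor` (best replicate per condition), plus everything needed to
#'   deterministically retrain any model (`grid`, `split`, `normalizer`,
#'   normalized table, `W`, `h`, `control`).
#' @export
run_scan <- function(grid, weekly, split, W = 7, h = 1,
                     control = fnn_control(), log10_factors = "algae",
                     ledger_file = NULL, verbose = FALSE) {
  stopifnot(inherits(grid, "scan_grid"), inherits(weekly, "weekly_table"),
            inherits(split, "split_spec"))
  years <- c(split$training, split$validation)
  tab <- weekly[weekly$year %in% years, ]
  class(tab) <- class(weekly)
  norm <- fit_normalizer(tab, split,
                         columns = c(date_fields, "algae", grid$candidates),
                         log10_factors = log10_factors)
  ntab <- apply_normalizer(norm, tab)

  done <- NULL
  if (!is.null(ledger_file) && file.exists(ledger_file))
    done <- utils::read.csv(ledger_file, stringsAsFactors = FALSE)

  rows <- list(); perfac <- list()
  for (s_i in seq_along(grid$subsets)) {
    subset <- grid$subsets[[s_i]]
    key <- subset_key(subset)
    ws <- build_windows(ntab, subset, W = W, h = h)
    tr <- filter_windows(ws, split$training)
    va <- filter_windows(ws, split$validation)
    for (m in grid$neurons) {
      for (r in seq_len(grid$replicates)) {
        prev <- if (!is.null(done))
          done[done$subset == key & done$n_hidden == m & done$replicate == r, ]
        if (!is.null(prev) && nrow(prev) == 1) { rows[[length(rows) + 1]] <- prev; next }
        seed <- condition_seed(grid$base_seed, key, m, r)
        row <- data.frame(subset = key, size = length(subset), n_hidden = m,
                          replicate = r, seed = seed,
                          train_r2 = NA_real_, train_mse = NA_real_,
                          val_r2 = NA_real_, val_mse = NA_real_,
                          diverged = FALSE, stringsAsFactors = FALSE)
        model <- tryCatch(fnn_train(tr, m, seed, control), error = function(e) NULL)
        if (is.null(model)) {
          row$diverged <- TRUE
        } else {
          str <- integrated_score(predict(model, tr), tr$Y)
          sva <- integrated_score(predict(model, va), va$Y)
          row$train_r2 <- str$integrated_r2; row$train_mse <- str$integrated_mse
          row$val_r2 <- sva$integrated_r2; row$val_mse <- sva$integrated_mse
        }
        rows[[length(rows) + 1]] <- row
        if (!is.null(ledger_file))
          utils::write.table(row, ledger_file, sep = ",", append = file.exists(ledger_file),
                             col.names = !file.exists(ledger_file), row.names = FALSE)
      }
    }
    if (verbose)
      message(sprintf("[%d/%d] scanned subset {%s}", s_i, length(grid$subsets), key))
  }
  ledger <- do.call(rbind, rows)
  rownames(ledger) <- NULL

  agg <- stats::aggregate(cbind(train_r2, train_mse, val_r2, val_mse) ~ subset + size + n_hidden,
                          data = ledger, FUN = mean, na.action = stats::na.pass)
  sds <- stats::aggregate(cbind(train_r2, val_r2) ~ subset + size + n_hidden,
                          data = ledger, FUN = stats::sd, na.action = stats::na.pass)
  names(sds)[4:5] <- c("train_r2_sd", "val_r2_sd")
  conditions <- merge(agg, sds, by = c("subset", "size", "n_hidden"))
  best <- do.call(rbind, lapply(split.data.frame(ledger, paste(ledger$subset, ledger$n_hidden)),
                                function(d) d[which.max(d$val_r2), ]))
  names(best)[names(best) == "seed"] <- "best_seed"
  conditions <- merge(conditions,
                      best[c("subset", "n_hidden", "best_seed", "replicate")],
                      by = c("subset", "n_hidden"))
  names(conditions)[names(conditions) == "replicate"] <- "best_replicate"
  conditions <- conditions[order(conditions$size, conditions$subset, conditions$n_hidden), ]
  rownames(conditions) <- NULL

  structure(list(ledger = ledger, conditions = conditions, grid = grid,
                 split = split, normalizer = norm, table = ntab,
                 W = W, h = h, control = control),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("scan_result: %d trainings over %d conditions (%d subsets x %d neuron counts x %d replicates)\n",
              nrow(x$ledger), nrow(x$conditions), length(x$grid$subsets),
              length(x$grid$neurons), x$grid$replicates))
  if (any(x$ledger$diverged))
    cat(sprintf("  %d diverged trainings flagged\n", sum(x$ledger$diverged)))
  bn <- best_neurons_per_subset(x)
  top <- utils::head(bn[order(-bn$val_r2), ], 5)
  cat("top subsets by mean validation integrated R^2 (at best neuron count):\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-38s n_hidden=%2d  R2=%.3f\n",
                top$subset[i], top$n_hidden[i], top$val_r2[i]))
  invisible(x)
}

#' @export
summary.scan_result <- function(object, ...) {
  bn <- best_neurons_per_subset(object)
  bn[order(-bn$val_r2), ]
}

#' Best hidden-layer size per subset
#'
#' Argmax over neuron counts of the mean validation integrated R^2, ties
#' broken toward the smaller network. The output-factor count is reported
#' alongside so the empirical tendency of the best size to match the number
#' of outputs can be inspected (it is reported, not asserted).
#'
#' @param result a `scan_result`.
#' @return data frame: `subset`, `n_hidden`, `val_r2`, `n_outputs`,
#'   `matches_outputs`.
#' @export
best_neurons_per_subset <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  cond <- result$conditions
  out <- do.call(rbind, lapply(split.data.frame(cond, cond$subset), function(d) {
    d <- d[order(d$n_hidden), ]
    b <- d[which.max(d$val_r2), ] # which.max takes the first (smallest) on ties
    b
  }))
  out$n_outputs <- out$size + 1L # subset factors + algae
  out$matches_outputs <- out$n_hidden == out$n_outputs
  rownames(out) <- NULL
  out[c("subset", "size", "n_hidden", "val_r2", "val_r2_sd", "best_seed",
        "n_outputs", "matches_outputs")]
}

# retrain the recorded best replicate of (subset, n_hidden) bit-identically
retrain_best <- function(result, key, n_hidden) {
  subset <- result$grid$subsets[[match(key, vapply(result$grid$subsets,
                                                   subset_key, character(1)))]]
  ws <- build_windows(result$table, subset, W = result$W, h = result$h)
  tr <- filter_windows(ws, result$split$training)
  seed <- result$conditions$best_seed[result$conditions$subset == key &
                                        result$conditions$n_hidden == n_hidden]
  fnn_train(tr, n_hidden, seed, result$control)
}

#' Retrieve the best trained model for a subset from a scan
#'
#' Deterministically retrains the recorded best replicate of the given
#' subset at its best neuron count (or a specified one). Useful for pulling
#' out the SP (empty subset) and BP (full subset) baseline models that are
#' ordinary members of the grid.
#'
#' @param result a `scan_result`.
#' @param subset character vector of factors (empty for the SP baseline).
#' @param n_hidden optional neuron count; default: the subset's best.
#' @return an `fnn`.
#' @export
scan_best_model <- function(result, subset = character(0), n_hidden = NULL) {
  stopifnot(inherits(result, "scan_result"))
  key <- subset_key(subset)
  if (is.null(n_hidden)) {
    bn <- best_neurons_per_subset(result)
    if (!key %in% bn$subset) stop(sprintf("subset '%s' not in scan", key), call. = FALSE)
    n_hidden <- bn$n_hidden[bn$subset == key]
  }
  retrain_best(result, key, n_hidden)
}

#' Select closed systems by the Granger-improvement rule
#'
#' Ranks subsets by mean validation integrated R^2 at each subset's best
#' neuron count, then verifies the defining closed-system property against
#' the scan's own neighbouring subsets: every member factor must improve the
#' system by more than `tolerance` (its removal drops the score), and no
#' outside factor may add more than `tolerance` when included. Ties in
#' ranking break toward smaller subsets. If no subset passes, the top
#' subsets are still returned with their property flags set false - the
#' failure is reported, not hidden.
#'
#' @param result a `scan_result`.
#' @param top_k how many systems to return.
#' @param tolerance R^2-units improvement threshold (default 0.01).
#' @param models if `TRUE` (default), deterministically retrain and attach
#'   each selected system's best replicate model.
#' @return an object of class `closed_system_set`: list of `closed_system`
#'   objects (subset, best `n_hidden`, the retrained best replicate model,
#'   and the member/non-member evidence table) plus the full ranking.
#' @export
select_closed_systems <- function(result, top_k = 2, tolerance = 0.01,
                                  models = TRUE) {
  stopifnot(inherits(result, "scan_result"))
  bn <- best_neurons_per_subset(result)
  score <- stats::setNames(bn$val_r2, bn$subset)
  keys <- vapply(result$grid$subsets, subset_key, character(1))
  nonempty <- bn[bn$subset != "SP", ]
  ord <- order(-nonempty$val_r2, nonempty$size, nonempty$subset)
  ranking <- nonempty[ord, ]
  ranking$rank <- seq_len(nrow(ranking))

  candidates <- result$grid$candidates
  check <- function(key) {
    subset <- result$grid$subsets[[match(key, keys)]]
    ev <- data.frame(factor = character(0), role = character(0),
                     delta = numeric(0))
    for (f in subset) {
      k2 <- subset_key(setdiff(subset, f))
      d <- if (k2 %in% names(score)) score[[key]] - score[[k2]] else NA_real_
      ev <- rbind(ev, data.frame(factor = f, role = "member", delta = d))
    }
    for (g in setdiff(candidates, subset)) {
      k2 <- subset_key(candidates[candidates %in% c(subset, g)])
      d <- if (k2 %in% names(score)) score[[k2]] - score[[key]] else NA_real_
      ev <- rbind(ev, data.frame(factor = g, role = "non_member", delta = d))
    }
    passes <- if (is.infinite(tolerance)) TRUE else
      isTRUE(all(ev$delta[ev$role == "member"] > tolerance, na.rm = FALSE) &&
               all(ev$delta[ev$role == "non_member"] <= tolerance, na.rm = FALSE))
    list(evidence = ev, passes = passes)
  }

  ranking$passes <- vapply(ranking$subset, function(k) check(k)$passes, logical(1))
  chosen <- ranking[ranking$passes, ]
  flagged_fallback <- nrow(chosen) == 0
  if (flagged_fallback) chosen <- ranking
  chosen <- utils::head(chosen, top_k)

  systems <- lapply(seq_len(nrow(chosen)), function(i) {
    key <- chosen$subset[i]
    ck <- check(key)
    structure(list(subset = result$grid$subsets[[match(key, keys)]],
                   key = key, n_hidden = chosen$n_hidden[i],
                   val_r2 = chosen$val_r2[i], rank = chosen$rank[i],
                   passes_property = ck$passes, evidence = ck$evidence,
                   model = if (models) retrain_best(result, key, chosen$n_hidden[i])),
              class = "closed_system")
  })
  structure(list(systems = systems, ranking = ranking, tolerance = tolerance,
                 fallback = flagged_fallback),
            class = "closed_system_set")
}

#' @export
print.closed_system <- function(x, ...) {
  cat(sprintf("closed_system {%s}: n_hidden=%d, validation integrated R^2=%.3f, rank %d, property %s\n",
              x$key, x$n_hidden, x$val_r2, x$rank,
              if (x$passes_property) "PASS" else "FAIL"))
  ev <- x$evidence
  for (i in seq_len(nrow(ev)))
    cat(sprintf("  %-12s %-10s delta R^2 = %+0.3f\n", ev$factor[i], ev$role[i],
                ev$delta[i]))
  invisible(x)
}

#' @export
print.closed_system_set <- function(x, ...) {
  if (x$fallback)
    cat("NOTE: no subset passed the closed-system property; showing top-ranked subsets flagged FAIL\n")
  for (s in x$systems) print(s)
  invisible(x)
}
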