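# Planted-structure recovery suite: five independent synthetic scenarios,
# each scanned over all 63 subsets of the 6 candidate factors with a reduced
# grid (neurons 1..5, 3 replicates). Computed once and shared by the
# acceptance checks that look at different aspects of the same runs.
recovery_suite <- local({
  cache <- NULL
  function(base_seed = 1) {
    if (!is.null(cache)) return(cache)
    rows <- list()
    for (i in 1:5) {
      cfg <- scenario_config(seed = condition_seed(base_seed, "scenario", i))
      series <- generate_scenario(cfg, sensors = FALSE)
      series <- inject_gap(series, 2021, drift = c(pH = 0.05, conductivity = 0.5))
      w <- to_weekly(series)
      sp <- split_spec()
      g <- scan_grid(neurons = 1:5, replicates = 3,
                     base_seed = condition_seed(base_seed, "scan", i))
      res <- run_scan(g, w, sp, control = fnn_control(maxit = 120))
      sel <- select_closed_systems(res, top_k = 1)
      top <- sel$systems[[1]]
      bn <- summary(res)
      bp_key <- paste(g$candidates, collapse = "+")
      sp_model <- scan_best_model(res, character(0))
      ev <- evaluate_models(list(SP = sp_model, CS = top$model), w, sp,
                            res$normalizer)
      pick <- function(m, p, f)
        ev$r2[ev$method == m & ev$period == p & ev$factor == f]
      rows[[i]] <- data.frame(
        scenario = i,
        top_system = top$key,
        top_passes = top$passes_property,
        temp_in_top = "temperature" %in% top$subset,
        pair_rank = which(bn$subset == "temperature+pH"),
        cs_val_r2 = top$val_r2,
        bp_val_r2 = bn$val_r2[bn$subset == bp_key],
        cs_app_algae_r2 = pick("CS", "application", "algae"),
        sp_app_algae_r2 = pick("SP", "application", "algae"))
    }
    cache <<- do.call(rbind, rows)
    cache
  }
})
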