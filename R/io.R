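#' Read and write long-format observation tables
#'
#' Observations are exchanged as tab-separated text with columns
#' `timestamp` (ISO-8601, UTC), `factor`, `value`, `unit`, `cadence`.
#'
#' @param series an `observation_series`.
#' @param path file path.
#' @export
write_observations <- function(series, path) {
  stopifnot(inherits(series, "observation_series"))
  out <- series
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  class(df) <- c("observation_series", "data.frame")
  df
}

#' Read and write scenario configurations as YAML
#'
#' @param config a [scenario_config()].
#' @param path file path.
#' @export
write_scenario_config <- function(config, path) {
  stopifnot(inherits(config, "scenario_config"))
  lst <- unclass(config)
  lst$sensor_noise_sd <- as.list(lst$sensor_noise_sd) # keep names in YAML map
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_scenario_config
#' @export
read_scenario_config <- function(path) {
  lst <- yaml::yaml.load_file(path)
  lst$sensor_noise_sd <- unlist(lst$sensor_noise_sd)
  cfg <- do.call(scenario_config, lst)
  cfg
}

#' Serialize an alkalinity-conductivity fit or a report to JSON
#'
#' @param x an `alk_cond_fit`, `evaluation_report`, or any list-like result.
#' @param path file path.
#' @export
write_report_json <- function(x, path) {
  if (inherits(x, "alk_cond_fit"))
    x <- x[c("slope", "intercept", "residual_sd", "n_pairs", "max_pairing_gap")]
  jsonlite::write_json(x, path, digits = NA, auto_unbox = TRUE, na = "null",
                       dataframe = "rows")
  invisible(path)
}

#' Write a scan ledger as delimited text
#'
#' @param result a `scan_result`.
#' @param path CSV file path.
#' @export
write_scan_ledger <- function(result, path) {
  stopifnot(inherits(result, "scan_result"))
  utils::write.csv(result$ledger, path, row.names = FALSE)
  invisible(path)
}
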