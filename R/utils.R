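#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic condition seed
#'
#' Folds a base seed and a character key into a 31-bit integer suitable for
#' `set.seed()`. Used so every (subset, neuron count, replicate) training in a
#' scan has its own reproducible seed, which also makes scans resumable.
#'
#' @param base_seed integer base seed.
#' @param ... character or numeric key components (e.g. subset name, neuron
#'   count, replicate index).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
condition_seed <- function(base_seed, ...) {
  key <- paste(vapply(list(...), function(x) paste(as.character(x), collapse = ","),
                      character(1)), collapse = "|")
  m <- 2147483629 # prime < 2^31
  h <- as.numeric(base_seed) %% m
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% m
  as.integer(h + 1)
}

# Monday (ISO weekday 1) of the ISO week containing each date
iso_monday <- function(dates) {
  d <- as.Date(dates)
  d - (as.integer(format(d, "%u")) - 1L)
}

# first Monday of a calendar year
first_monday <- function(year) {
  d <- as.Date(sprintf("%d-01-01", year))
  d + (8L - as.integer(format(d, "%u"))) %% 7L
}

stop_names <- function(missing, where) {
  stop(sprintf("missing required factor(s) in %s: %s", where,
               paste(missing, collapse = ", ")), call. = FALSE)
}
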