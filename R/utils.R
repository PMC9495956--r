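# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and labels
#'
#' A single master seed expands deterministically into independent-looking
#' substreams for each (station, model, scenario, stage) combination, so every
#' stochastic output can record the exact seed that produced it.
#'
#' @param master integer master seed.
#' @param ... character or numeric labels identifying the substream.
#' @return An integer seed in \code{[0, 2^31 - 2]}.
#' @export
substream_seed <- function(master, ...) {
  labels <- unlist(lapply(list(...), as.character))
  h <- as.double(master) %% 2147483647
  for (lab in labels) {
    for (code in utf8ToInt(lab)) {
      h <- (h * 31 + code) %% 2147483647
    }
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

days_in_month <- function(year, month) {
  stopifnot(all(month >= 1), all(month <= 12))
  base <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  base[month] + ifelse(month == 2 & leap, 1, 0)
}

# saturation vapour pressure (kPa) at air temperature T (degC), Tetens form
svp <- function(temp) 0.6108 * exp(17.27 * temp / (temp + 237.3))

`%||%` <- function(a, b) if (is.null(a)) b else a
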