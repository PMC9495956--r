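# Yearly atmospheric CO2 concentration trajectories per SSP scenario,
# evaluated from editable coefficient configurations (a small term library:
# constants, shifted linear terms and shifted powers), with plausibility
# validation of every configured trajectory.

co2_scenarios <- c("SSP126", "SSP245", "SSP370", "SSP585")

#' CO2 curve coefficient set
#'
#' A scenario's yearly CO2 curve is the sum of configured terms, each of the
#' form \code{coef * (year - center)^degree} (degree 0 gives a constant).
#' Coefficient sets normally come from the shipped YAML configuration (see
#' [default_co2_coefficients]), which users may edit; every edited set must
#' still pass [build_trajectory] validation.
#'
#' @param scenario one of SSP126, SSP245, SSP370, SSP585 (or any label).
#' @param terms list of lists with elements \code{coef}, \code{center}
#'   (default 0) and \code{degree} (default 1).
#' @param year_range integer vector \code{c(first, last)} of valid years.
#' @return An object of class \code{co2_coefficients}.
#' @export
co2_coefficients <- function(scenario, terms, year_range = c(1981L, 2070L)) {
  stopifnot(is.list(terms), length(terms) >= 1)
  terms <- lapply(terms, function(t) {
    t$center <- t$center %||% 0
    t$degree <- t$degree %||% 1
    if (!is.finite(t$coef) || !is.finite(t$center) || !is.finite(t$degree))
      stop("CO2 curve term has non-finite coefficient", call. = FALSE)
    t
  })
  structure(list(scenario = scenario, terms = terms,
                 year_range = as.integer(year_range)),
            class = "co2_coefficients")
}

#' Evaluate a scenario CO2 curve at given years
#'
#' Pure, deterministic evaluation of the configured curve.
#'
#' @param coeffs a [co2_coefficients] object.
#' @param year integer year(s) within the coefficient set's valid range.
#' @return CO2 concentration(s) in ppm.
#' @export
co2_for_year <- function(coeffs, year) {
  stopifnot(inherits(coeffs, "co2_coefficients"))
  if (any(year < coeffs$year_range[1]) || any(year > coeffs$year_range[2]))
    stop(sprintf("year outside valid range [%d, %d]",
                 coeffs$year_range[1], coeffs$year_range[2]), call. = FALSE)
  out <- numeric(length(year))
  for (t in coeffs$terms) out <- out + t$coef * (year - t$center)^t$degree
  out
}

#' Build and validate a yearly CO2 trajectory
#'
#' Evaluates the curve for every year in the valid range and validates the
#' result against a plausibility envelope. A value outside the envelope is a
#' configuration error naming the offending year.
#'
#' @param coeffs a [co2_coefficients] object.
#' @param envelope allowed ppm range, default \code{c(300, 1200)}.
#' @return An object of class \code{co2_trajectory}: data frame with columns
#'   \code{year} and \code{ppm}.
#' @export
build_trajectory <- function(coeffs, envelope = c(300, 1200)) {
  years <- seq(coeffs$year_range[1], coeffs$year_range[2])
  ppm <- co2_for_year(coeffs, years)
  bad <- which(ppm < envelope[1] | ppm > envelope[2] | !is.finite(ppm))
  if (length(bad))
    stop(sprintf("implausible CO2 value %.1f ppm in year %d for %s",
                 ppm[bad[1]], years[bad[1]], coeffs$scenario), call. = FALSE)
  structure(data.frame(year = years, ppm = ppm),
            scenario = coeffs$scenario,
            class = c("co2_trajectory", "data.frame"))
}

#' Shipped CO2 curve coefficients for the four SSP scenarios
#'
#' Reads the packaged YAML configuration. The shipped defaults are a
#' documented reconstruction (see the methods vignette): the shifted
#' polynomial and linear terms of the published empirical curves are kept
#' verbatim, and each curve's ambiguous leading terms are represented by a
#' constant anchoring all four scenarios at 340 ppm in 1981.
#'
#' @param path optional path to an alternative YAML configuration.
#' @return Named list of [co2_coefficients], one per scenario.
#' @export
default_co2_coefficients <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "co2_coefficients.yaml", package = "rotaclim")
  cfg <- yaml::read_yaml(path)
  out <- lapply(names(cfg), function(sc) {
    terms <- lapply(cfg[[sc]]$terms, function(t)
      list(coef = as.numeric(t$coef), center = as.numeric(t$center %||% 0),
           degree = as.numeric(t$degree %||% 1)))
    co2_coefficients(sc, terms,
                     year_range = as.integer(cfg[[sc]]$year_range %||% c(1981, 2070)))
  })
  names(out) <- names(cfg)
  out
}

#' Export a trajectory as two-column CSV
#'
#' @param trajectory a \code{co2_trajectory}.
#' @param path file path.
#' @export
write_co2_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory)[c("year", "ppm")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.co2_trajectory <- function(x, ...) {
  cat(sprintf("CO2 trajectory %s: %d-%d, %.1f -> %.1f ppm\n",
              attr(x, "scenario"), min(x$year), max(x$year),
              x$ppm[1], x$ppm[nrow(x)]))
  invisible(x)
}
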