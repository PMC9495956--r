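# Core weather data model: station metadata, daily series, solar geometry,
# Angstrom-Prescott radiation, monthly aggregation and growth-period summaries.

#' Station metadata
#'
#' @param station_id short identifier.
#' @param name station name.
#' @param latitude decimal degrees, in \code{[-90, 90]}.
#' @param longitude decimal degrees.
#' @param elevation metres above sea level.
#' @return An object of class \code{station_meta}.
#' @export
station_meta <- function(station_id, name = station_id, latitude, longitude,
                         elevation = 0) {
  if (!is.finite(latitude) || abs(latitude) > 90)
    stop("latitude must be within [-90, 90]", call. = FALSE)
  if (!is.finite(elevation)) stop("elevation must be finite", call. = FALSE)
  structure(list(station_id = as.character(station_id), name = as.character(name),
                 latitude = latitude, longitude = longitude,
                 elevation = elevation),
            class = "station_meta")
}

#' @export
print.station_meta <- function(x, ...) {
  cat(sprintf("Station %s (%s): %.2f N, %.2f E, %.0f m\n",
              x$station_id, x$name, x$latitude, x$longitude, x$elevation))
  invisible(x)
}

#' Angstrom-Prescott coefficients
#'
#' Coefficients of the linear relation between the atmospheric transmissivity
#' ratio Rad/Ra and relative sunshine duration n/N. \code{a} is the
#' transmissivity on a fully overcast day, \code{a + b} on a clear day.
#'
#' @param a intercept, dimensionless, > 0.
#' @param b slope, dimensionless, > 0; \code{a + b <= 1}.
#' @return An object of class \code{angstrom_coefficients}.
#' @export
angstrom_coefficients <- function(a = 0.25, b = 0.50) {
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("Angstrom-Prescott coefficients must be positive and finite", call. = FALSE)
  if (a + b > 1 + 1e-9)
    stop("Angstrom-Prescott coefficients must satisfy a + b <= 1", call. = FALSE)
  structure(list(a = a, b = b), class = "angstrom_coefficients")
}

#' Extraterrestrial radiation
#'
#' Daily extraterrestrial (top-of-atmosphere) solar radiation from latitude
#' and day of year, using the standard FAO-56 solar-geometry convention
#' (solar constant 0.0820 MJ m-2 min-1, sinusoidal declination and
#' inverse-distance factors, sunset hour angle clamped for polar day/night).
#'
#' @param latitude decimal degrees in \code{[-90, 90]}.
#' @param day_of_year integer in \code{[1, 366]}.
#' @return Extraterrestrial radiation in MJ m-2 d-1 (>= 0). Vectorised.
#' @export
extraterrestrial_radiation <- function(latitude, day_of_year) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("latitude must be within [-90, 90]", call. = FALSE)
  if (any(day_of_year < 1) || any(day_of_year > 366))
    stop("day_of_year must be in [1, 366]", call. = FALSE)
  gsc <- 0.0820                            # MJ m-2 min-1
  phi <- latitude * pi / 180
  j <- day_of_year
  dr <- 1 + 0.033 * cos(2 * pi * j / 365)
  delta <- 0.409 * sin(2 * pi * j / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  ra <- (24 * 60 / pi) * gsc * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
  pmax(ra, 0)
}

#' Theoretical day length
#'
#' Maximum possible sunshine duration from the sunset hour angle.
#'
#' @inheritParams extraterrestrial_radiation
#' @return Day length in hours, in \code{[0, 24]}. Vectorised.
#' @export
day_length <- function(latitude, day_of_year) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90))
    stop("latitude must be within [-90, 90]", call. = FALSE)
  if (any(day_of_year < 1) || any(day_of_year > 366))
    stop("day_of_year must be in [1, 366]", call. = FALSE)
  phi <- latitude * pi / 180
  delta <- 0.409 * sin(2 * pi * day_of_year / 365 - 1.39)
  ws <- acos(clamp(-tan(phi) * tan(delta), -1, 1))
  24 * ws / pi
}

#' Solar radiation from sunshine duration (Angstrom-Prescott)
#'
#' Rad = (a + b n/N) Ra. With N = 0 (polar night) n is forced to zero and the
#' overcast term a Ra is returned.
#'
#' @param n actual sunshine hours, \code{0 <= n <= N}.
#' @param N theoretical day length in hours.
#' @param coeffs an [angstrom_coefficients] object.
#' @param Ra extraterrestrial radiation, MJ m-2 d-1.
#' @return Surface solar radiation in MJ m-2 d-1. Vectorised.
#' @export
angstrom_prescott <- function(n, N, coeffs = angstrom_coefficients(), Ra) {
  if (any(Ra < 0)) stop("Ra must be >= 0", call. = FALSE)
  if (any(n < 0)) stop("sunshine hours must be >= 0", call. = FALSE)
  if (any(n > N + 1e-9)) stop("sunshine hours n exceed day length N", call. = FALSE)
  ratio <- ifelse(N <= 0, 0, n / pmax(N, .Machine$double.eps))
  (coeffs$a + coeffs$b * ratio) * Ra
}

#' Calibrate Angstrom-Prescott coefficients from observed radiation
#'
#' Ordinary least squares of the transmissivity ratio rad_obs/Ra on relative
#' sunshine n/N.
#'
#' @param observed data frame with columns \code{n}, \code{N}, \code{Ra},
#'   \code{rad_obs}.
#' @return An [angstrom_coefficients] object with the fit stored in
#'   attribute \code{"fit"}.
#' @export
calibrate_angstrom <- function(observed) {
  stopifnot(is.data.frame(observed),
            all(c("n", "N", "Ra", "rad_obs") %in% names(observed)))
  ratio <- observed$n / observed$N
  trans <- observed$rad_obs / observed$Ra
  if (length(unique(round(ratio, 12))) < 2)
    stop("all n/N ratios identical: singular fit", call. = FALSE)
  fit <- stats::lm(trans ~ ratio)
  out <- angstrom_coefficients(a = unname(stats::coef(fit)[1]),
                               b = unname(stats::coef(fit)[2]))
  attr(out, "fit") <- fit
  out
}

#' Construct and validate a daily weather series
#'
#' @param station a [station_meta] object.
#' @param records data frame with columns \code{date} (Date), \code{tmax},
#'   \code{tmin} (degC), \code{prec} (mm d-1) and optionally \code{sh}
#'   (sunshine hours) and \code{rad} (MJ m-2 d-1).
#' @param validate check the series invariants (contiguous dates,
#'   \code{tmax >= tmin}, non-negative precipitation, sunshine within day
#'   length, non-negative radiation).
#' @return An object of class \code{daily_series} (a data frame with the
#'   station stored as an attribute).
#' @export
daily_series <- function(station, records, validate = TRUE) {
  stopifnot(inherits(station, "station_meta"), is.data.frame(records))
  need <- c("date", "tmax", "tmin", "prec")
  if (!all(need %in% names(records)))
    stop("records must have columns date, tmax, tmin, prec", call. = FALSE)
  if (!inherits(records$date, "Date")) records$date <- as.Date(records$date)
  if (is.null(records$sh)) records$sh <- NA_real_
  if (is.null(records$rad)) records$rad <- NA_real_
  records <- records[c("date", "tmax", "tmin", "prec", "sh", "rad")]
  out <- structure(records, station = station,
                   class = c("daily_series", "data.frame"))
  if (validate) validate_daily_series(out)
  out
}

#' @rdname daily_series
#' @param x a \code{daily_series}.
#' @export
validate_daily_series <- function(x) {
  stopifnot(inherits(x, "daily_series"))
  d <- as.integer(diff(x$date))
  if (length(d) && any(d != 1L))
    stop("dates must be strictly increasing by one day with no gaps", call. = FALSE)
  if (any(x$tmax < x$tmin)) stop("tmax < tmin in daily series", call. = FALSE)
  if (any(x$prec < 0)) stop("negative precipitation", call. = FALSE)
  has_sh <- !is.na(x$sh)
  if (any(has_sh)) {
    doy <- as.integer(strftime(x$date[has_sh], "%j"))
    N <- day_length(attr(x, "station")$latitude, doy)
    if (any(x$sh[has_sh] < 0 | x$sh[has_sh] > N + 1e-6))
      stop("sunshine hours outside [0, day length]", call. = FALSE)
  }
  if (any(!is.na(x$rad) & x$rad < 0)) stop("negative radiation", call. = FALSE)
  invisible(x)
}

#' @export
print.daily_series <- function(x, ...) {
  st <- attr(x, "station")
  cat(sprintf("Daily weather series: %s, %d days (%s to %s)\n",
              st$station_id, nrow(x), format(min(x$date)), format(max(x$date))))
  invisible(x)
}

#' Derived daily mean temperature
#'
#' Tmean is the arithmetic midpoint (tmax + tmin)/2, the standard
#' agro-meteorological convention.
#'
#' @param x a \code{daily_series} or data frame with tmax/tmin.
#' @return Numeric vector of daily mean temperatures (degC).
#' @export
tmean <- function(x) (x$tmax + x$tmin) / 2

#' Aggregate a daily series to calendar months
#'
#' Partial months at either end of the series are excluded. Precipitation is
#' summed; temperatures and radiation are arithmetic means over the days of
#' the month.
#'
#' @param series a \code{daily_series}.
#' @return A \code{monthly_series}: data frame with columns \code{year},
#'   \code{month}, \code{tmax_mean}, \code{tmin_mean}, \code{prec_total},
#'   \code{rad_mean}; station kept as an attribute.
#' @export
aggregate_monthly <- function(series) {
  stopifnot(inherits(series, "daily_series"))
  yr <- as.integer(strftime(series$date, "%Y"))
  mo <- as.integer(strftime(series$date, "%m"))
  key <- yr * 100L + mo
  n_days <- tapply(key, key, length)
  full <- names(n_days)[n_days == days_in_month(as.integer(names(n_days)) %/% 100L,
                                                as.integer(names(n_days)) %% 100L)]
  keep <- key %in% as.integer(full)
  if (!any(keep)) stop("series contains no complete month", call. = FALSE)
  f <- factor(key[keep], levels = sort(unique(key[keep])))
  out <- data.frame(
    year = as.integer(levels(f)) %/% 100L,
    month = as.integer(levels(f)) %% 100L,
    tmax_mean = as.numeric(tapply(series$tmax[keep], f, mean)),
    tmin_mean = as.numeric(tapply(series$tmin[keep], f, mean)),
    prec_total = as.numeric(tapply(series$prec[keep], f, sum)),
    rad_mean = as.numeric(tapply(series$rad[keep], f, mean)),
    row.names = NULL
  )
  structure(out, station = attr(series, "station"),
            class = c("monthly_series", "data.frame"))
}

# Label each day of a series with its growth season (harvest year) for a
# (start month/day, end month/day) window; NA outside the window. Windows may
# span the calendar year boundary (e.g. wheat Oct 15 - May 31).
season_labels <- function(dates, start, end) {
  mo <- as.integer(strftime(dates, "%m"))
  dy <- as.integer(strftime(dates, "%d"))
  yr <- as.integer(strftime(dates, "%Y"))
  md <- mo * 100L + dy
  s <- start[1] * 100L + start[2]
  e <- end[1] * 100L + end[2]
  if (s <= e) {
    inside <- md >= s & md <= e
    ifelse(inside, yr, NA_integer_)
  } else {
    inside <- md >= s | md <= e
    ifelse(inside, ifelse(md >= s, yr + 1L, yr), NA_integer_)
  }
}

# expected number of days in a full season window harvested in year y
season_window_days <- function(harvest_year, start, end) {
  s <- start[1] * 100L + start[2]
  e <- end[1] * 100L + end[2]
  if (s <= e) {
    first <- as.Date(sprintf("%04d-%02d-%02d", harvest_year, start[1], start[2]))
  } else {
    first <- as.Date(sprintf("%04d-%02d-%02d", harvest_year - 1L, start[1], start[2]))
  }
  last <- as.Date(sprintf("%04d-%02d-%02d", harvest_year, end[1], end[2]))
  as.integer(last - first) + 1L
}

#' Growth-period climate summary
#'
#' Summarises a daily series over a crop growth window: per season the mean
#' daily maximum/minimum temperature, total precipitation and mean daily
#' radiation are computed over all days inside the window, then averaged over
#' seasons. Only seasons fully covered by the series are used. Windows
#' spanning the year boundary (wheat) are labelled by harvest year.
#'
#' @param series a \code{daily_series}.
#' @param start,end \code{c(month, day)} window bounds (inclusive).
#' @param crop label, e.g. "wheat" or "rice".
#' @return An object of class \code{growth_period_summary}.
#' @export
growth_period_summary <- function(series, start, end, crop = "crop") {
  stopifnot(inherits(series, "daily_series"), length(start) == 2, length(end) == 2)
  if (start[1] == end[1] && start[2] == end[2])
    stop("degenerate growth window: start equals end", call. = FALSE)
  lab <- season_labels(series$date, start, end)
  if (all(is.na(lab))) stop("no days fall inside the growth window", call. = FALSE)
  keep <- !is.na(lab)
  f <- factor(lab[keep])
  counts <- tapply(rep(1L, sum(keep)), f, sum)
  expect <- vapply(as.integer(levels(f)), season_window_days,
                   integer(1), start = start, end = end)
  full <- levels(f)[counts == expect]
  if (!length(full)) stop("no season is fully covered by the series", call. = FALSE)
  use <- keep & lab %in% as.integer(full)
  g <- factor(lab[use])
  per_season <- data.frame(
    season = as.integer(levels(g)),
    tmax_mean = as.numeric(tapply(series$tmax[use], g, mean)),
    tmin_mean = as.numeric(tapply(series$tmin[use], g, mean)),
    prec_total = as.numeric(tapply(series$prec[use], g, sum)),
    rad_mean = as.numeric(tapply(series$rad[use], g, mean))
  )
  structure(list(crop = crop, n_seasons = nrow(per_season),
                 tmax_mean = mean(per_season$tmax_mean),
                 tmin_mean = mean(per_season$tmin_mean),
                 prec_total = mean(per_season$prec_total),
                 rad_mean = mean(per_season$rad_mean),
                 per_season = per_season),
            class = "growth_period_summary")
}

#' @export
print.growth_period_summary <- function(x, ...) {
  cat(sprintf(
    "%s growth period (%d seasons): Tmax %.1f degC, Tmin %.1f degC, Prec %.1f mm, Rad %.1f MJ m-2 d-1\n",
    x$crop, x$n_seasons, x$tmax_mean, x$tmin_mean, x$prec_total, x$rad_mean))
  invisible(x)
}
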