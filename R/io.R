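# Reading and writing daily weather in CSV and APSIM-met-style text formats.

#' Write / read daily weather as CSV
#'
#' Column layout: \code{station_id, date, tmax, tmin, prec, sh, rad} with
#' ISO-8601 dates. On read, when \code{rad} is missing but sunshine hours are
#' present and Angstrom-Prescott coefficients are supplied, radiation is
#' reconstructed from sunshine duration.
#'
#' @param series a \code{daily_series}.
#' @param path file path.
#' @export
write_daily_csv <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  st <- attr(series, "station")
  df <- data.frame(station_id = st$station_id,
                   date = format(series$date, "%Y-%m-%d"),
                   tmax = series$tmax, tmin = series$tmin, prec = series$prec,
                   sh = series$sh, rad = series$rad)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_daily_csv
#' @param station a [station_meta] for the series (latitude is needed to
#'   reconstruct radiation from sunshine hours).
#' @param coeffs optional [angstrom_coefficients] used to fill missing
#'   radiation from sunshine hours on load.
#' @export
read_daily_csv <- function(path, station, coeffs = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$date <- as.Date(df$date)
  if (!is.null(coeffs)) {
    fill <- is.na(df$rad) & !is.na(df$sh)
    if (any(fill)) {
      doy <- as.integer(strftime(df$date[fill], "%j"))
      ra <- extraterrestrial_radiation(station$latitude, doy)
      N <- day_length(station$latitude, doy)
      df$rad[fill] <- angstrom_prescott(pmin(df$sh[fill], N), N, coeffs, ra)
    }
  }
  daily_series(station, df[c("date", "tmax", "tmin", "prec", "sh", "rad")])
}

#' Write / read daily weather in APSIM met format
#'
#' Plain-text met layout: comment header with station coordinates, a
#' \code{year day radn maxt mint rain} column line, a units line, then
#' whitespace-separated values.
#'
#' @inheritParams write_daily_csv
#' @export
write_met <- function(series, path) {
  stopifnot(inherits(series, "daily_series"))
  st <- attr(series, "station")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("!station = %s (%s)", st$station_id, st$name),
    sprintf("latitude = %.4f  (DECIMALDEGREES)", st$latitude),
    sprintf("longitude = %.4f  (DECIMALDEGREES)", st$longitude),
    "year  day  radn  maxt  mint  rain",
    "  ()   ()  (MJ/m^2)  (oC)  (oC)  (mm)"), con)
  yr <- as.integer(strftime(series$date, "%Y"))
  doy <- as.integer(strftime(series$date, "%j"))
  writeLines(sprintf("%4d %4d %8.3f %7.2f %7.2f %8.3f",
                     yr, doy, series$rad, series$tmax, series$tmin, series$prec),
             con)
  invisible(path)
}

#' @rdname write_met
#' @export
read_met <- function(path, station = NULL) {
  lines <- readLines(path)
  lat <- NA_real_; lon <- NA_real_; sid <- "met"
  hdr <- grep("^year\\s+day", lines)
  if (!length(hdr)) stop("not an APSIM met file: no 'year day' header", call. = FALSE)
  for (l in lines[seq_len(hdr - 1)]) {
    if (grepl("^latitude", l)) lat <- as.numeric(sub("^latitude\\s*=\\s*([-0-9.]+).*", "\\1", l))
    if (grepl("^longitude", l)) lon <- as.numeric(sub("^longitude\\s*=\\s*([-0-9.]+).*", "\\1", l))
    if (grepl("^!station", l)) sid <- sub("^!station\\s*=\\s*(\\S+).*", "\\1", l)
  }
  dat <- utils::read.table(text = lines[-seq_len(hdr + 1)],
                           col.names = c("year", "day", "radn", "maxt", "mint", "rain"))
  if (is.null(station)) station <- station_meta(sid, latitude = lat, longitude = lon)
  dates <- as.Date(sprintf("%d-01-01", dat$year)) + (dat$day - 1)
  daily_series(station, data.frame(date = dates, tmax = dat$maxt, tmin = dat$mint,
                                   prec = dat$rain, sh = NA_real_, rad = dat$radn))
}
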