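# Shared fixtures and independent mini-oracles used across test files.

test_station <- function(lat = 31.87, lon = 117.23) {
  station_meta("test", "Test station", lat, lon, 30)
}

# constant-weather daily series over whole years
const_series <- function(years = 2001, tmax = 20, tmin = 10, prec = 0,
                         rad = 12, station = test_station()) {
  dates <- seq(as.Date(sprintf("%d-01-01", years[1])),
               as.Date(sprintf("%d-12-31", years[length(years)])), by = "day")
  daily_series(station, data.frame(date = dates, tmax = tmax, tmin = tmin,
                                   prec = prec, sh = NA_real_, rad = rad))
}

# independently coded type-7 empirical quantile (sort-and-index oracle)
quantile7_oracle <- function(x, p) {
  s <- sort(x); n <- length(s)
  vapply(p, function(pp) {
    h <- (n - 1) * pp + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }, numeric(1))
}

# shift a whole daily series by a temperature offset / radiation factor
perturb_series <- function(series, dt = 0, rad_factor = 1) {
  df <- as.data.frame(series)
  df$tmax <- df$tmax + dt; df$tmin <- df$tmin + dt
  df$rad <- df$rad * rad_factor
  daily_series(attr(series, "station"), df)
}

# small fixed-weather fixture shared by the crop directional tests
crop_fixture_series <- function(years = 8, seed = 301) {
  clim <- default_station_climatology("hefei")
  generate_station_baseline(clim, test_station(), years, seed = seed,
                            start_year = 2001)
}
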