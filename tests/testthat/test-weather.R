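# Solar geometry, Angstrom-Prescott radiation, aggregation and
# growth-period summaries.

test_that("extraterrestrial radiation matches solar geometry", {
  # equinox symmetry at the equator
  expect_equal(extraterrestrial_radiation(0, 80),
               extraterrestrial_radiation(0, 266), tolerance = 0.02)
  # polar night
  expect_equal(extraterrestrial_radiation(90, 355), 0)
  # independent oracle: numerical integration of the cosine of the solar
  # zenith angle over the day (minute steps), same declination convention
  ra_oracle <- function(lat, doy) {
    phi <- lat * pi / 180
    dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
    delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
    omega <- seq(-pi, pi, length.out = 24 * 60 + 1)[-1]  # hour angle per minute
    cosz <- sin(phi) * sin(delta) + cos(phi) * cos(delta) * cos(omega)
    0.0820 * dr * sum(pmax(cosz, 0)) * (24 * 60 / length(omega))
  }
  for (case in list(c(32, 172), c(34, 1), c(0, 80), c(-45, 200), c(60, 300))) {
    expect_equal(extraterrestrial_radiation(case[1], case[2]),
                 ra_oracle(case[1], case[2]), tolerance = 1e-4)
  }
  expect_error(extraterrestrial_radiation(91, 100), "latitude")
  expect_error(extraterrestrial_radiation(40, 0), "day_of_year")
})

test_that("day length covers equatorial, polar and oracle cases", {
  expect_equal(day_length(0, 80), 12, tolerance = 0.1 / 12)
  expect_equal(day_length(0, 200), 12, tolerance = 0.1 / 12)
  expect_equal(day_length(90, 172), 24)
  expect_equal(day_length(90, 355), 0)
  # sunset-hour-angle oracle coded directly
  dl_oracle <- function(lat, doy) {
    delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
    x <- -tan(lat * pi / 180) * tan(delta)
    (24 / pi) * acos(min(max(x, -1), 1))
  }
  for (case in list(c(34, 1), c(32, 172), c(-20, 40)))
    expect_equal(day_length(case[1], case[2]), dl_oracle(case[1], case[2]),
                 tolerance = 1e-10)
})

test_that("Angstrom-Prescott identities and monotonicity hold", {
  cf <- angstrom_coefficients(0.25, 0.50)
  expect_equal(angstrom_prescott(12, 12, cf, 30), 22.5)
  expect_equal(angstrom_prescott(0, 12, cf, 40), 10.0)
  expect_equal(angstrom_prescott(6, 12, angstrom_coefficients(0.20, 0.50), 20),
               9.0)
  # polar night: N = 0 handled as overcast
  expect_equal(angstrom_prescott(0, 0, cf, 5), 0.25 * 5)
  expect_error(angstrom_prescott(13, 12, cf, 30), "exceed")
  # monotone nondecreasing in n, a, b, Ra
  base <- angstrom_prescott(6, 12, cf, 25)
  expect_gte(angstrom_prescott(8, 12, cf, 25), base)
  expect_gte(angstrom_prescott(6, 12, angstrom_coefficients(0.30, 0.50), 25), base)
  expect_gte(angstrom_prescott(6, 12, angstrom_coefficients(0.25, 0.60), 25), base)
  expect_gte(angstrom_prescott(6, 12, cf, 30), base)
  # coefficient invariants
  expect_error(angstrom_coefficients(-0.1, 0.5), "positive")
  expect_error(angstrom_coefficients(0.6, 0.5), "a \\+ b")
})

test_that("coefficient calibration recovers known transmissivity lines", {
  N <- 12
  n <- seq(0, 12, length.out = 24)
  Ra <- rep(30, 24)
  obs <- data.frame(n = n, N = N, Ra = Ra,
                    rad_obs = (0.25 + 0.50 * n / N) * Ra)
  cf <- calibrate_angstrom(obs)
  expect_equal(cf$a, 0.25, tolerance = 1e-10)
  expect_equal(cf$b, 0.50, tolerance = 1e-10)
  # two points determine the line exactly
  cf2 <- calibrate_angstrom(obs[c(1, 24), ])
  expect_equal(cf2$a, 0.25, tolerance = 1e-10)
  expect_equal(cf2$b, 0.50, tolerance = 1e-10)
  # noisy recovery: 360 points, transmissivity noise sd 0.02
  set.seed(11)
  n360 <- runif(360, 0, 12)
  trans <- 0.25 + 0.50 * n360 / N + rnorm(360, 0, 0.02)
  noisy <- data.frame(n = n360, N = N, Ra = 30, rad_obs = trans * 30)
  cfn <- calibrate_angstrom(noisy)
  expect_lt(abs(cfn$a - 0.25), 0.01)
  expect_lt(abs(cfn$b - 0.50), 0.01)
  # degenerate: identical ratios
  expect_error(calibrate_angstrom(obs[rep(3, 12), ]), "singular")
})

test_that("daily series enforce their invariants", {
  st <- test_station()
  good <- const_series(2001, station = st)
  expect_s3_class(good, "daily_series")
  df <- as.data.frame(good)
  expect_error(daily_series(st, df[-5, ]), "one day")
  bad <- df; bad$tmin[10] <- bad$tmax[10] + 1
  expect_error(daily_series(st, bad), "tmax")
  bad <- df; bad$prec[3] <- -1
  expect_error(daily_series(st, bad), "precipitation")
  bad <- df; bad$sh[100] <- 23
  expect_error(daily_series(st, bad), "sunshine")
  # derived Tmean always lies within [tmin, tmax]
  ser <- crop_fixture_series(years = 2)
  tm <- tmean(ser)
  expect_true(all(tm >= ser$tmin & tm <= ser$tmax))
})

test_that("monthly aggregation sums, averages and conserves precipitation", {
  st <- test_station()
  dates <- seq(as.Date("2001-04-01"), as.Date("2001-04-30"), by = "day")
  ser <- daily_series(st, data.frame(date = dates, tmax = 20, tmin = 10,
                                     prec = 1, rad = 12))
  m <- aggregate_monthly(ser)
  expect_equal(m$prec_total, 30)
  expect_equal(m$tmax_mean, 20)
  # partial months are excluded
  ser2 <- daily_series(st, data.frame(date = seq(as.Date("2001-04-15"),
                                                 as.Date("2001-06-30"), "day"),
                                      tmax = 20, tmin = 10, prec = 0, rad = 12))
  expect_equal(aggregate_monthly(ser2)$month, c(5, 6))
  # mixed synthetic month vs brute-force oracle, plus conservation over a year
  ser3 <- crop_fixture_series(years = 1)
  m3 <- aggregate_monthly(ser3)
  mo <- as.integer(strftime(ser3$date, "%m"))
  for (mm in c(1, 6, 12)) {
    expect_equal(m3$prec_total[m3$month == mm], sum(ser3$prec[mo == mm]))
    expect_equal(m3$tmax_mean[m3$month == mm], mean(ser3$tmax[mo == mm]))
    expect_equal(m3$rad_mean[m3$month == mm], mean(ser3$rad[mo == mm]))
  }
  expect_equal(sum(m3$prec_total), sum(ser3$prec))
})

test_that("growth-period summaries match day-by-day enumeration", {
  ser <- const_series(2001:2003, tmax = 21, tmin = 9, prec = 2, rad = 13)
  gs <- growth_period_summary(ser, c(1, 1), c(12, 31), "year")
  expect_equal(gs$tmax_mean, 21)
  expect_equal(gs$prec_total, 365 * 2)
  # wheat window spanning the year boundary, against explicit enumeration
  ser2 <- crop_fixture_series(years = 3)
  gw <- growth_period_summary(ser2, c(10, 15), c(5, 31), "wheat")
  md <- as.integer(strftime(ser2$date, "%m")) * 100 +
    as.integer(strftime(ser2$date, "%d"))
  yr <- as.integer(strftime(ser2$date, "%Y"))
  seasons <- lapply(2002:2003, function(h) {
    inside <- (yr == h - 1 & md >= 1015) | (yr == h & md <= 531)
    list(tmax = mean(ser2$tmax[inside]), prec = sum(ser2$prec[inside]),
         rad = mean(ser2$rad[inside]))
  })
  expect_equal(gw$n_seasons, 2)
  expect_equal(gw$tmax_mean, mean(vapply(seasons, `[[`, 1, "tmax")))
  expect_equal(gw$prec_total, mean(vapply(seasons, `[[`, 1, "prec")))
  expect_equal(gw$rad_mean, mean(vapply(seasons, `[[`, 1, "rad")))
  expect_error(growth_period_summary(ser, c(3, 1), c(3, 1)), "degenerate")
})

test_that("CSV and met round trips preserve the series", {
  ser <- crop_fixture_series(years = 1)
  st <- attr(ser, "station")
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".met")
  write_daily_csv(ser, f1)
  back <- read_daily_csv(f1, st)
  expect_equal(back$tmax, ser$tmax, tolerance = 1e-12)
  expect_equal(back$prec, ser$prec, tolerance = 1e-12)
  expect_equal(back$date, ser$date)
  write_met(ser, f2)
  back2 <- read_met(f2)
  expect_equal(back2$rad, ser$rad, tolerance = 1e-3)
  expect_equal(attr(back2, "station")$latitude, st$latitude, tolerance = 1e-4)
  # radiation reconstructed from sunshine hours on load
  df <- as.data.frame(ser)
  doy <- as.integer(strftime(df$date, "%j"))
  N <- day_length(st$latitude, doy)
  cf <- angstrom_coefficients(0.25, 0.5)
  ra <- extraterrestrial_radiation(st$latitude, doy)
  df$sh <- pmin(N * pmax(df$rad / ra - 0.25, 0) / 0.5, N)
  df$rad <- NA_real_
  f3 <- tempfile(fileext = ".csv")
  write_daily_csv(daily_series(st, df), f3)
  filled <- read_daily_csv(f3, st, coeffs = cf)
  expect_true(all(is.finite(filled$rad)))
  expect_equal(filled$rad, angstrom_prescott(df$sh, N, cf, ra),
               tolerance = 1e-6)
})
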