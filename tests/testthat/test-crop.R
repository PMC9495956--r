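# Thermal time, development factors, CO2 modifiers, potential ET, the soil
# water bucket, and the season/rotation simulators.

wheat <- default_wheat_params()
rice <- default_rice_params()

test_that("thermal time follows the triangular response", {
  expect_equal(daily_thermal_time(0, 0, wheat), 0)          # Tmean = Tbase
  expect_equal(daily_thermal_time(26, 26, wheat), 26)       # peak at Topt
  expect_equal(daily_thermal_time(40, 40, wheat), 0)        # above Tupper
  # between Topt and Tupper: linear interpolation oracle
  tm <- 30
  oracle <- (wheat$topt - wheat$tbase) *
    (wheat$tupper - tm) / (wheat$tupper - wheat$topt)
  expect_equal(daily_thermal_time(30, 30, wheat), oracle)
  # monotone rise below Topt
  expect_true(all(diff(daily_thermal_time(seq(2, 26, 2), seq(2, 26, 2),
                                          wheat)) > 0))
  expect_error(crop_params("x", 10, 5, 20, 1, 1, 1, rue = 1), "cardinal")
})

test_that("vernalization and photoperiod factors follow their accrual rules", {
  norm <- crop_params("w", 0, 26, 34, 100, 900, 600, rue = 1, vern_req = 40)
  expect_equal(vernalization_factor(0, rice), 1)       # requirement zero
  expect_equal(vernalization_factor(40, norm), 1)      # saturated
  expect_equal(vernalization_factor(20, norm), 0.5)    # linear accrual
  expect_equal(vernalization_factor(60, norm), 1)
  pp <- crop_params("w", 0, 26, 34, 100, 900, 600, rue = 1,
                    photoperiod_sens = 0.1, photoperiod_crit = 13)
  expect_equal(photoperiod_factor(13, pp), 1)
  expect_equal(photoperiod_factor(10, pp), 0.7)
  expect_true(all(diff(photoperiod_factor(seq(8, 16, 0.5), pp)) >= 0))
  expect_equal(photoperiod_factor(9, rice), 1)         # insensitive crop
})

test_that("CO2 modifiers are normalised at 350 ppm and monotone", {
  expect_equal(co2_rue_modifier(350, wheat), 1)
  expect_equal(co2_te_modifier(350, wheat), 1)
  slope7 <- crop_params("w", 0, 26, 34, 100, 900, 600, rue = 1,
                        co2_rue_slope = 7e-4, co2_rue_cap = 2)
  expect_equal(co2_rue_modifier(700, slope7), 1.245)
  grid <- seq(300, 1200, 10)
  expect_true(all(diff(co2_rue_modifier(grid, wheat)) >= 0))
  expect_true(all(diff(co2_te_modifier(grid, wheat)) >= 0))
  # rue response is capped
  expect_equal(co2_rue_modifier(5000, wheat), wheat$co2_rue_cap)
})

test_that("potential ET is zero without energy and matches the PT oracle", {
  expect_equal(potential_et(0, 25, 15), 0)
  expect_equal(potential_et(30, 25, 15), 2 * potential_et(15, 25, 15))
  # independently coded Priestley-Taylor computation
  pt_oracle <- function(rad, tmax, tmin, kc) {
    tm <- (tmax + tmin) / 2
    es <- 0.6108 * exp(17.27 * tm / (tm + 237.3))
    slope <- 4098 * es / (tm + 237.3)^2
    1.26 * slope / (slope + 0.066) * 0.75 * rad / 2.45 * kc
  }
  expect_equal(potential_et(15, 25, 15, 1), pt_oracle(15, 25, 15, 1),
               tolerance = 1e-12)
  expect_equal(potential_et(8, 10, 2, 1.15), pt_oracle(8, 10, 2, 1.15),
               tolerance = 1e-12)
})

test_that("the soil bucket conserves water and honours supply limits", {
  soil <- soil_params(pawc = 150, soil_evap_coeff = 1)
  # empty soil, no rain: no ET
  dry <- step_water_balance(list(storage = 0), 0, 0, 5, 0.5, soil)
  expect_equal(dry$aet, 0)
  # saturated soil with default canopy demand: ET equals potential ET
  sat <- step_water_balance(list(storage = 150), 0, 0, 5, 0.5, soil)
  expect_equal(sat$aet, 5, tolerance = 1e-12)
  # 120-day random season: cumulative mass balance closes below 1e-6 mm
  set.seed(4)
  state <- list(storage = 100)
  inflow <- 0; outflow <- 0
  for (i in 1:120) {
    prec <- rexp(1, 1 / 4) * (runif(1) < 0.4)
    irr <- if (i %% 7 == 0) 10 else 0
    pet <- runif(1, 1, 6); cover <- runif(1)
    wb <- step_water_balance(state, prec, irr, pet, cover, soil,
                             transp_demand = runif(1, 0, 4))
    inflow <- inflow + prec + irr
    outflow <- outflow + wb$aet + wb$drainage + wb$runoff
    expect_gte(wb$transp, 0); expect_gte(wb$aet, wb$transp)
    state <- wb$state
  }
  expect_lt(abs(inflow - outflow - (state$storage - 100)), 1e-6)
})

test_that("a season without radiation produces no biomass or yield", {
  ser <- crop_fixture_series(years = 2)
  df <- as.data.frame(ser); df$rad <- 0
  dark <- daily_series(attr(ser, "station"), df)
  seg <- df$date >= as.Date("2001-06-18") & df$date <= as.Date("2001-11-30")
  res <- simulate_crop(daily_series(attr(ser, "station"), df[seg, ]),
                       380, rice, irrigated = TRUE)
  expect_false(res$failed)
  expect_equal(res$biomass, 0)
  expect_equal(res$yield, 0)
})

test_that("single-factor responses have the expected directions", {
  ser <- crop_fixture_series(years = 8)
  base <- simulate_rotation(ser, 380)
  ok <- function(r, cr) r$seasons[r$seasons$crop == cr & !r$seasons$failed, ]
  doy <- function(d) mean(as.integer(strftime(d, "%j")))

  # +2 degC: wheat flowering and maturity advance; yields fall
  warm <- simulate_rotation(perturb_series(ser, dt = 2), 380)
  expect_lt(doy(ok(warm, "wheat")$fd), doy(ok(base, "wheat")$fd))
  expect_lt(doy(ok(warm, "wheat")$md), doy(ok(base, "wheat")$md))
  expect_lt(mean(ok(warm, "wheat")$yield), mean(ok(base, "wheat")$yield))
  expect_lt(mean(ok(warm, "rice")$yield), mean(ok(base, "rice")$yield))

  # CO2 550 vs 380 ppm: higher yield, lower ET, both crops
  high <- simulate_rotation(ser, 550)
  for (cr in c("wheat", "rice")) {
    expect_gt(mean(ok(high, cr)$yield), mean(ok(base, cr)$yield))
    expect_lt(mean(ok(high, cr)$et), mean(ok(base, cr)$et))
  }

  # +10% radiation: higher yield and higher ET
  bright <- simulate_rotation(perturb_series(ser, rad_factor = 1.1), 380)
  for (cr in c("wheat", "rice")) {
    expect_gt(mean(ok(bright, cr)$yield), mean(ok(base, cr)$yield))
    expect_gt(mean(ok(bright, cr)$et), mean(ok(base, cr)$et))
  }

  # structural invariants on every simulated season
  sv <- base$seasons[!base$seasons$failed, ]
  expect_true(all(sv$yield <= sv$biomass))
  expect_true(all(sv$yield >= 0))
  expect_true(all(sv$et >= sv$transpiration))
  expect_true(all(abs(sv$wue * sv$et - sv$yield) < 1e-6))
  expect_true(all(sv$md > sv$fd & sv$fd > sv$sowing))
  expect_true(all(abs(sv$balance_residual) < 1e-6))
  # harvest index never exceeds its cap
  expect_true(all(sv$yield / sv$biomass <= pmax(wheat$hi_cap, rice$hi_cap)))
  # irrigated rice never experiences water stress
  expect_true(all(ok(base, "rice")$min_stress == 1))
})

test_that("a truncated season is flagged failed and excluded from totals", {
  ser <- crop_fixture_series(years = 1)
  df <- as.data.frame(ser)
  seg <- df$date >= as.Date("2001-06-18") & df$date <= as.Date("2001-07-20")
  res <- simulate_crop(daily_series(attr(ser, "station"), df[seg, ]),
                       380, rice, irrigated = TRUE)
  expect_true(res$failed)
  expect_true(is.na(res$yield))
})

test_that("the rotation reaches a steady annual cycle on repeating weather", {
  st <- test_station()
  clim <- default_station_climatology("hefei")
  z <- clim
  z$months$tmax_sd[] <- 0; z$months$tmin_sd[] <- 0; z$months$rad_sd[] <- 0
  z$months$tmax_wet_offset[] <- 0; z$months$tmin_wet_offset[] <- 0
  z$months$rad_wet_offset[] <- 0
  mo_means <- z$months
  dates <- seq(as.Date("2001-01-01"), as.Date("2003-12-31"), by = "day")
  mo <- as.integer(strftime(dates, "%m"))
  det <- daily_series(st, data.frame(
    date = dates, tmax = mo_means$tmax_mean[mo], tmin = mo_means$tmin_mean[mo],
    prec = 3, sh = NA_real_, rad = mo_means$rad_mean[mo]))
  rot <- simulate_rotation(det, 380)
  ric <- rot$seasons[rot$seasons$crop == "rice" & !rot$seasons$failed, ]
  whe <- rot$seasons[rot$seasons$crop == "wheat" & !rot$seasons$failed, ]
  # identical seasons after the spin-up year
  expect_equal(ric$yield[2], ric$yield[3], tolerance = 1e-9)
  expect_equal(ric$et[2], ric$et[3], tolerance = 1e-9)
  expect_equal(whe$yield[1], whe$yield[2], tolerance = 1e-9)
  # annual totals are sums of the two crops, and WUE x ET = yield
  ann <- rot$annual
  for (i in seq_len(nrow(ann))) {
    y <- ann$season[i]
    sub <- rot$seasons[rot$seasons$season == y & !rot$seasons$failed, ]
    expect_equal(ann$yield[i], sum(sub$yield))
    expect_equal(ann$et[i], sum(sub$et))
    expect_equal(ann$wue[i] * ann$et[i], ann$yield[i], tolerance = 1e-9)
  }
})
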