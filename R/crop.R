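# Simplified process-based rice-wheat rotation simulator: thermal-time
# phenology (with vernalization and photoperiod for wheat), radiation-use-
# efficiency biomass accumulation with CO2 and water-stress modifiers,
# transpiration from a transpiration-efficiency/VPD relation with a CO2
# stomatal response, a single-bucket soil water balance, and harvest-index
# yield formation with a reproductive-period heat-stress penalty.

#' Crop parameter set
#'
#' @param name "wheat" or "rice" (any label accepted).
#' @param tbase,topt,tupper cardinal temperatures (degC), \code{tbase < topt
#'   < tupper}; development follows a triangular response of daily mean
#'   temperature.
#' @param tt_emerge,tt_flower,tt_grainfill thermal-time targets (degC d) for
#'   sowing to emergence, emergence to flowering, flowering to maturity.
#' @param photoperiod_sens photoperiod sensitivity (h-1); 0 disables.
#' @param photoperiod_crit critical day length (h).
#' @param vern_req vernalization requirement (days within the effective
#'   band); 0 disables.
#' @param vern_band effective temperature band \code{c(lo, hi)} (degC).
#' @param rue radiation-use efficiency (g biomass per MJ intercepted).
#' @param k_ext canopy extinction coefficient.
#' @param max_cover maximum fractional light interception.
#' @param lai_max leaf-area-index ceiling used for cover development.
#' @param hi_rate harvest-index accrual rate (d-1) during the reproductive
#'   period.
#' @param hi_cap harvest-index ceiling, in (0, 1).
#' @param te_coeff transpiration-efficiency coefficient
#'   (g kPa m-2 mm-1), normalised at 350 ppm CO2.
#' @param co2_rue_slope linear RUE response to CO2 (ppm-1) above 350 ppm.
#' @param co2_rue_cap ceiling of the RUE multiplier.
#' @param co2_te_slope linear transpiration-efficiency response to CO2
#'   (ppm-1) above 350 ppm (stomatal-conductance proxy).
#' @param heat_threshold daily Tmax (degC) above which reproductive-period
#'   heat stress accrues.
#' @param heat_penalty grain-set penalty per degree-day above the threshold.
#' @param kc crop coefficient scaling potential ET.
#' @return An object of class \code{crop_params}.
#' @export
crop_params <- function(name, tbase, topt, tupper,
                        tt_emerge, tt_flower, tt_grainfill,
                        photoperiod_sens = 0, photoperiod_crit = 13,
                        vern_req = 0, vern_band = c(0, 10),
                        rue, k_ext = 0.55, max_cover = 0.95, lai_max = 6,
                        hi_rate = 0.012, hi_cap = 0.48,
                        te_coeff = 5, co2_rue_slope = 7e-4, co2_rue_cap = 1.35,
                        co2_te_slope = 1.2e-3,
                        heat_threshold = 30, heat_penalty = 0.004, kc = 1) {
  if (!(tbase < topt && topt < tupper))
    stop("cardinal temperatures must satisfy tbase < topt < tupper", call. = FALSE)
  if (rue <= 0 || te_coeff <= 0)
    stop("efficiencies must be > 0", call. = FALSE)
  if (hi_cap <= 0 || hi_cap >= 1)
    stop("harvest-index cap must lie in (0, 1)", call. = FALSE)
  structure(as.list(environment()), class = "crop_params")
}

#' Default wheat and rice parameter sets
#'
#' Cardinal temperatures typical of winter wheat (0/26/34 degC) and paddy
#' rice (8/30/42 degC); thermal-time targets, efficiencies and stress
#' parameters chosen to reproduce plausible phenology, yield (6-8 t ha-1) and
#' seasonal ET for a humid-subtropical rice-wheat rotation. Fully
#' configurable; see the methods vignette for rationale.
#'
#' @name default_crop_params
#' @export
default_wheat_params <- function() {
  crop_params("wheat", tbase = 0, topt = 26, tupper = 34,
              tt_emerge = 120, tt_flower = 950, tt_grainfill = 600,
              photoperiod_sens = 0.08, photoperiod_crit = 13,
              vern_req = 35, vern_band = c(0, 10),
              rue = 1.25, k_ext = 0.55, max_cover = 0.95, lai_max = 6,
              hi_rate = 0.012, hi_cap = 0.48,
              te_coeff = 5.0, heat_threshold = 30, heat_penalty = 0.004,
              kc = 1.0)
}

#' @rdname default_crop_params
#' @export
default_rice_params <- function() {
  crop_params("rice", tbase = 8, topt = 30, tupper = 42,
              tt_emerge = 60, tt_flower = 1150, tt_grainfill = 520,
              photoperiod_sens = 0, vern_req = 0,
              rue = 1.4, k_ext = 0.6, max_cover = 0.95, lai_max = 6.5,
              hi_rate = 0.013, hi_cap = 0.50,
              te_coeff = 4.0, heat_threshold = 35, heat_penalty = 0.008,
              kc = 1.15)
}

#' Soil bucket parameters
#'
#' @param pawc plant-available water capacity (mm).
#' @param init_fraction initial storage as a fraction of capacity.
#' @param drain_coef fraction of above-capacity water drained per day.
#' @param soil_evap_coeff fraction of potential ET evaporated from the
#'   uncovered soil fraction.
#' @param runoff_threshold daily precipitation (mm) above which excess runs
#'   off.
#' @param uptake_rate fraction of stored water extractable by the crop per
#'   day (transpiration supply).
#' @return An object of class \code{soil_params}.
#' @export
soil_params <- function(pawc = 150, init_fraction = 0.8, drain_coef = 0.5,
                        soil_evap_coeff = 0.7, runoff_threshold = 50,
                        uptake_rate = 0.13) {
  if (pawc < 0) stop("capacity must be >= 0", call. = FALSE)
  if (any(c(init_fraction, drain_coef, soil_evap_coeff, uptake_rate) < 0) ||
      any(c(init_fraction, drain_coef, soil_evap_coeff, uptake_rate) > 1))
    stop("soil coefficients must lie in [0, 1]", call. = FALSE)
  structure(as.list(environment()), class = "soil_params")
}

#' Rotation management parameters
#'
#' Wheat is rain-fed and sown in mid/late October; rice is transplanted in
#' mid June under a continuous-flood proxy (the soil bucket is refilled to
#' capacity daily).
#'
#' @param wheat_sowing \code{c(month, day)} wheat sowing date.
#' @param rice_sowing \code{c(month, day)} rice transplanting date.
#' @param rice_irrigated logical; daily refill irrigation for rice.
#' @param wheat_window,rice_window growth-period windows
#'   (\code{list(start = c(m, d), end = c(m, d))}) used for climate
#'   summaries.
#' @return An object of class \code{management_params}.
#' @export
management_params <- function(wheat_sowing = c(10L, 20L),
                              rice_sowing = c(6L, 18L),
                              rice_irrigated = TRUE,
                              wheat_window = list(start = c(10L, 15L),
                                                  end = c(5L, 31L)),
                              rice_window = list(start = c(6L, 15L),
                                                 end = c(10L, 5L))) {
  structure(as.list(environment()), class = "management_params")
}

#' Daily thermal time
#'
#' Triangular response on daily mean temperature: zero at or below
#' \code{tbase}, rising linearly to \code{topt - tbase} at \code{topt},
#' falling linearly to zero at \code{tupper}.
#'
#' @param tmax,tmin daily extremes (degC).
#' @param crop a [crop_params] (only the cardinals are used).
#' @return Thermal time (degC d). Vectorised.
#' @export
daily_thermal_time <- function(tmax, tmin, crop) {
  tm <- (tmax + tmin) / 2
  peak <- crop$topt - crop$tbase
  up <- (tm - crop$tbase)
  down <- peak * (crop$tupper - tm) / (crop$tupper - crop$topt)
  ifelse(tm <= crop$tbase | tm >= crop$tupper, 0,
         ifelse(tm <= crop$topt, up, pmax(down, 0)))
}

#' Vernalization and photoperiod development factors
#'
#' Vernal days accrue (one per day) while the daily mean temperature lies in
#' the effective band; the factor is the fulfilled fraction of the
#' requirement, saturating at one (a crop with requirement zero is always
#' fully vernalized). The photoperiod factor increases linearly with day
#' length below the critical photoperiod, clamped to \code{[0, 1]}.
#'
#' @param vern_days vernal days accumulated so far.
#' @param crop a [crop_params].
#' @return Multiplier in \code{[0, 1]}.
#' @export
vernalization_factor <- function(vern_days, crop) {
  if (crop$vern_req <= 0) return(rep(1, length(vern_days)))
  clamp(vern_days / crop$vern_req, 0, 1)
}

#' @rdname vernalization_factor
#' @param day_len day length (h).
#' @export
photoperiod_factor <- function(day_len, crop) {
  if (crop$photoperiod_sens <= 0) return(rep(1, length(day_len)))
  clamp(1 - crop$photoperiod_sens * (crop$photoperiod_crit - day_len), 0, 1)
}

#' CO2 response multipliers
#'
#' Both equal one at the 350 ppm reference. The RUE multiplier rises
#' linearly with CO2 (C3 fertilization), capped; the transpiration-
#' efficiency multiplier rises linearly (reduced stomatal conductance), so
#' transpiration per unit biomass falls as CO2 rises.
#'
#' @param co2_ppm atmospheric CO2 (ppm).
#' @param crop a [crop_params].
#' @return Multiplier (>= 0). Vectorised.
#' @export
co2_rue_modifier <- function(co2_ppm, crop) {
  pmin(1 + crop$co2_rue_slope * (co2_ppm - 350), crop$co2_rue_cap)
}

#' @rdname co2_rue_modifier
#' @export
co2_te_modifier <- function(co2_ppm, crop) {
  pmax(1 + crop$co2_te_slope * (co2_ppm - 350), 0.1)
}

#' Potential evapotranspiration (Priestley-Taylor form)
#'
#' alpha * slope/(slope + gamma) * net-radiation proxy / lambda, scaled by
#' the crop coefficient. The net-radiation proxy is 0.75 of incoming solar
#' radiation; slope is the saturation-vapour-pressure slope at the daily
#' mean temperature.
#'
#' @param rad solar radiation (MJ m-2 d-1).
#' @param tmax,tmin daily extremes (degC).
#' @param kc crop coefficient.
#' @return Potential ET (mm d-1, >= 0). Vectorised.
#' @export
potential_et <- function(rad, tmax, tmin, kc = 1) {
  tm <- (tmax + tmin) / 2
  delta <- 4098 * svp(tm) / (tm + 237.3)^2   # kPa / degC
  gamma <- 0.066
  alpha <- 1.26
  lambda <- 2.45                              # MJ / kg
  pmax(alpha * delta / (delta + gamma) * (0.75 * rad) / lambda * kc, 0)
}

#' One day of the bucket soil water balance
#'
#' Mass balance closes exactly:
#' prec + irrigation = runoff + drainage + transpiration + soil evaporation
#' + change in storage. Transpiration is the demand limited by the supply
#' function (uptake_rate times current storage); soil evaporation comes from
#' the uncovered fraction and cannot exceed the remaining storage.
#'
#' @param state list with element \code{storage} (mm).
#' @param prec precipitation (mm).
#' @param irrigation applied irrigation (mm).
#' @param pet potential ET (mm).
#' @param cover fractional canopy light interception in \code{[0, 1]}.
#' @param soil a [soil_params].
#' @param transp_demand transpiration demand (mm); defaults to
#'   \code{pet * cover}.
#' @return List with \code{state}, \code{aet}, \code{transp},
#'   \code{soil_evap}, \code{drainage}, \code{runoff}.
#' @export
step_water_balance <- function(state, prec, irrigation, pet, cover, soil,
                               transp_demand = pet * cover) {
  storage <- state$storage
  runoff <- max(0, prec - soil$runoff_threshold)
  storage <- storage + (prec - runoff) + irrigation
  drainage <- soil$drain_coef * max(0, storage - soil$pawc)
  storage <- storage - drainage
  supply <- soil$uptake_rate * storage
  transp <- min(max(transp_demand, 0), supply)
  storage <- storage - transp
  soil_evap <- min(soil$soil_evap_coeff * pet * (1 - cover), storage)
  soil_evap <- max(soil_evap, 0)
  storage <- storage - soil_evap
  list(state = list(storage = storage), aet = transp + soil_evap,
       transp = transp, soil_evap = soil_evap,
       drainage = drainage, runoff = runoff)
}

#' Simulate one crop season
#'
#' Daily loop from sowing (the first day of \code{weather}) to maturity:
#' thermal-time phenology modulated by vernalization and photoperiod, canopy
#' cover development, RUE biomass growth with CO2 fertilization and water
#' stress, transpiration from the TE/VPD relation with the CO2 stomatal
#' response bounded by soil supply, harvest-index accrual during the
#' reproductive period with a heat-stress penalty on degree-days above the
#' threshold.
#'
#' @param weather a \code{daily_series} segment starting at sowing and
#'   covering the whole season.
#' @param co2_ppm atmospheric CO2 for the season (ppm).
#' @param crop a [crop_params].
#' @param soil a [soil_params].
#' @param irrigated daily refill irrigation (rice flooding proxy).
#' @param init_storage initial soil storage (mm); defaults to
#'   \code{init_fraction * pawc}.
#' @return An object of class \code{crop_sim_result}; \code{failed = TRUE}
#'   (with the other fields NA) when maturity is not reached before the
#'   segment ends.
#' @export
simulate_crop <- function(weather, co2_ppm, crop, soil = soil_params(),
                          irrigated = FALSE, init_storage = NULL) {
  stopifnot(inherits(weather, "daily_series"), inherits(crop, "crop_params"))
  station <- attr(weather, "station")
  n <- nrow(weather)
  doy <- as.integer(strftime(weather$date, "%j"))
  dl <- day_length(station$latitude, pmin(doy, 366L))
  tt <- daily_thermal_time(weather$tmax, weather$tmin, crop)
  tm <- tmean(weather)
  vpd <- pmax(0.75 * (svp(weather$tmax) - svp(weather$tmin)), 0.05)
  pet <- potential_et(weather$rad, weather$tmax, weather$tmin, crop$kc)
  rue_mod <- co2_rue_modifier(co2_ppm, crop)
  te_mod <- co2_te_modifier(co2_ppm, crop)

  storage <- init_storage %||% (soil$init_fraction * soil$pawc)
  stage <- 0L          # 0 sown, 1 vegetative, 2 reproductive, 3 mature
  tt_acc <- 0; vern_days <- 0
  biomass <- 0; hi <- 0; hdd <- 0
  et_sum <- 0; transp_sum <- 0; irr_sum <- 0
  in_balance <- 0; out_balance <- 0
  fd <- NA; md <- NA
  min_stress <- 1

  for (i in seq_len(n)) {
    if (stage == 0L) {
      tt_acc <- tt_acc + tt[i]
      if (tt_acc >= crop$tt_emerge) { stage <- 1L; tt_acc <- 0 }
    } else if (stage == 1L) {
      if (crop$vern_req > 0 && tm[i] >= crop$vern_band[1] &&
          tm[i] <= crop$vern_band[2]) vern_days <- vern_days + 1
      vf <- vernalization_factor(vern_days, crop)
      pf <- photoperiod_factor(dl[i], crop)
      tt_acc <- tt_acc + tt[i] * vf * pf
      if (tt_acc >= crop$tt_flower) { stage <- 2L; tt_acc <- 0; fd <- weather$date[i] }
    } else if (stage == 2L) {
      tt_acc <- tt_acc + tt[i]
      hi <- min(crop$hi_cap, hi + crop$hi_rate)
      hdd <- hdd + max(0, weather$tmax[i] - crop$heat_threshold)
      if (tt_acc >= crop$tt_grainfill) { stage <- 3L; md <- weather$date[i] }
    }

    # canopy cover
    if (stage >= 1L && stage < 3L) {
      if (stage == 1L) {
        lai <- crop$lai_max * min(1, tt_acc / (0.65 * crop$tt_flower))
      } else {
        lai <- crop$lai_max * (1 - 0.5 * min(1, tt_acc / crop$tt_grainfill))
      }
      cover <- crop$max_cover * (1 - exp(-crop$k_ext * lai))
    } else cover <- 0

    irr <- if (irrigated) max(0, soil$pawc - storage) else 0
    db_pot <- weather$rad[i] * cover * crop$rue * rue_mod      # g m-2
    demand <- db_pot * vpd[i] / (crop$te_coeff * te_mod)       # mm
    wb <- step_water_balance(list(storage = storage), weather$prec[i], irr,
                             pet[i], cover, soil, transp_demand = demand)
    stress <- if (demand > 1e-12) wb$transp / demand else 1
    if (stage >= 1L && stage < 3L) min_stress <- min(min_stress, stress)
    biomass <- biomass + db_pot * stress
    storage <- wb$state$storage
    et_sum <- et_sum + wb$aet
    transp_sum <- transp_sum + wb$transp
    irr_sum <- irr_sum + irr
    in_balance <- in_balance + weather$prec[i] + irr
    out_balance <- out_balance + wb$aet + wb$drainage + wb$runoff

    if (stage == 3L) break
  }

  failed <- stage < 3L
  init <- init_storage %||% (soil$init_fraction * soil$pawc)
  residual <- in_balance - out_balance - (storage - init)
  biomass_kgha <- biomass * 10
  heat_factor <- max(0.2, 1 - crop$heat_penalty * hdd)
  yield <- if (failed) NA_real_ else min(biomass_kgha * hi * heat_factor,
                                         biomass_kgha)
  structure(list(
    crop = crop$name, sowing = weather$date[1],
    fd = fd, md = md,
    rgp = if (failed) NA_real_ else as.numeric(md - fd),
    yield = yield, biomass = biomass_kgha,
    et = et_sum, transpiration = transp_sum, irrigation = irr_sum,
    wue = if (failed || et_sum <= 0) NA_real_ else yield / et_sum,
    failed = failed, final_storage = storage,
    balance_residual = residual, min_stress = min_stress,
    heat_dd = hdd, harvest_index = hi, heat_factor = heat_factor),
    class = "crop_sim_result")
}

#' @export
print.crop_sim_result <- function(x, ...) {
  if (x$failed) {
    cat(sprintf("%s season sown %s: FAILED (maturity not reached)\n",
                x$crop, format(x$sowing)))
  } else {
    cat(sprintf(
      "%s sown %s: FD %s, MD %s, RGP %.0f d, yield %.0f kg/ha, ET %.0f mm, WUE %.1f kg/ha/mm\n",
      x$crop, format(x$sowing), format(x$fd), format(x$md), x$rgp,
      x$yield, x$et, x$wue))
  }
  invisible(x)
}

# advance the bare-soil bucket over fallow days; returns storage
run_fallow <- function(weather, idx, storage, soil) {
  for (i in idx) {
    pet <- potential_et(weather$rad[i], weather$tmax[i], weather$tmin[i], 1)
    wb <- step_water_balance(list(storage = storage), weather$prec[i], 0,
                             pet, 0, soil, transp_demand = 0)
    storage <- wb$state$storage
  }
  storage
}

#' Simulate the rice-wheat rotation over a multi-year series
#'
#' Alternates rice (transplanted mid June, flood-irrigated) and wheat (sown
#' mid/late October, rain-fed) per the rotation calendar; the soil water
#' state carries across seasons and fallow periods. Wheat seasons are
#' labelled by harvest year. Annual totals (per harvest year with both crops)
#' sum yield and ET, with total WUE = total yield / total ET.
#'
#' @param weather a multi-year \code{daily_series}.
#' @param co2_by_year named numeric vector (names = years, values = ppm), or
#'   a single number used for all years.
#' @param wheat,rice [crop_params] for the two crops.
#' @param soil a [soil_params].
#' @param mgmt a [management_params].
#' @return A list of class \code{rotation_result} with \code{seasons}
#'   (data frame, one row per season) and \code{annual} (data frame of
#'   harvest-year totals).
#' @export
simulate_rotation <- function(weather, co2_by_year,
                              wheat = default_wheat_params(),
                              rice = default_rice_params(),
                              soil = soil_params(),
                              mgmt = management_params()) {
  stopifnot(inherits(weather, "daily_series"))
  years <- sort(unique(as.integer(strftime(weather$date, "%Y"))))
  co2_of <- function(y) {
    if (length(co2_by_year) == 1 && is.null(names(co2_by_year)))
      return(as.numeric(co2_by_year))
    v <- co2_by_year[as.character(y)]
    if (is.na(v)) stop(sprintf("no CO2 value for year %d", y), call. = FALSE)
    as.numeric(v)
  }
  mk_date <- function(y, md) as.Date(sprintf("%04d-%02d-%02d", y, md[1], md[2]))
  station <- attr(weather, "station")
  segment <- function(from, to) {
    idx <- weather$date >= from & weather$date <= to
    daily_series(station, as.data.frame(weather)[idx, ], validate = FALSE)
  }

  storage <- soil$init_fraction * soil$pawc
  cursor <- weather$date[1]
  rows <- list()
  for (y in years) {
    # rice season of year y
    rs <- mk_date(y, mgmt$rice_sowing)
    re <- min(mk_date(y, c(11L, 30L)), max(weather$date))
    if (rs >= cursor && re > rs + 60) {
      storage <- run_fallow(weather, which(weather$date >= cursor &
                                             weather$date < rs), storage, soil)
      res <- simulate_crop(segment(rs, re), co2_of(y), rice, soil,
                           irrigated = mgmt$rice_irrigated,
                           init_storage = storage)
      storage <- res$final_storage
      cursor <- if (res$failed) re + 1 else res$md + 1
      rows[[length(rows) + 1]] <- c(list(season = y), unclass(res))
    }
    # wheat season sown in year y, harvested year y + 1
    ws <- mk_date(y, mgmt$wheat_sowing)
    we <- min(mk_date(y + 1, c(7L, 15L)), max(weather$date))
    if (ws >= cursor && we > ws + 150) {
      storage <- run_fallow(weather, which(weather$date >= cursor &
                                             weather$date < ws), storage, soil)
      res <- simulate_crop(segment(ws, we), co2_of(y + 1), wheat, soil,
                           irrigated = FALSE, init_storage = storage)
      storage <- res$final_storage
      cursor <- if (res$failed) we + 1 else res$md + 1
      rows[[length(rows) + 1]] <- c(list(season = y + 1), unclass(res))
    }
  }
  seasons <- do.call(rbind, lapply(rows, function(r)
    data.frame(season = r$season, crop = r$crop,
               sowing = r$sowing, fd = r$fd %||% as.Date(NA),
               md = r$md %||% as.Date(NA),
               rgp = r$rgp, yield = r$yield, biomass = r$biomass,
               et = r$et, transpiration = r$transpiration,
               irrigation = r$irrigation, wue = r$wue, failed = r$failed,
               balance_residual = r$balance_residual,
               min_stress = r$min_stress)))
  ok <- seasons[!seasons$failed, ]
  both <- intersect(ok$season[ok$crop == "rice"], ok$season[ok$crop == "wheat"])
  annual <- do.call(rbind, lapply(both, function(y) {
    sub <- ok[ok$season == y, ]
    data.frame(season = y, yield = sum(sub$yield), et = sum(sub$et),
               wue = sum(sub$yield) / sum(sub$et))
  }))
  structure(list(seasons = seasons, annual = annual),
            class = "rotation_result")
}

#' @export
print.rotation_result <- function(x, ...) {
  ok <- x$seasons[!x$seasons$failed, ]
  for (cr in unique(ok$crop)) {
    sub <- ok[ok$crop == cr, ]
    cat(sprintf("%s: %d seasons, mean yield %.0f kg/ha, mean ET %.0f mm, mean WUE %.1f\n",
                cr, nrow(sub), mean(sub$yield), mean(sub$et), mean(sub$wue)))
  }
  if (any(x$seasons$failed))
    cat(sprintf("failed seasons: %d\n", sum(x$seasons$failed)))
  invisible(x)
}
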