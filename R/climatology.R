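# Monthly climatology model and stochastic daily weather generation
# (Richardson-type WGEN: first-order two-state Markov precipitation
# occurrence, gamma wet-day amounts, lag-1 autoregressive cross-correlated
# temperature/radiation residuals with wet/dry conditional shifts).

#' Monthly climatology model for stochastic weather generation
#'
#' @param months data frame with 12 rows (calendar months) and columns
#'   \code{tmax_mean}, \code{tmin_mean}, \code{tmax_sd}, \code{tmin_sd},
#'   \code{rad_mean}, \code{rad_sd} (all-day monthly moments),
#'   \code{p01} (wet given dry), \code{p11} (wet given wet),
#'   \code{gamma_shape}, \code{gamma_scale} (wet-day amount distribution, mm;
#'   NA when a month has no wet days), and wet-minus-dry contrasts
#'   \code{tmax_wet_offset}, \code{tmin_wet_offset}, \code{rad_wet_offset}.
#'   Contrasts are applied mean-preservingly, so the stated monthly means are
#'   marginal means regardless of wet-day frequency.
#' @param ar1 named numeric length-3 lag-1 autocorrelations of the
#'   standardised tmax/tmin/rad residuals.
#' @param cross_cor 3x3 cross-correlation matrix of residual innovations.
#' @param trace minimum wet-day amount (mm), default 0.1.
#' @return An object of class \code{climatology}.
#' @export
climatology <- function(months, ar1 = c(tmax = 0.6, tmin = 0.55, rad = 0.3),
                        cross_cor = default_cross_cor(), trace = 0.1) {
  need <- c("tmax_mean", "tmin_mean", "tmax_sd", "tmin_sd", "rad_mean", "rad_sd",
            "p01", "p11", "gamma_shape", "gamma_scale",
            "tmax_wet_offset", "tmin_wet_offset", "rad_wet_offset")
  stopifnot(is.data.frame(months), nrow(months) == 12, all(need %in% names(months)))
  with(months, {
    if (any(p01 < 0 | p01 > 1 | p11 < 0 | p11 > 1, na.rm = TRUE))
      stop("transition probabilities must lie in [0, 1]", call. = FALSE)
    if (any(c(tmax_sd, tmin_sd, rad_sd) < 0))
      stop("standard deviations must be >= 0", call. = FALSE)
    if (any(gamma_shape <= 0 | gamma_scale <= 0, na.rm = TRUE))
      stop("gamma parameters must be > 0", call. = FALSE)
    if (any(tmax_mean < tmin_mean))
      stop("monthly tmax_mean below tmin_mean", call. = FALSE)
  })
  ev <- eigen(cross_cor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-8)) stop("cross_cor is not positive semi-definite", call. = FALSE)
  structure(list(months = months, ar1 = ar1, cross_cor = cross_cor, trace = trace),
            class = "climatology")
}

default_cross_cor <- function() {
  m <- matrix(c(1, 0.7, 0.45,
                0.7, 1, 0.15,
                0.45, 0.15, 1), 3, 3,
              dimnames = list(c("tmax", "tmin", "rad"), c("tmax", "tmin", "rad")))
  m
}

#' @export
print.climatology <- function(x, ...) {
  cat(sprintf("Monthly climatology: Tmax %.1f..%.1f degC, annual prec ~%.0f mm\n",
              min(x$months$tmax_mean), max(x$months$tmax_mean),
              sum(expected_month_prec(x))))
  invisible(x)
}

# expected monthly precipitation totals implied by the chain and amounts
expected_month_prec <- function(clim) {
  m <- clim$months
  pw <- ifelse(is.na(m$p01) | is.na(m$p11), 0,
               m$p01 / pmax(1 + m$p01 - m$p11, 1e-12))
  amt <- ifelse(is.na(m$gamma_shape), 0, m$gamma_shape * m$gamma_scale)
  pw * days_in_month(2001, 1:12) * amt
}

#' Fit a monthly climatology from a daily series
#'
#' Estimates, per calendar month: marginal moments of tmax/tmin/rad, wet/dry
#' transition frequencies of the precipitation occurrence chain, gamma
#' wet-day amount parameters by method of moments, wet-minus-dry conditional
#' offsets, and (pooled over months) lag-1 autocorrelations and the residual
#' cross-correlation matrix.
#'
#' Degenerate months: with no wet days the gamma parameters are recorded as
#' NA and generation produces dry days only; with all days wet \code{p01} is
#' undefined and recorded as 1.
#'
#' @param series a \code{daily_series}.
#' @param trace wet-day threshold (mm): days with \code{prec >= trace} count
#'   as wet.
#' @return A \code{climatology} object.
#' @export
fit_climatology <- function(series, trace = 0.1) {
  stopifnot(inherits(series, "daily_series"))
  mo <- as.integer(strftime(series$date, "%m"))
  wet <- series$prec >= trace
  n <- nrow(series)
  prev_wet <- c(NA, wet[-n])
  rows <- lapply(1:12, function(m) {
    i <- which(mo == m)
    w <- wet[i]; pw <- prev_wet[i]
    ok <- !is.na(pw)
    n01 <- sum(ok & !pw[] & w); n0 <- sum(ok & !pw)
    n11 <- sum(ok & pw & w); n1 <- sum(ok & pw)
    p01 <- if (n0 > 0) n01 / n0 else 1    # all-wet chain: p01 undefined -> 1
    p11 <- if (n1 > 0) n11 / n1 else 0
    amounts <- series$prec[i][w]
    if (length(amounts) >= 2 && stats::var(amounts) > 0) {
      mu <- mean(amounts); v <- stats::var(amounts)
      shape <- mu^2 / v; scale <- v / mu
    } else if (length(amounts) >= 1) {
      shape <- 1; scale <- mean(amounts)
    } else {
      shape <- NA_real_; scale <- NA_real_
    }
    off <- function(x) {
      if (any(w) && any(!w)) mean(x[w]) - mean(x[!w]) else 0
    }
    data.frame(
      tmax_mean = mean(series$tmax[i]), tmin_mean = mean(series$tmin[i]),
      tmax_sd = stats::sd(series$tmax[i]), tmin_sd = stats::sd(series$tmin[i]),
      rad_mean = mean(series$rad[i]), rad_sd = stats::sd(series$rad[i]),
      p01 = p01, p11 = p11, gamma_shape = shape, gamma_scale = scale,
      tmax_wet_offset = off(series$tmax[i]), tmin_wet_offset = off(series$tmin[i]),
      rad_wet_offset = off(series$rad[i]))
  })
  months <- do.call(rbind, rows)
  months$tmax_sd[is.na(months$tmax_sd)] <- 0
  months$tmin_sd[is.na(months$tmin_sd)] <- 0
  months$rad_sd[is.na(months$rad_sd)] <- 0
  # standardised residuals pooled across months for correlation structure
  z <- residual_matrix(series, months, mo, wet)
  ar1 <- vapply(1:3, function(k) {
    x <- z[, k]
    if (stats::sd(x, na.rm = TRUE) > 0)
      stats::cor(x[-n], x[-1], use = "complete.obs") else 0
  }, numeric(1))
  names(ar1) <- c("tmax", "tmin", "rad")
  cc <- tryCatch(suppressWarnings(stats::cor(z, use = "complete.obs")),
                 error = function(e) diag(3))
  if (any(!is.finite(cc))) cc <- diag(3)
  dimnames(cc) <- dimnames(default_cross_cor())
  climatology(months, ar1 = clamp(ar1, -0.95, 0.95), cross_cor = cc, trace = trace)
}

residual_matrix <- function(series, months, mo, wet) {
  pw <- months$p01 / pmax(1 + months$p01 - months$p11, 1e-12)
  z <- matrix(NA_real_, nrow(series), 3)
  vars <- c("tmax", "tmin", "rad")
  for (k in seq_along(vars)) {
    v <- vars[k]
    m <- months[[paste0(v, "_mean")]][mo]
    s <- months[[paste0(v, "_sd")]][mo]
    o <- months[[paste0(v, "_wet_offset")]][mo]
    f <- pw[mo]
    cond <- ifelse(wet, m + (1 - f) * o, m - f * o)
    z[, k] <- ifelse(s > 0, (series[[v]] - cond) / s, 0)
  }
  z
}

#' Generate a synthetic station daily weather series
#'
#' Richardson-type generation: precipitation occurrence from the monthly
#' two-state Markov chain, wet-day amounts from the monthly gamma law (never
#' below the trace threshold; dry days exactly zero), and tmax/tmin/rad from
#' monthly means plus mean-preserving wet/dry shifts plus lag-1
#' autoregressive residuals with cross-correlated innovations.
#' \code{tmin} is capped at \code{tmax - 0.1}; radiation is floored at zero
#' and capped at clear-sky transmissivity (0.8 Ra at the station latitude).
#'
#' @param clim a \code{climatology}.
#' @param station a [station_meta].
#' @param years number of years to generate.
#' @param seed integer seed (the series records it as attribute
#'   \code{"seed"}).
#' @param start_year first calendar year, default 1981.
#' @return A \code{daily_series}.
#' @export
generate_station_baseline <- function(clim, station, years, seed,
                                      start_year = 1981L) {
  stopifnot(inherits(clim, "climatology"), inherits(station, "station_meta"))
  set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", start_year + years - 1L)), by = "day")
  out <- generate_days(clim, station, dates)
  ser <- daily_series(station, out)
  attr(ser, "seed") <- seed
  ser
}

# core day-loop generator used for both free-running and monthly-conditioned
# generation; RNG state is the caller's responsibility.
generate_days <- function(clim, station, dates, state = NULL) {
  n <- length(dates)
  mo <- as.integer(strftime(dates, "%m"))
  doy <- as.integer(strftime(dates, "%j"))
  m <- clim$months
  pw_stat <- m$p01 / pmax(1 + m$p01 - m$p11, 1e-12)

  # precipitation occurrence: sequential Markov chain
  u <- stats::runif(n)
  wet <- logical(n)
  prev <- if (!is.null(state)) state$wet else stats::runif(1) < pw_stat[mo[1]]
  for (i in seq_len(n)) {
    p <- if (prev) m$p11[mo[i]] else m$p01[mo[i]]
    if (is.na(p)) p <- 0
    wet[i] <- u[i] < p
    prev <- wet[i]
  }
  # amounts: gamma, floored at trace; months without a defined law stay dry
  prec <- numeric(n)
  if (any(wet)) {
    sh <- m$gamma_shape[mo[wet]]; sc <- m$gamma_scale[mo[wet]]
    def <- !is.na(sh)
    amt <- numeric(sum(wet))
    amt[def] <- pmax(stats::rgamma(sum(def), shape = sh[def], scale = sc[def]),
                     clim$trace)
    wet[wet][!def] <- FALSE
    prec[which(wet)] <- amt[def]
  }

  # residuals: AR(1) per variable, cross-correlated innovations
  L <- chol_psd(clim$cross_cor)
  eps <- matrix(stats::rnorm(n * 3), n, 3) %*% L
  phi <- clim$ar1[c("tmax", "tmin", "rad")]
  z <- matrix(0, n, 3)
  z0 <- if (!is.null(state)) state$z else as.numeric(eps[1, ])
  for (k in 1:3) {
    innov <- eps[, k] * sqrt(max(1 - phi[k]^2, 0))
    z[, k] <- as.numeric(stats::filter(innov, phi[k], method = "recursive",
                                       init = z0[k]))
  }

  f <- pw_stat[mo]
  shift <- function(off) ifelse(wet, (1 - f) * off[mo], -f * off[mo])
  tmax <- m$tmax_mean[mo] + shift(m$tmax_wet_offset) + m$tmax_sd[mo] * z[, 1]
  tmin <- m$tmin_mean[mo] + shift(m$tmin_wet_offset) + m$tmin_sd[mo] * z[, 2]
  rad <- m$rad_mean[mo] + shift(m$rad_wet_offset) + m$rad_sd[mo] * z[, 3]
  tmin <- pmin(tmin, tmax - 0.1)
  ra <- extraterrestrial_radiation(station$latitude, pmin(doy, 366L))
  rad <- clamp(rad, 0, 0.8 * ra)

  df <- data.frame(date = dates, tmax = tmax, tmin = tmin, prec = prec,
                   sh = NA_real_, rad = rad)
  attr(df, "state") <- list(wet = wet[n], z = z[n, ])
  df
}

chol_psd <- function(m) {
  out <- tryCatch(chol(m), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(m, symmetric = TRUE)
    out <- chol(e$vectors %*% diag(pmax(e$values, 1e-8)) %*% t(e$vectors))
  }
  out
}

#' Scenario specification for the pseudo-GCM ensemble
#'
#' Describes how a scenario perturbs the future window relative to the
#' baseline: additive temperature and radiation deltas and a multiplicative
#' precipitation factor, each with an inter-model spread, plus the ensemble
#' size.
#'
#' @param scenario scenario label.
#' @param delta_t_mean,delta_t_spread ensemble mean and between-model sd of
#'   the warming (degC).
#' @param delta_rad_mean,delta_rad_spread radiation delta (MJ m-2 d-1; may be
#'   negative).
#' @param prec_factor_mean,prec_factor_spread multiplicative precipitation
#'   factor (> 0).
#' @param n_models ensemble size (>= 2).
#' @return An object of class \code{scenario_spec}.
#' @export
scenario_spec <- function(scenario, delta_t_mean, delta_t_spread = 0,
                          delta_rad_mean = 0, delta_rad_spread = 0,
                          prec_factor_mean = 1, prec_factor_spread = 0,
                          n_models = 22L) {
  if (n_models < 2) stop("ensemble statistics need n_models >= 2", call. = FALSE)
  if (prec_factor_mean <= 0) stop("prec_factor_mean must be > 0", call. = FALSE)
  structure(list(scenario = scenario, delta_t_mean = delta_t_mean,
                 delta_t_spread = delta_t_spread,
                 delta_rad_mean = delta_rad_mean,
                 delta_rad_spread = delta_rad_spread,
                 prec_factor_mean = prec_factor_mean,
                 prec_factor_spread = prec_factor_spread,
                 n_models = as.integer(n_models)),
            class = "scenario_spec")
}

#' Default SSP-like scenario specifications
#'
#' Ensemble deltas emulating the qualitative multi-GCM pattern for the 2050s
#' in a humid-monsoon rice-wheat region: warming increasing with forcing
#' (SSP126 < SSP245 < SSP370 < SSP585, the strongest scenario above 2 degC),
#' radiation increasing under SSP126/245/585 but decreasing under SSP370
#' (aerosol-heavy pathway), and a modest precipitation increase with little
#' separation between scenarios.
#'
#' @param n_models ensemble size per scenario.
#' @return Named list of [scenario_spec] objects.
#' @export
default_scenario_specs <- function(n_models = 22L) {
  list(
    SSP126 = scenario_spec("SSP126", 1.6, 0.4, 1.1, 0.4, 1.04, 0.04, n_models),
    SSP245 = scenario_spec("SSP245", 2.0, 0.4, 0.5, 0.3, 1.05, 0.04, n_models),
    SSP370 = scenario_spec("SSP370", 2.2, 0.5, -0.5, 0.3, 1.05, 0.05, n_models),
    SSP585 = scenario_spec("SSP585", 2.6, 0.5, 0.5, 0.3, 1.06, 0.05, n_models)
  )
}

#' Generate a pseudo-GCM monthly ensemble around a station
#'
#' Stands in for a real multi-GCM archive. Each pseudo-model draws its own
#' static bias offsets (temperature and radiation additive, precipitation
#' multiplicative) and its own scenario deltas from the spec's mean and
#' spread. Node monthly values are the station climatology plus a smooth
#' deterministic spatial gradient, the model bias, shared inter-annual noise
#' and, in the future window, the model's delta. The future window reuses the
#' baseline window's inter-annual noise realisation (common random numbers),
#' so a null scenario with zero spread and bias reproduces the baseline
#' exactly and imposed deltas survive downstream with minimal sampling noise.
#'
#' @param clim station \code{climatology}.
#' @param spec a [scenario_spec].
#' @param station a [station_meta]; the grid is laid out around it.
#' @param seed master seed; per-model substreams are derived from it.
#' @param grid_size nodes per side (default 5 x 5).
#' @param spacing node spacing in degrees (default 1).
#' @param baseline_years,future_years integer year vectors of the two windows
#'   (defaults 1981-2010 and 2041-2070); they must have equal length.
#' @param bias_sd_t,bias_sd_rad,bias_sdlog_prec per-model static bias scales.
#' @return List of \code{gcm_grid} objects (one per pseudo-model), each with
#'   fields \code{model}, \code{scenario}, \code{nodes} and a \code{monthly}
#'   data frame (window, node, lat, lon, year, month, tmax, tmin, prec, rad).
#' @export
generate_pseudo_gcm_ensemble <- function(clim, spec, station, seed,
                                         grid_size = 5L, spacing = 1,
                                         baseline_years = 1981:2010,
                                         future_years = 2041:2070,
                                         bias_sd_t = 0.6, bias_sd_rad = 0.6,
                                         bias_sdlog_prec = 0.12) {
  stopifnot(inherits(clim, "climatology"), inherits(spec, "scenario_spec"))
  if (length(baseline_years) != length(future_years))
    stop("baseline and future windows must have equal length", call. = FALSE)
  half <- (grid_size - 1) / 2
  nodes <- expand.grid(
    lat = station$latitude + spacing * (seq_len(grid_size) - 1 - half),
    lon = station$longitude + spacing * (seq_len(grid_size) - 1 - half))
  nodes$node <- seq_len(nrow(nodes))
  m <- clim$months
  ndays <- days_in_month(2001, 1:12)
  prec_clim <- expected_month_prec(clim)
  # effective sd of a monthly mean of autocorrelated days
  month_sd <- function(sd_day, phi) sd_day / sqrt(ndays) *
    sqrt(pmax((1 + phi) / (1 - phi), 1))
  sd_tmax <- month_sd(m$tmax_sd, clim$ar1["tmax"])
  sd_tmin <- month_sd(m$tmin_sd, clim$ar1["tmin"])
  sd_rad <- month_sd(m$rad_sd, clim$ar1["rad"])

  nyr <- length(baseline_years)
  lapply(seq_len(spec$n_models), function(im) {
    set.seed(substream_seed(seed, "gcm", station$station_id, spec$scenario, im))
    bias_t <- stats::rnorm(1, 0, bias_sd_t)
    bias_rad <- stats::rnorm(1, 0, bias_sd_rad)
    bias_prec <- exp(stats::rnorm(1, 0, bias_sdlog_prec))
    d_t <- stats::rnorm(1, spec$delta_t_mean, spec$delta_t_spread)
    d_rad <- stats::rnorm(1, spec$delta_rad_mean, spec$delta_rad_spread)
    f_prec <- max(stats::rnorm(1, spec$prec_factor_mean, spec$prec_factor_spread),
                  0.1)
    # shared inter-annual noise (year x month), reused by the future window
    zt <- matrix(stats::rnorm(nyr * 12), nyr, 12)
    zn <- matrix(stats::rnorm(nyr * 12), nyr, 12)
    zr <- matrix(stats::rnorm(nyr * 12), nyr, 12)
    zp <- matrix(stats::rnorm(nyr * 12, 0, 0.25), nyr, 12)

    one_window <- function(window, years, dt, drad, fp) {
      grid <- expand.grid(year = years, month = 1:12)
      base <- do.call(rbind, lapply(seq_len(nrow(nodes)), function(k) {
        glat <- 0.6 * (nodes$lat[k] - station$latitude)       # degC per degree
        glon <- 0.15 * (nodes$lon[k] - station$longitude)
        iy <- match(grid$year, years); imn <- grid$month
        data.frame(
          window = window, node = nodes$node[k],
          lat = nodes$lat[k], lon = nodes$lon[k],
          year = grid$year, month = grid$month,
          tmax = m$tmax_mean[imn] - glat + glon + bias_t + dt +
            sd_tmax[imn] * zt[cbind(iy, imn)],
          tmin = m$tmin_mean[imn] - glat + glon + bias_t + dt +
            sd_tmin[imn] * zn[cbind(iy, imn)],
          prec = prec_clim[imn] * bias_prec * fp * exp(zp[cbind(iy, imn)] -
                                                         0.25^2 / 2),
          rad = pmax(m$rad_mean[imn] + 0.1 * glat + bias_rad + drad +
                       sd_rad[imn] * zr[cbind(iy, imn)], 0.1))
      }))
      base$tmin <- pmin(base$tmin, base$tmax - 0.5)
      base
    }
    monthly <- rbind(
      one_window("baseline", baseline_years, 0, 0, 1),
      one_window("future", future_years, d_t, d_rad, f_prec))
    structure(list(model = sprintf("pGCM%02d", im), scenario = spec$scenario,
                   nodes = nodes, monthly = monthly,
                   bias = c(t = bias_t, rad = bias_rad, prec = bias_prec),
                   delta = c(t = d_t, rad = d_rad, prec_factor = f_prec),
                   windows = list(baseline = baseline_years,
                                  future = future_years)),
              class = "gcm_grid")
  })
}

#' @export
print.gcm_grid <- function(x, ...) {
  cat(sprintf("Pseudo-GCM %s (%s): %d nodes, dT=%.2f degC, dRad=%.2f, prec x%.3f\n",
              x$model, x$scenario, nrow(x$nodes),
              x$delta["t"], x$delta["rad"], x$delta["prec_factor"]))
  invisible(x)
}

#' Write a pseudo-GCM grid as CSV plus a YAML ensemble manifest
#'
#' One CSV per model/scenario with columns (window, node_lat, node_lon, year,
#' month, tmax, tmin, prec, rad); the manifest lists the ensemble catalogue.
#'
#' @param grids list of \code{gcm_grid} objects.
#' @param dir output directory.
#' @export
write_gcm_ensemble <- function(grids, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- lapply(grids, function(g) {
    fn <- sprintf("%s_%s.csv", g$model, g$scenario)
    df <- g$monthly
    names(df)[names(df) == "lat"] <- "node_lat"
    names(df)[names(df) == "lon"] <- "node_lon"
    utils::write.csv(df[c("window", "node_lat", "node_lon", "year", "month",
                          "tmax", "tmin", "prec", "rad")],
                     file.path(dir, fn), row.names = FALSE, quote = FALSE)
    list(model = g$model, scenario = g$scenario, file = fn)
  })
  yaml::write_yaml(list(models = manifest), file.path(dir, "manifest.yaml"))
  invisible(dir)
}
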