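# Two-step statistical downscaling: inverse-distance spatial interpolation of
# the monthly grid to the station, empirical quantile-quantile bias
# correction against the station observations, and temporal disaggregation
# to daily weather with a monthly-conditioned stochastic generator.

# great-circle distance (km) via the haversine formula
haversine_km <- function(lat1, lon1, lat2, lon2) {
  r <- 6371.0088
  p <- pi / 180
  dlat <- (lat2 - lat1) * p; dlon <- (lon2 - lon1) * p
  a <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  2 * r * asin(pmin(sqrt(a), 1))
}

#' Inverse-distance-weighted interpolation to a point
#'
#' Weighted mean over the k nearest nodes with weights proportional to
#' great-circle distance^(-power); weights sum to one. A node closer than
#' \code{eps} km to the target returns that node's value exactly. Equidistant
#' nodes receive equal weights.
#'
#' @param node_values data frame with columns \code{lat}, \code{lon},
#'   \code{value}.
#' @param target \code{c(lat, lon)} of the target point.
#' @param power distance exponent (> 0), default 2.
#' @param k_neighbors number of nearest nodes used, default 4.
#' @param eps coincidence tolerance in km.
#' @return Interpolated value.
#' @export
idw_interpolate <- function(node_values, target, power = 2, k_neighbors = 4L,
                            eps = 1e-6) {
  if (!nrow(node_values)) stop("empty node list", call. = FALSE)
  if (power <= 0) stop("power must be > 0", call. = FALSE)
  d <- haversine_km(node_values$lat, node_values$lon, target[1], target[2])
  hit <- which(d < eps)
  if (length(hit)) return(node_values$value[hit[1]])
  k <- min(k_neighbors, length(d))
  sel <- order(d)[seq_len(k)]
  w <- d[sel]^(-power)
  sum(w * node_values$value[sel]) / sum(w)
}

#' Fit an empirical quantile-quantile bias-correction map
#'
#' Pairs K empirical quantiles of the model baseline distribution with the
#' corresponding quantiles of the observations, in rank order, for one
#' variable and calendar month.
#'
#' @param obs_monthly observed monthly values.
#' @param model_monthly_baseline model monthly values over the baseline
#'   window.
#' @param variable variable name (metadata).
#' @param month calendar month (metadata).
#' @param K number of quantile knots (>= 2), default 30; reduced to the
#'   available sample size if needed.
#' @return An object of class \code{qq_map}.
#' @export
fit_qq_map <- function(obs_monthly, model_monthly_baseline,
                       variable = "var", month = NA_integer_, K = 30L) {
  n <- min(length(obs_monthly), length(model_monthly_baseline))
  K <- as.integer(min(K, n))
  if (K < 2) stop("need at least 2 values in each input", call. = FALSE)
  probs <- seq(0, 1, length.out = K)
  mq <- as.numeric(stats::quantile(model_monthly_baseline, probs, type = 7))
  oq <- as.numeric(stats::quantile(obs_monthly, probs, type = 7))
  structure(list(variable = variable, month = month,
                 model_q = mq, obs_q = oq, K = K),
            class = "qq_map")
}

#' Apply a quantile-quantile map
#'
#' Piecewise-linear interpolation between knots; beyond the outermost knots
#' the correction extrapolates with the constant offset of the nearest edge
#' pair (value + obs_edge - model_edge), so future values outside the
#' calibrated range are shifted, not clamped.
#'
#' @param map a \code{qq_map}.
#' @param value numeric vector to correct.
#' @return Corrected values.
#' @export
apply_qq_map <- function(map, value) {
  mq <- map$model_q; oq <- map$obs_q
  K <- length(mq)
  out <- numeric(length(value))
  lo <- value < mq[1]; hi <- value > mq[K]
  mid <- !lo & !hi
  if (any(mid)) {
    if (mq[K] - mq[1] < 1e-12) {
      out[mid] <- oq[stats::median(seq_len(K))] + (value[mid] - mq[1])
    } else {
      out[mid] <- stats::approx(mq, oq, xout = value[mid], ties = "ordered")$y
    }
  }
  out[lo] <- value[lo] + (oq[1] - mq[1])
  out[hi] <- value[hi] + (oq[K] - mq[K])
  out
}

#' Fit stochastic weather generator parameters
#'
#' Extends [fit_climatology] with explicit per-month conditional (wet/dry)
#' means and standard deviations of tmax/tmin/rad for inspection; generation
#' uses the same mean-preserving representation as the climatology.
#'
#' @inheritParams fit_climatology
#' @return An object of class \code{c("wgen_params", "climatology")}.
#' @export
fit_wgen <- function(series, trace = 0.1) {
  clim <- fit_climatology(series, trace = trace)
  mo <- as.integer(strftime(series$date, "%m"))
  wet <- series$prec >= trace
  cond <- do.call(rbind, lapply(1:12, function(mm) {
    i <- which(mo == mm)
    w <- wet[i]
    stat <- function(x, sel, f) if (any(sel)) f(x[sel]) else NA_real_
    data.frame(
      tmax_wet_mean = stat(series$tmax[i], w, mean),
      tmax_dry_mean = stat(series$tmax[i], !w, mean),
      tmax_wet_sd = stat(series$tmax[i], w, stats::sd),
      tmax_dry_sd = stat(series$tmax[i], !w, stats::sd),
      tmin_wet_mean = stat(series$tmin[i], w, mean),
      tmin_dry_mean = stat(series$tmin[i], !w, mean),
      rad_wet_mean = stat(series$rad[i], w, mean),
      rad_dry_mean = stat(series$rad[i], !w, mean))
  }))
  clim$conditional <- cond
  class(clim) <- c("wgen_params", "climatology")
  clim
}

#' Serialise generator parameters or a qq map to YAML
#'
#' @param x a \code{climatology}/\code{wgen_params} or \code{qq_map}.
#' @param path output file.
#' @export
write_params_yaml <- function(x, path) {
  if (inherits(x, "climatology")) {
    obj <- list(type = class(x)[1], months = as.list(x$months),
                ar1 = as.list(x$ar1),
                cross_cor = as.list(as.data.frame(x$cross_cor)),
                trace = x$trace)
  } else if (inherits(x, "qq_map")) {
    obj <- list(type = "qq_map", variable = x$variable, month = x$month,
                model_q = x$model_q, obs_q = x$obs_q)
  } else stop("unsupported object", call. = FALSE)
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' Generate daily weather conditioned on monthly targets
#'
#' Runs the stochastic generator month by month (Markov/AR state carries
#' across months) and adjusts each month to match its target exactly:
#' wet-day amounts are rescaled multiplicatively to the target monthly total
#' (a month whose chain produced no wet day but whose target is positive gets
#' one forced wet day at a uniformly chosen position, recorded in attribute
#' \code{"forced_wet"}); temperatures are shifted additively to the target
#' monthly means; radiation is rescaled multiplicatively and floored at zero.
#' \code{tmin} is capped at \code{tmax - 0.1} after shifting.
#'
#' @param params \code{wgen_params} (or \code{climatology}).
#' @param target a \code{monthly_series} (or data frame with year, month,
#'   tmax_mean, tmin_mean, prec_total, rad_mean) covering whole months.
#' @param station a [station_meta]; taken from the target attribute when
#'   absent.
#' @param seed integer seed.
#' @return A \code{daily_series} whose monthly precipitation totals equal the
#'   targets to 1e-9 mm.
#' @export
generate_daily_conditioned <- function(params, target, station = NULL, seed) {
  stopifnot(inherits(params, "climatology"))
  station <- station %||% attr(target, "station")
  stopifnot(inherits(station, "station_meta"))
  target <- as.data.frame(target)
  o <- order(target$year, target$month)
  target <- target[o, ]
  set.seed(seed)
  state <- NULL
  forced <- integer(0)
  pieces <- vector("list", nrow(target))
  for (i in seq_len(nrow(target))) {
    yr <- target$year[i]; mn <- target$month[i]
    nd <- days_in_month(yr, mn)
    dates <- seq(as.Date(sprintf("%04d-%02d-01", yr, mn)), by = "day",
                 length.out = nd)
    g <- generate_days(params, station, dates, state = state)
    state <- attr(g, "state")

    # precipitation: exact monthly total
    tgt <- target$prec_total[i]
    if (tgt <= 0) {
      g$prec[] <- 0
    } else {
      s <- sum(g$prec)
      if (s > 0) {
        g$prec <- g$prec * (tgt / s)
      } else {
        pos <- floor(stats::runif(1, 1, nd + 1))
        g$prec[pos] <- tgt
        forced <- c(forced, i)
        state$wet <- pos == nd
      }
    }
    # temperatures: additive shift to target means
    g$tmax <- g$tmax + (target$tmax_mean[i] - mean(g$tmax))
    g$tmin <- g$tmin + (target$tmin_mean[i] - mean(g$tmin))
    g$tmin <- pmin(g$tmin, g$tmax - 0.1)
    # radiation: multiplicative rescale, floored at zero
    mg <- mean(g$rad)
    if (!is.na(target$rad_mean[i])) {
      if (mg > 0) g$rad <- pmax(g$rad * (target$rad_mean[i] / mg), 0)
      else g$rad[] <- max(target$rad_mean[i], 0)
    }
    pieces[[i]] <- g
  }
  df <- do.call(rbind, pieces)
  # date contiguity is only checkable for contiguous targets (replicated
  # single-month targets are a legitimate use); the remaining invariants
  # (tmax >= tmin, prec >= 0) hold by construction
  contiguous <- all(diff(df$date) == 1)
  out <- daily_series(station, df, validate = contiguous)
  attr(out, "seed") <- seed
  attr(out, "forced_wet") <- forced
  out
}

#' Downscale one pseudo-GCM to station daily weather
#'
#' Composes the full two-step chain for one model/scenario: per month and
#' variable the grid nodes are interpolated to the station (IDW), a
#' quantile-quantile map fitted on the baseline window per calendar month is
#' applied to both windows, and the corrected monthly series are
#' disaggregated to daily weather with the generator fitted to the station
#' observations. The same generator substream is used for both windows
#' (common random numbers), so window differences reflect the model's climate
#' deltas rather than generator sampling noise.
#'
#' @param grid a \code{gcm_grid}.
#' @param station a [station_meta].
#' @param obs observed (or pseudo-observed) station \code{daily_series}
#'   covering the baseline window.
#' @param seed integer seed.
#' @param K quantile knots for the bias correction, default 30.
#' @param power,k_neighbors IDW parameters.
#' @param wgen optional pre-fitted \code{wgen_params} (refitted from
#'   \code{obs} when NULL).
#' @return An object of class \code{downscaled_scenario} with fields
#'   \code{station}, \code{model}, \code{scenario}, \code{baseline},
#'   \code{future} (daily series), \code{monthly} (corrected monthly values)
#'   and \code{provenance}.
#' @export
downscale_model <- function(grid, station, obs, seed, K = 30L, power = 2,
                            k_neighbors = 4L, wgen = NULL) {
  stopifnot(inherits(grid, "gcm_grid"), inherits(obs, "daily_series"))
  obs_monthly <- aggregate_monthly(obs)
  if (is.null(wgen)) wgen <- fit_wgen(obs)
  vars <- c("tmax", "tmin", "prec", "rad")

  # spatial step: IDW node -> station. The node layout is static, so the IDW
  # weights are computed once and applied to every window/year/month.
  nd <- grid$nodes
  d <- haversine_km(nd$lat, nd$lon, station$latitude, station$longitude)
  k <- min(k_neighbors, nrow(nd))
  sel <- order(d)[seq_len(k)]
  if (d[sel[1]] < 1e-6) {
    w <- c(1, rep(0, k - 1))
  } else {
    w <- d[sel]^(-power); w <- w / sum(w)
  }
  mdf <- grid$monthly[grid$monthly$node %in% nd$node[sel], ]
  wv <- w[match(mdf$node, nd$node[sel])]
  key <- sprintf("%s|%04d|%02d", mdf$window, mdf$year, mdf$month)
  agg <- rowsum(cbind(tmax = mdf$tmax, tmin = mdf$tmin,
                      prec = mdf$prec, rad = mdf$rad) * wv, key)
  parts <- do.call(rbind, strsplit(rownames(agg), "|", fixed = TRUE))
  spat <- data.frame(window = parts[, 1], year = as.integer(parts[, 2]),
                     month = as.integer(parts[, 3]), agg, row.names = NULL)
  spat <- spat[order(spat$window, spat$year, spat$month), ]

  # bias correction: qq map per variable and calendar month, fitted on the
  # baseline window against the observations
  obs_cols <- c(tmax = "tmax_mean", tmin = "tmin_mean",
                prec = "prec_total", rad = "rad_mean")
  maps <- list()
  corrected <- spat
  for (v in vars) {
    for (mm in 1:12) {
      ob <- obs_monthly[[obs_cols[[v]]]][obs_monthly$month == mm]
      bl <- spat[[v]][spat$window == "baseline" & spat$month == mm]
      map <- fit_qq_map(ob, bl, variable = v, month = mm, K = K)
      maps[[paste(v, mm, sep = ".")]] <- map
      idx <- corrected$month == mm
      corrected[[v]][idx] <- apply_qq_map(map, spat[[v]][idx])
    }
  }
  corrected$prec <- pmax(corrected$prec, 0)
  corrected$tmin <- pmin(corrected$tmin, corrected$tmax - 0.5)
  corrected$rad <- pmax(corrected$rad, 0.1)

  # temporal step: conditioned generation per window, common substream
  gen_seed <- substream_seed(seed, "wgen", station$station_id,
                             grid$scenario, grid$model)
  make_target <- function(window) {
    df <- corrected[corrected$window == window,
                    c("year", "month", "tmax", "tmin", "prec", "rad")]
    names(df) <- c("year", "month", "tmax_mean", "tmin_mean", "prec_total",
                   "rad_mean")
    df
  }
  baseline <- generate_daily_conditioned(wgen, make_target("baseline"),
                                         station, seed = gen_seed)
  future <- generate_daily_conditioned(wgen, make_target("future"),
                                       station, seed = gen_seed)
  structure(list(station = station, model = grid$model,
                 scenario = grid$scenario,
                 baseline = baseline, future = future,
                 monthly = corrected, qq_maps = maps,
                 provenance = list(seed = seed, gen_seed = gen_seed,
                                   K = K, power = power,
                                   k_neighbors = k_neighbors)),
            class = "downscaled_scenario")
}

#' @export
print.downscaled_scenario <- function(x, ...) {
  cat(sprintf("Downscaled %s / %s at %s: %d + %d days\n",
              x$model, x$scenario, x$station$station_id,
              nrow(x$baseline), nrow(x$future)))
  invisible(x)
}
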