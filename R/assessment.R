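# Ensemble experiment runner, box statistics in the multi-model convention,
# and the delta-attribution regressions with significance stars.

doy_of <- function(d) as.integer(strftime(d, "%j"))

annual_climate <- function(series) {
  m <- aggregate_monthly(series)
  yrs <- unique(m$year)
  full <- yrs[vapply(yrs, function(y) sum(m$year == y) == 12L, logical(1))]
  m <- m[m$year %in% full, ]
  ndays <- days_in_month(m$year, m$month)
  list(
    tmean = sum((m$tmax_mean + m$tmin_mean) / 2 * ndays) / sum(ndays),
    rad = sum(m$rad_mean * ndays) / sum(ndays),
    prec = sum(m$prec_total) / length(full))
}

window_climate <- function(series, window) {
  gs <- growth_period_summary(series, window$start, window$end)
  list(tmean = (gs$tmax_mean + gs$tmin_mean) / 2, rad = gs$rad_mean,
       prec = gs$prec_total)
}

crop_cell_stats <- function(rot, cropname) {
  sub <- rot$seasons[rot$seasons$crop == cropname, ]
  frac_failed <- if (nrow(sub)) mean(sub$failed) else 1
  ok <- sub[!sub$failed, ]
  if (!nrow(ok))
    return(list(frac_failed = frac_failed, yield = NA, et = NA, wue = NA,
                fd = NA, md = NA, rgp = NA))
  list(frac_failed = frac_failed,
       yield = mean(ok$yield), et = mean(ok$et), wue = mean(ok$wue),
       fd = mean(doy_of(ok$fd)), md = mean(doy_of(ok$md)), rgp = mean(ok$rgp))
}

#' Run the baseline/future ensemble experiment
#'
#' Simulates the rotation for the baseline and future windows of every
#' downscaled model and computes per station x scenario x model x crop change
#' rows (future-window mean minus baseline-window mean): climate deltas over
#' the crop growth window (annual values for the "total" rows), CO2 delta as
#' the difference of annual means, and crop outcome deltas (flowering and
#' maturity day-of-year, reproductive period length, yield, ET, WUE). Cells
#' with more than \code{fail_threshold} failed seasons in either window are
#' flagged \code{excluded} and dropped from regressions.
#'
#' @param downscaled list of \code{downscaled_scenario} objects.
#' @param co2 either a single ppm value (used for all years: null
#'   experiments) or a named list of [co2_coefficients] per scenario.
#' @param wheat,rice,soil,mgmt simulation parameters.
#' @param fail_threshold maximum tolerated failed-season fraction.
#' @return A data frame of class \code{ensemble_change}.
#' @export
run_experiment <- function(downscaled, co2,
                           wheat = default_wheat_params(),
                           rice = default_rice_params(),
                           soil = soil_params(),
                           mgmt = management_params(),
                           fail_threshold = 0.2) {
  rows <- lapply(downscaled, function(ds) {
    co2_vec <- function(series) {
      yrs <- sort(unique(as.integer(strftime(series$date, "%Y"))))
      yrs <- c(yrs, max(yrs) + 1L)     # wheat harvested the year after sowing
      if (is.numeric(co2) && length(co2) == 1) {
        stats::setNames(rep(co2, length(yrs)), yrs)
      } else {
        traj <- build_trajectory(co2[[ds$scenario]])
        ok <- pmin(pmax(yrs, min(traj$year)), max(traj$year))
        stats::setNames(traj$ppm[match(ok, traj$year)], yrs)
      }
    }
    cb <- co2_vec(ds$baseline); cf <- co2_vec(ds$future)
    rot_b <- simulate_rotation(ds$baseline, cb, wheat, rice, soil, mgmt)
    rot_f <- simulate_rotation(ds$future, cf, wheat, rice, soil, mgmt)
    d_co2 <- mean(cf) - mean(cb)

    windows <- list(rice = mgmt$rice_window, wheat = mgmt$wheat_window)
    out <- lapply(c("rice", "wheat", "total"), function(cr) {
      if (cr == "total") {
        clim_b <- annual_climate(ds$baseline); clim_f <- annual_climate(ds$future)
        ok_b <- rot_b$annual; ok_f <- rot_f$annual
        sb <- list(yield = mean(ok_b$yield), et = mean(ok_b$et),
                   wue = mean(ok_b$wue), fd = NA, md = NA, rgp = NA,
                   frac_failed = mean(rot_b$seasons$failed))
        sf <- list(yield = mean(ok_f$yield), et = mean(ok_f$et),
                   wue = mean(ok_f$wue), fd = NA, md = NA, rgp = NA,
                   frac_failed = mean(rot_f$seasons$failed))
      } else {
        clim_b <- window_climate(ds$baseline, windows[[cr]])
        clim_f <- window_climate(ds$future, windows[[cr]])
        sb <- crop_cell_stats(rot_b, cr); sf <- crop_cell_stats(rot_f, cr)
      }
      data.frame(
        station = ds$station$station_id, scenario = ds$scenario,
        model = ds$model, crop = cr,
        d_tmean = clim_f$tmean - clim_b$tmean,
        d_rad = clim_f$rad - clim_b$rad,
        d_pre = clim_f$prec - clim_b$prec,
        d_co2 = d_co2,
        d_fd = sf$fd - sb$fd, d_md = sf$md - sb$md, d_rgp = sf$rgp - sb$rgp,
        d_yield = sf$yield - sb$yield,
        d_yield_pct = 100 * (sf$yield - sb$yield) / sb$yield,
        d_et = sf$et - sb$et, d_wue = sf$wue - sb$wue,
        frac_failed = max(sb$frac_failed, sf$frac_failed),
        excluded = max(sb$frac_failed, sf$frac_failed) > fail_threshold)
    })
    do.call(rbind, out)
  })
  structure(do.call(rbind, rows), class = c("ensemble_change", "data.frame"))
}

#' Ensemble box statistics
#'
#' Mean, median and the 10th/25th/75th/90th percentiles across the model
#' dimension, the convention of multi-GCM box plots (box = quartiles,
#' whiskers = 10th/90th). Percentiles use the linear-interpolation
#' convention.
#'
#' @param changes an \code{ensemble_change} data frame.
#' @param response column to summarise, e.g. \code{"d_yield"}.
#' @param by grouping columns, default station, scenario and crop.
#' @return Data frame of class \code{box_stats} with columns mean, median,
#'   p10, p25, p75, p90 and n per group.
#' @export
ensemble_box_stats <- function(changes, response,
                               by = c("station", "scenario", "crop")) {
  stopifnot(response %in% names(changes))
  groups <- split(changes, changes[by], drop = TRUE)
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- g[[response]][!g$excluded & is.finite(g[[response]])]
    q <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7,
                         names = FALSE)
    cbind(g[1, by, drop = FALSE],
          data.frame(response = response, mean = mean(v), median = q[3],
                     p10 = q[1], p25 = q[2], p75 = q[4], p90 = q[5],
                     n = length(v)))
  }))
  rownames(out) <- NULL
  structure(out, class = c("box_stats", "data.frame"))
}

#' Delta-attribution regression
#'
#' Ordinary least squares of an outcome change on the four climate-driver
#' changes, pooling stations, scenarios and models for one crop:
#' \deqn{\Delta y = a \Delta Tmean + b \Delta Rad + c \Delta Pre + d \Delta CO2}
#' without an intercept. Two-sided t tests per coefficient; significance
#' flags at 0.05 (*) and 0.01 (**); R-squared follows the no-intercept
#' convention (total sum of squares about zero).
#'
#' @param changes an \code{ensemble_change} data frame.
#' @param response one of \code{"d_yield"}, \code{"d_et"}, \code{"d_wue"}.
#' @param crop "rice", "wheat" or "total".
#' @param intercept include an intercept (sensitivity option; default FALSE,
#'   matching the attribution model).
#' @param min_rows minimum usable rows, default 10.
#' @return An object of class \code{delta_regression}.
#' @export
delta_regression <- function(changes, response = c("d_yield", "d_et", "d_wue"),
                             crop = "total", intercept = FALSE,
                             min_rows = 10L) {
  response <- match.arg(response)
  preds <- c("d_tmean", "d_rad", "d_pre", "d_co2")
  df <- as.data.frame(changes)
  df <- df[df$crop == crop & !df$excluded, c(response, preds)]
  df <- df[stats::complete.cases(df), ]
  if (nrow(df) < min_rows)
    stop(sprintf("only %d usable rows (need >= %d)", nrow(df), min_rows),
         call. = FALSE)
  X <- as.matrix(df[preds])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- preds[qrX$pivot[seq(qrX$rank + 1L, ncol(X))]]
    stop(sprintf("rank-deficient design: collinear column(s) %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  fml <- stats::reformulate(c(if (!intercept) "0", preds), response)
  fit <- stats::lm(fml, data = df)
  sm <- summary(fit)
  ct <- sm$coefficients
  keep <- rownames(ct) %in% preds
  stars <- ifelse(ct[keep, 4] < 0.01, "**",
                  ifelse(ct[keep, 4] < 0.05, "*", ""))
  structure(list(
    response = response, crop = crop, n = nrow(df),
    coefficients = data.frame(term = rownames(ct)[keep],
                              estimate = ct[keep, 1],
                              std_error = ct[keep, 2],
                              p_value = ct[keep, 4],
                              stars = stars, row.names = NULL),
    r_squared = sm$r.squared, model = fit, intercept = intercept),
    class = "delta_regression")
}

#' @export
coef.delta_regression <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' @export
print.delta_regression <- function(x, ...) {
  cat(sprintf("Delta regression: %s ~ dTmean + dRad + dPre + dCO2 (%s, n = %d, no intercept%s)\n",
              x$response, x$crop, x$n, if (x$intercept) " + intercept" else ""))
  co <- x$coefficients
  for (i in seq_len(nrow(co)))
    cat(sprintf("  %-8s %12.4f %-2s (p = %.3g)\n", co$term[i], co$estimate[i],
                co$stars[i], co$p_value[i]))
  cat(sprintf("  R^2 = %.3f\n", x$r_squared))
  invisible(x)
}

# the qualitative sign pattern reported for the attribution regressions:
# yield falls with warming, rises with radiation, precipitation and CO2;
# ET rises with radiation and falls with CO2; WUE falls with warming and
# rises with CO2.
expected_sign_pattern <- function() {
  list(d_yield = c(d_tmean = -1, d_rad = 1, d_pre = 1, d_co2 = 1),
       d_et = c(d_rad = 1, d_co2 = -1),
       d_wue = c(d_tmean = -1, d_co2 = 1))
}

#' Sign-concordance report for attribution regressions
#'
#' Compares the signs of significant (p < 0.05) fitted coefficients against
#' the expected qualitative pattern (see \code{expected_sign_pattern});
#' non-significant coefficients are reported but not counted for or against
#' concordance.
#'
#' @param results list of \code{delta_regression} objects.
#' @param pattern expected sign pattern; a named list response -> named
#'   vector of -1/+1 per term.
#' @return A data frame of class \code{sign_report} with one row per
#'   expected cell and a \code{concordance} attribute
#'   (matches / (matches + mismatches)).
#' @export
sign_pattern_report <- function(results, pattern = expected_sign_pattern()) {
  rows <- list()
  for (res in results) {
    exp_signs <- pattern[[res$response]]
    if (is.null(exp_signs)) next
    co <- res$coefficients
    for (term in names(exp_signs)) {
      i <- match(term, co$term)
      sig <- co$p_value[i] < 0.05
      status <- if (!sig) "not_significant"
      else if (sign(co$estimate[i]) == exp_signs[term]) "match" else "mismatch"
      rows[[length(rows) + 1]] <- data.frame(
        response = res$response, crop = res$crop, term = term,
        expected = exp_signs[term], estimate = co$estimate[i],
        p_value = co$p_value[i], status = status, row.names = NULL)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(response = character(), crop = character(), term = character(),
               expected = numeric(), estimate = numeric(),
               p_value = numeric(), status = character())
  nm <- sum(out$status == "match"); nx <- sum(out$status == "mismatch")
  attr(out, "concordance") <- if (nm + nx > 0) nm / (nm + nx) else NA_real_
  class(out) <- c("sign_report", "data.frame")
  out
}

#' @export
print.sign_report <- function(x, ...) {
  cat(sprintf("Sign concordance: %.0f%% (%d match, %d mismatch, %d not significant)\n",
              100 * attr(x, "concordance"), sum(x$status == "match"),
              sum(x$status == "mismatch"), sum(x$status == "not_significant")))
  print.data.frame(x)
  invisible(x)
}
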