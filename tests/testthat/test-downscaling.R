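# IDW interpolation, quantile-quantile bias correction, the conditioned
# generator, and the composed per-model downscaling chain.

test_that("IDW reproduces node values, symmetry and the weight oracle", {
  nodes <- data.frame(lat = c(30, 32), lon = c(117, 117), value = c(10, 20))
  # node exactness
  expect_equal(idw_interpolate(data.frame(lat = 31, lon = 117, value = 7.3),
                               c(31, 117)), 7.3)
  # two equidistant nodes average
  expect_equal(idw_interpolate(nodes, c(31, 117), k_neighbors = 2), 15)
  expect_error(idw_interpolate(nodes[0, ], c(31, 117)), "empty")
  expect_error(idw_interpolate(nodes, c(31, 117), power = 0), "power")
  # brute-force weight oracle on random layouts (independent distance code)
  skip_if_not_installed("geosphere")
  set.seed(101)
  for (rep in 1:100) {
    n <- sample(4:9, 1)
    nd <- data.frame(lat = runif(n, 28, 36), lon = runif(n, 114, 122),
                     value = rnorm(n, 15, 5))
    tg <- c(runif(1, 29, 35), runif(1, 115, 121))
    k <- sample(2:4, 1)
    d <- geosphere::distHaversine(cbind(nd$lon, nd$lat), c(tg[2], tg[1]),
                                  r = 6371008.8)
    sel <- order(d)[seq_len(k)]
    w <- d[sel]^(-2); w <- w / sum(w)
    oracle <- sum(w * nd$value[sel])
    expect_equal(idw_interpolate(nd, tg, power = 2, k_neighbors = k), oracle,
                 tolerance = 1e-12)
  }
})

test_that("qq maps invert shifts and match the quantile oracle", {
  set.seed(5)
  obs <- rnorm(360, 10, 3)
  # identical distributions: identity map at every knot
  m0 <- fit_qq_map(obs, obs, "t", 1, K = 20)
  expect_equal(m0$model_q, m0$obs_q)
  expect_equal(apply_qq_map(m0, obs), obs, tolerance = 1e-9)
  # pure shift: every knot maps x -> x - 2
  m2 <- fit_qq_map(obs, obs + 2, "t", 1, K = 20)
  expect_equal(m2$obs_q, m2$model_q - 2, tolerance = 1e-9)
  expect_equal(apply_qq_map(m2, m2$model_q), m2$model_q - 2, tolerance = 1e-9)
  # knots equal independently computed empirical quantiles
  model <- rgamma(360, 2, 0.5)
  mg <- fit_qq_map(obs, model, "prec", 6, K = 20)
  p <- seq(0, 1, length.out = 20)
  expect_equal(mg$model_q, quantile7_oracle(model, p), tolerance = 1e-12)
  expect_equal(mg$obs_q, quantile7_oracle(obs, p), tolerance = 1e-12)
  # beyond the outermost knot: constant-offset extrapolation
  delta <- 3.7
  expect_equal(apply_qq_map(mg, max(model) + delta),
               max(mg$obs_q) + delta, tolerance = 1e-9)
  expect_equal(apply_qq_map(mg, min(model) - delta),
               min(mg$obs_q) - delta, tolerance = 1e-9)
})

test_that("corrected baseline distributions match observations (KS < 0.05)", {
  set.seed(8)
  obs <- rnorm(360, 12, 2.5)
  model <- rgamma(360, 4, 0.4)           # strongly biased and skewed
  map <- fit_qq_map(obs, model, "t", 1, K = 30)
  corrected <- apply_qq_map(map, model)
  ks <- suppressWarnings(stats::ks.test(corrected, obs)$statistic)
  expect_lt(unname(ks), 0.05)
})

test_that("conditioned generation matches monthly targets exactly", {
  st <- test_station()
  obs <- crop_fixture_series(years = 10)
  wg <- fit_wgen(obs)
  target <- aggregate_monthly(obs)
  gen <- generate_daily_conditioned(wg, target, st, seed = 17)
  back <- aggregate_monthly(gen)
  expect_equal(back$prec_total, target$prec_total, tolerance = 1e-9)
  expect_true(all(abs(back$tmax_mean - target$tmax_mean) < 0.05))
  expect_true(all(abs(back$rad_mean - target$rad_mean) < 1e-6))
  expect_true(all(gen$tmax >= gen$tmin))
  expect_true(all(gen$prec >= 0))
  # zero-precipitation target: all days dry
  t0 <- target[1:2, ]; t0$prec_total <- 0
  g0 <- generate_daily_conditioned(wg, t0, st, seed = 17)
  expect_true(all(g0$prec == 0))
  # determinism under a fixed seed
  gen2 <- generate_daily_conditioned(wg, target, st, seed = 17)
  expect_identical(as.data.frame(gen), as.data.frame(gen2))
})

test_that("conditioned occurrence preserves the wet-wet transition rate", {
  st <- test_station()
  obs <- crop_fixture_series(years = 10)
  wg <- fit_wgen(obs)
  # 1000 generated Januaries from known parameters
  target <- data.frame(year = 1001:2000, month = 1, tmax_mean = 6,
                       tmin_mean = -2, prec_total = 40, rad_mean = 8)
  gen <- generate_daily_conditioned(wg, target, st, seed = 23)
  wet <- gen$prec > 0
  n11 <- sum(wet[-length(wet)] & wet[-1])
  n1 <- sum(wet[-length(wet)])
  expect_lt(abs(n11 / n1 - wg$months$p11[1]), 0.05)
  # invariants on every generated day
  expect_true(all(gen$tmax >= gen$tmin))
  expect_true(all(gen$prec >= 0))
})

test_that("a positive target with a dry chain forces one wet day", {
  st <- test_station()
  obs <- crop_fixture_series(years = 10)
  wg <- fit_wgen(obs)
  dry <- wg
  dry$months$p01[] <- 0; dry$months$p11[] <- 0     # chain can never rain
  target <- data.frame(year = 2001, month = 7, tmax_mean = 30, tmin_mean = 22,
                       prec_total = 120, rad_mean = 15)
  gen <- generate_daily_conditioned(dry, target, st, seed = 2)
  expect_equal(sum(gen$prec), 120, tolerance = 1e-9)
  expect_equal(sum(gen$prec > 0), 1)
  expect_length(attr(gen, "forced_wet"), 1)
})

test_that("the identity pipeline returns the observed monthlies", {
  st <- test_station()
  obs <- crop_fixture_series(years = 10)
  om <- aggregate_monthly(obs)
  # a grid whose every node carries the observed monthly series, no bias
  nodes <- expand.grid(lat = st$latitude + (-1:1), lon = st$longitude + (-1:1))
  nodes$node <- seq_len(nrow(nodes))
  monthly <- do.call(rbind, lapply(nodes$node, function(k) {
    rbind(
      data.frame(window = "baseline", node = k, lat = nodes$lat[k],
                 lon = nodes$lon[k], year = om$year, month = om$month,
                 tmax = om$tmax_mean, tmin = om$tmin_mean,
                 prec = om$prec_total, rad = om$rad_mean),
      data.frame(window = "future", node = k, lat = nodes$lat[k],
                 lon = nodes$lon[k], year = om$year + 60, month = om$month,
                 tmax = om$tmax_mean, tmin = om$tmin_mean,
                 prec = om$prec_total, rad = om$rad_mean))
  }))
  grid <- structure(list(model = "ident", scenario = "NULLSC", nodes = nodes,
                         monthly = monthly,
                         delta = c(t = 0, rad = 0, prec_factor = 1),
                         windows = list(baseline = unique(om$year),
                                        future = unique(om$year) + 60)),
                    class = "gcm_grid")
  ds <- downscale_model(grid, st, obs, seed = 31)
  cm <- ds$monthly[ds$monthly$window == "baseline", ]
  cm <- cm[order(cm$year, cm$month), ]
  omo <- om[order(om$year, om$month), ]
  expect_equal(cm$tmax, omo$tmax_mean, tolerance = 1e-8)
  expect_equal(cm$prec, omo$prec_total, tolerance = 1e-8)
  expect_equal(cm$rad, omo$rad_mean, tolerance = 1e-8)
})

test_that("imposed scenario deltas survive the full downscaling chain", {
  st <- test_station()
  clim <- default_station_climatology("hefei")
  obs <- generate_station_baseline(clim, st, 30, seed = 3)
  wg <- fit_wgen(obs)
  spec <- scenario_spec("TEST", delta_t_mean = 2, delta_t_spread = 0,
                        delta_rad_mean = 0, prec_factor_mean = 1.1,
                        prec_factor_spread = 0, n_models = 2)
  grids <- generate_pseudo_gcm_ensemble(clim, spec, st, seed = 5,
                                        baseline_years = 1981:2010,
                                        future_years = 2041:2070)
  for (g in grids) {
    ds <- downscale_model(g, st, obs, seed = 5, wgen = wg)
    dt <- mean(tmean(ds$future)) - mean(tmean(ds$baseline))
    expect_lt(abs(dt - 2), 0.2)
    pf <- sum(ds$future$prec) / sum(ds$baseline$prec)
    expect_lt(abs(pf / 1.1 - 1), 0.10)
    # all generated days satisfy the series invariants
    expect_true(all(ds$future$tmax >= ds$future$tmin))
    expect_true(all(ds$future$prec >= 0) && all(ds$future$rad >= 0))
  }
  # byte-identical determinism of the whole chain
  ds1 <- downscale_model(grids[[1]], st, obs, seed = 5, wgen = wg)
  ds2 <- downscale_model(grids[[1]], st, obs, seed = 5, wgen = wg)
  expect_identical(as.data.frame(ds1$baseline), as.data.frame(ds2$baseline))
  expect_identical(as.data.frame(ds1$future), as.data.frame(ds2$future))
})

test_that("generator parameters serialise to YAML for replay", {
  obs <- crop_fixture_series(years = 3)
  wg <- fit_wgen(obs)
  f <- tempfile(fileext = ".yaml")
  write_params_yaml(wg, f)
  back <- yaml::read_yaml(f)
  expect_equal(back$months$p11, wg$months$p11, tolerance = 1e-12)
  m <- fit_qq_map(rnorm(50), rnorm(50), "t", 2, K = 10)
  write_params_yaml(m, f)
  back2 <- yaml::read_yaml(f)
  expect_equal(back2$model_q, m$model_q, tolerance = 1e-9)
})
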