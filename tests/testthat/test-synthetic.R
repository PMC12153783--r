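test_that("a zero-variance model yields a constant field and seeds are reproducible", {
  xy <- random_coords(30, 1)
  m0 <- variogram_model("spherical", 0, 0, 1)
  expect_equal(grf_simulate(m0, xy, mean = 3.5, seed = 2), rep(3.5, 30))
  m <- variogram_model("exponential", 0.1, 0.9, 0.4)
  a <- grf_simulate(m, xy, mean = 1, seed = 99)
  b <- grf_simulate(m, xy, mean = 1, seed = 99)
  expect_identical(a, b)
  expect_false(identical(a, grf_simulate(m, xy, mean = 1, seed = 100)))
  expect_error(grf_simulate(m, rbind(c(0, 0), c(0, 0)), seed = 1), "distinct")
})

test_that("simulated fields show the requested spatial structure and variance", {
  set.seed(1234)
  xy <- cbind(runif(2000), runif(2000))
  m <- variogram_model("spherical", 0.1, 0.9, 0.3)
  z <- grf_simulate(m, xy, mean = 0, seed = 777, n_sim = 20)
  vars <- apply(z, 2, var)
  expect_lt(abs(mean(vars) - 1), 0.25)
  g_near <- g_far <- numeric(20)
  for (j in 1:20) {
    ev <- empirical_variogram(xy, z[, j], n_lags = 12, max_dist = 0.6)
    g_near[j] <- ev$gamma[1]          # lag ~ 0.025, well below the range
    g_far[j] <- ev$gamma[12]          # lag ~ 0.575, beyond the range
  }
  expect_true(all(g_near < g_far))
  expect_lt(abs(mean(g_far) - 1), 0.25)
})

test_that("fitting the generating family to a realization recovers the structure", {
  xy <- random_coords(1200, 55)
  truth <- variogram_model("spherical", 0.1, 0.9, 0.3)
  sims <- grf_simulate(truth, xy, seed = 808, n_sim = 6)
  sills <- ranges <- numeric(6)
  for (j in 1:6) {
    fit <- fit_variogram(empirical_variogram(xy, sims[, j]), "spherical")
    sills[j] <- sill(fit); ranges[j] <- fit$range
  }
  expect_lt(abs(median(sills) - 1) / 1, 0.3)
  expect_lt(abs(median(ranges) - 0.3) / 0.3, 0.5)
})

test_that("the climate generator matches its configuration", {
  cfg <- synthetic_config(years = 2018:2019, drought_years = numeric(),
                          tair_gradient = 0, seed = 31)
  f <- generate_climate_series(cfg)
  expect_s3_class(f, "climate_field")
  expect_setequal(unique(f$year), 2018:2019)
  # spatial mean Tair within 3 SE of the base under no gradient/drought;
  # the SE of the mean of a correlated field is sqrt(mean of the
  # covariance matrix), computed from the generating model
  sub0 <- f[f$year == 2018, ]
  Cm <- sill(cfg$variogram) -
    predict(cfg$variogram, pair_distances(cbind(sub0$lon, sub0$lat)))
  diag(Cm) <- sill(cfg$variogram)
  se_mean <- sqrt(mean(Cm))
  for (yr in 2018:2019) {
    sub <- f[f$year == yr, ]
    expect_lt(abs(mean(sub$tair_c) - cfg$base_tair), 3 * se_mean)
  }
  # wind positivity is structural
  expect_gt(min(f$ws_ms), 0)
  expect_lte(max(f$ws_ms), 2.8 + 1e-9)
  # determinism: bit-identical under identical configs
  expect_identical(f, generate_climate_series(cfg))
})

test_that("drought years scale precipitation by the configured multiplier", {
  cfg <- synthetic_config(years = 2012:2017, drought_years = 2014,
                          drought_multiplier = 0.5, seed = 77)
  f <- generate_climate_series(cfg)
  dry <- mean(f$precip_mm[f$year == 2014])
  wet <- mean(f$precip_mm[f$year != 2014])
  # ratio ~ 0.5 within sampling error over ~300 points/year
  expect_lt(abs(dry / wet - 0.5), 0.06)
})

test_that("gamma MLE recovers the generator's precipitation parameters", {
  cfg <- synthetic_config(years = 2020, drought_years = numeric(), seed = 5)
  f <- generate_climate_series(cfg)
  expect_gte(nrow(f), 200)
  fit <- fit_gamma_mle(f$precip_mm)
  expect_lt(abs(fit$alpha - cfg$precip_shape) / cfg$precip_shape, 0.15)
  expect_lt(abs(fit$beta - cfg$precip_scale) / cfg$precip_scale, 0.15)
})

test_that("configuration invariants are enforced", {
  expect_error(synthetic_config(years = integer()), "non-empty")
  expect_error(synthetic_config(grid_step = 0), "grid_step")
  expect_error(synthetic_config(precip_shape = -1), "gamma")
  expect_error(synthetic_config(drought_multiplier = 1.2), "multiplier")
})
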