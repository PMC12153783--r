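test_that("empirical semivariogram matches hand-computed pairs", {
  # two points, equal values: single occupied bin with gamma = 0
  ev <- empirical_variogram(cbind(c(0, 1), c(0, 0)), c(3, 3),
                            n_lags = 4, max_dist = 1)
  occ <- ev[ev$n_pairs > 0, ]
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$gamma, 0)
  # values 0 and 2: gamma = (1/2) * 2^2 / 1 = 2
  ev <- empirical_variogram(cbind(c(0, 1), c(0, 0)), c(0, 2),
                            n_lags = 4, max_dist = 1)
  expect_equal(ev$gamma[ev$n_pairs > 0], 2)
  expect_error(empirical_variogram(cbind(c(1, 1), c(2, 2)), c(0, 1)),
               "degenerate|coincident")
})

test_that("empirical semivariogram equals a double-loop oracle bin by bin", {
  for (seed in c(1, 2, 3)) {
    xy <- random_coords(20, seed)
    z <- rnorm(20)
    md <- max(dist(xy)) / 2
    got <- empirical_variogram(xy, z, n_lags = 6, max_dist = md)
    want <- oracle_semivariogram(xy, z, n_lags = 6, max_dist = md)
    expect_equal(got$n_pairs, want$n_pairs)
    expect_equal(got$gamma, want$gamma, tolerance = 1e-12)
    expect_equal(got$lag, want$lag, tolerance = 1e-12)
  }
})

test_that("model semivariance follows the three closed forms", {
  sph <- variogram_model("spherical", 0.2, 0.8, 2)
  exc <- variogram_model("exponential", 0.2, 0.8, 2)
  gau <- variogram_model("gaussian", 0.2, 0.8, 2)
  # nugget is a discontinuity at the origin
  expect_equal(predict(sph, 0), 0)
  expect_gt(predict(sph, 1e-12), 0.2)
  # sill reached exactly at the range for the spherical model
  expect_equal(predict(sph, 2), 1.0)
  expect_equal(predict(sph, 50), 1.0)
  expect_equal(predict(exc, 2), 0.2 + 0.8 * (1 - exp(-3)))
  expect_equal(predict(gau, 2), 0.2 + 0.8 * (1 - exp(-3)))
  # asymptotic approach to the sill for the other families
  expect_equal(predict(exc, 1e4), 1.0, tolerance = 1e-9)
  expect_equal(predict(gau, 1e4), 1.0, tolerance = 1e-9)
  h <- seq(0.01, 10, by = 0.01)
  for (m in list(sph, exc, gau)) {
    g <- predict(m, h)
    expect_equal(g, vapply(h, function(d)
      oracle_gamma(m$family, 0.2, 0.8, 2, d), numeric(1)), tolerance = 1e-12)
    expect_true(all(diff(g) >= -1e-12))
  }
  expect_error(predict(sph, -1), ">= 0")
})

test_that("noise-free variogram fitting recovers the generating parameters", {
  h <- seq(0.08, 1.2, length.out = 12)
  for (fam in c("spherical", "exponential", "gaussian")) {
    truth <- variogram_model(fam, nugget = 0.12, psill = 0.88, range = 0.45)
    emp <- structure(data.frame(lag = h, gamma = predict(truth, h),
                                n_pairs = rep(50L, 12)),
                     class = c("empirical_variogram", "data.frame"))
    fit <- fit_variogram(emp, fam)
    expect_equal(coef(fit), coef(truth), tolerance = 1e-4)
  }
})

test_that("a flat variogram is fitted as pure nugget", {
  h <- seq(0.1, 1, length.out = 8)
  emp <- structure(data.frame(lag = h, gamma = rep(0.7, 8), n_pairs = rep(10L, 8)),
                   class = c("empirical_variogram", "data.frame"))
  expect_warning(fit <- fit_variogram(emp, "spherical"), "no spatial structure")
  expect_equal(sill(fit), 0.7, tolerance = 1e-6)
  expect_lt(fit$psill, 1e-6)
})

test_that("constructor rejects invalid parameters and few lags", {
  expect_error(variogram_model("spherical", -0.1, 1, 1), "nugget")
  expect_error(variogram_model("spherical", 0, -1, 1), "psill")
  expect_error(variogram_model("spherical", 0, 1, 0), "range")
  emp <- structure(data.frame(lag = c(0.1, 0.2, 0.3), gamma = c(1, 1, 1),
                              n_pairs = c(1L, 1L, 1L)),
                   class = c("empirical_variogram", "data.frame"))
  expect_error(fit_variogram(emp, "spherical"), "4 occupied lags")
})
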