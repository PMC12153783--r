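test_that("LOO cross-validation metrics equal an explicit-loop oracle", {
  for (seed in c(21, 22)) {
    xy <- random_coords(10, seed)
    z <- rnorm(10)
    m <- variogram_model("spherical", 0.1, 0.9, 0.5)
    got <- loo_cv(xy, z, m, n_neighbors = Inf)
    want <- oracle_cv_metrics("spherical", 0.1, 0.9, 0.5, xy, z)
    for (k in c("me", "mse", "ase", "rmse", "rmsse"))
      expect_equal(got[[k]], want[[k]], tolerance = 1e-10)
  }
})

test_that("RMSE dominates the absolute mean error on random data", {
  for (seed in 31:35) {
    xy <- random_coords(12, seed)
    z <- rnorm(12)
    cv <- loo_cv(xy, z, variogram_model("exponential", 0.2, 0.8, 0.4),
                 n_neighbors = Inf)
    expect_gte(cv$rmse, abs(cv$me))
  }
})

test_that("perfect interpolation of a smooth noise-free field gives tiny errors", {
  # near-degenerate limit: smooth gaussian model, dense samples of a
  # very smooth surface
  xy <- as.matrix(expand.grid(seq(0, 1, by = 0.2), seq(0, 1, by = 0.2)))
  z <- 2 + 0.05 * xy[, 1] + 0.03 * xy[, 2]
  cv <- loo_cv(xy, z, variogram_model("gaussian", 1e-6, 1, 3), n_neighbors = Inf)
  expect_lt(abs(cv$me), 1e-3)
  expect_lt(cv$rmse, 1e-2)
})

test_that("model selection follows the RMSSE-closest-to-1 rule with stable ties", {
  mk <- function(rmsse, rmse = 0.13, ase = 0.16)
    structure(list(me = 0, mse = 0, ase = ase, rmse = rmse, rmsse = rmsse,
                   n = 100, pointwise = NULL), class = "loo_cv")
  # reported cross-validation metrics for one year of the THI analysis
  got <- select_model(list(spherical = mk(0.748842232),
                           gaussian = mk(0.657260615),
                           exponential = mk(0.625094344)))
  expect_equal(as.character(got), "spherical")
  rk <- attr(got, "ranking")
  expect_equal(rk$family, c("spherical", "gaussian", "exponential"))
  # identical metrics: fixed family order decides
  tie <- select_model(list(gaussian = mk(0.9), exponential = mk(0.9),
                           spherical = mk(0.9)))
  expect_equal(as.character(tie), "spherical")
  # ties on RMSSE broken by |RMSE - ASE|
  g <- select_model(list(spherical = mk(0.9, rmse = 0.13, ase = 0.20),
                         gaussian = mk(0.9, rmse = 0.13, ase = 0.14)))
  expect_equal(as.character(g), "gaussian")
  expect_equal(as.character(select_model(list(gaussian = mk(0.5)))), "gaussian")
  expect_error(select_model(list()), "empty")
})

test_that("degree of spatial dependence reproduces the nugget-to-sill ratio", {
  # strong dependence, published parameter pairs
  m <- variogram_model("spherical", 0.007121, 0.4263 - 0.007121, 9000)
  d <- dsd(m)
  expect_equal(round(d$dsd_percent, 3), 1.670)
  expect_equal(d$dsd_class, "strong")
  expect_equal(dsd(variogram_model("spherical", 0, 1, 1))$dsd_percent, 0)
  w <- dsd(variogram_model("spherical", 1, 0, 1))
  expect_equal(w$dsd_percent, 100)
  expect_equal(w$dsd_class, "weak")
  expect_equal(dsd(variogram_model("spherical", 1, 1, 1))$dsd_class, "moderate")
  # scale invariance
  a <- dsd(variogram_model("exponential", 0.3, 0.7, 2))
  b <- dsd(variogram_model("exponential", 0.3 * 17, 0.7 * 17, 2))
  expect_equal(a, b)
})

test_that("DSD boundary values class as strong/moderate/weak bands", {
  mk <- function(p) variogram_model("spherical", p, 100 - p, 1)
  expect_equal(dsd(mk(24.999))$dsd_class, "strong")
  expect_equal(dsd(mk(25))$dsd_class, "moderate")
  expect_equal(dsd(mk(75))$dsd_class, "moderate")
  expect_equal(dsd(mk(75.001))$dsd_class, "weak")
})

test_that("residual normality check holds its level and detects skew", {
  level <- power <- logical(50)
  for (s in 1:50) {
    set.seed(s)
    level[s] <- residual_normality(rnorm(100))$p_value > 0.05
    power[s] <- residual_normality(rlnorm(100, sdlog = 1))$p_value < 0.05
  }
  expect_gte(mean(level), 0.9)
  expect_gte(mean(power), 0.9)
  expect_error(residual_normality(rep(1, 20)), "constant|variance")
  expect_error(residual_normality(rnorm(2)), "between 3 and 5000")
})
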