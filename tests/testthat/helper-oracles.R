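# Brute-force oracles, coded independently of the package internals.

# Double-loop method-of-moments semivariogram.
oracle_semivariogram <- function(coords, values, n_lags, max_dist) {
  n <- nrow(coords)
  breaks <- seq(0, max_dist, length.out = n_lags + 1)
  ssum <- npair <- numeric(n_lags)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
    if (d <= 0 || d > max_dist) next
    b <- max(1L, min(n_lags, findInterval(d, breaks, rightmost.closed = TRUE)))
    ssum[b] <- ssum[b] + (values[i] - values[j])^2
    npair[b] <- npair[b] + 1
  }
  data.frame(lag = (breaks[-1] + breaks[-(n_lags + 1)]) / 2,
             gamma = ifelse(npair > 0, ssum / (2 * npair), NA_real_),
             n_pairs = npair)
}

# Semivariance evaluated from first principles per family.
oracle_gamma <- function(family, c0, c, a, h) {
  if (h == 0) return(0)
  switch(family,
    spherical = if (h > a) c0 + c else c0 + c * (1.5 * h / a - 0.5 * (h / a)^3),
    exponential = c0 + c * (1 - exp(-3 * h / a)),
    gaussian = c0 + c * (1 - exp(-3 * h^2 / a^2)))
}

# Direct global ordinary-kriging solve for one target (explicit loops).
oracle_krige <- function(family, c0, c, a, coords, values, target) {
  n <- nrow(coords)
  A <- matrix(0, n + 1, n + 1)
  for (i in 1:n) for (j in 1:n) if (i != j)
    A[i, j] <- oracle_gamma(family, c0, c, a,
                            sqrt(sum((coords[i, ] - coords[j, ])^2)))
  A[n + 1, 1:n] <- 1; A[1:n, n + 1] <- 1
  b <- numeric(n + 1)
  for (i in 1:n)
    b[i] <- oracle_gamma(family, c0, c, a,
                         sqrt(sum((coords[i, ] - target)^2)))
  b[n + 1] <- 1
  sol <- solve(A, b)
  lambda <- sol[1:n]
  list(estimate = sum(lambda * values),
       variance = sum(lambda * b[1:n]) + sol[n + 1],
       weights = lambda)
}

# Explicit-loop leave-one-out cross-validation metrics.
oracle_cv_metrics <- function(family, c0, c, a, coords, values) {
  n <- nrow(coords)
  err <- sig <- numeric(n)
  for (i in 1:n) {
    o <- oracle_krige(family, c0, c, a, coords[-i, , drop = FALSE],
                      values[-i], coords[i, ])
    err[i] <- o$estimate - values[i]
    sig[i] <- sqrt(max(o$variance, 0))
  }
  me <- 0; mse <- 0; ase <- 0; sse <- 0; ssse <- 0
  for (i in 1:n) {
    me <- me + err[i] / n
    mse <- mse + (err[i] / sig[i]) / n
    ase <- ase + sig[i] / n
    sse <- sse + err[i]^2 / n
    ssse <- ssse + (err[i] / sig[i])^2 / n
  }
  list(me = me, mse = mse, ase = ase, rmse = sqrt(sse), rmsse = sqrt(ssse))
}

random_coords <- function(n, seed) {
  set.seed(seed)
  cbind(runif(n), runif(n))
}
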