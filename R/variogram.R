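#' Isotropic variogram model
#'
#' Parametric semivariogram with a nugget discontinuity at the origin:
#' `gamma(0) = 0` exactly, and for `h > 0` the semivariance rises from the
#' nugget `C0` towards the sill `C0 + C`. Three families are supported:
#'
#' * spherical: `C0 + C * (1.5 (h/a) - 0.5 (h/a)^3)` for `0 < h <= a`,
#'   `C0 + C` beyond the range `a`;
#' * exponential: `C0 + C * (1 - exp(-3 h / a))` (practical range `a`);
#' * gaussian: `C0 + C * (1 - exp(-3 h^2 / a^2))`.
#'
#' @param family `"spherical"`, `"exponential"` or `"gaussian"`.
#' @param nugget nugget variance `C0` (>= 0).
#' @param psill partial sill `C` (>= 0); the total sill is `nugget + psill`.
#' @param range range parameter `a` (> 0), in the distance-metric units.
#' @return object of class `"variogram_model"`.
#' @examples
#' m <- variogram_model("spherical", nugget = 0.1, psill = 0.9, range = 3)
#' predict(m, h = c(0, 1.5, 3, 10))
#' @export
variogram_model <- function(family = c("spherical", "exponential", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot(is.numeric(nugget), is.numeric(psill), is.numeric(range),
            length(nugget) == 1L, length(psill) == 1L, length(range) == 1L)
  if (!is.finite(nugget) || nugget < 0) stop("'nugget' must be finite and >= 0")
  if (!is.finite(psill) || psill < 0) stop("'psill' must be finite and >= 0")
  if (!is.finite(range) || range <= 0) stop("'range' must be finite and > 0")
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range),
            class = "variogram_model")
}

#' Model semivariance at given distances
#'
#' @param object a [variogram_model()].
#' @param h vector of non-negative distances.
#' @param ... unused.
#' @return semivariances `gamma(h)`; `gamma(0) = 0` exactly.
#' @export
predict.variogram_model <- function(object, h, ...) {
  if (any(!is.finite(h)) || any(h < 0)) stop("distances must be finite and >= 0")
  C0 <- object$nugget; C <- object$psill; a <- object$range
  g <- switch(object$family,
    spherical = {
      u <- pmin(h / a, 1)
      C0 + C * (1.5 * u - 0.5 * u^3)
    },
    exponential = C0 + C * (1 - exp(-3 * h / a)),
    gaussian    = C0 + C * (1 - exp(-3 * h^2 / a^2)))
  g[h == 0] <- 0
  g
}

#' Total sill of a variogram model
#' @param object a [variogram_model()].
#' @return `nugget + psill`.
#' @export
sill <- function(object) object$nugget + object$psill

#' @export
print.variogram_model <- function(x, ...) {
  cat(sprintf("%s variogram: nugget %.6g, partial sill %.6g, range %.6g (sill %.6g)\n",
              x$family, x$nugget, x$psill, x$range, sill(x)))
  if (!is.null(x$wsse))
    cat(sprintf("  fitted by N(h)-weighted least squares, weighted SSE %.6g\n", x$wsse))
  invisible(x)
}

#' @export
coef.variogram_model <- function(object, ...) {
  c(nugget = object$nugget, psill = object$psill, range = object$range)
}

#' Experimental (empirical) semivariogram
#'
#' Method-of-moments estimator: point pairs are binned by separation
#' distance into `n_lags` equal-width bins up to `max_dist`, and per bin
#' `gamma = sum((z_i - z_j)^2) / (2 N)` over the `N` pairs it contains.
#'
#' @param coords two-column matrix/data frame of point locations.
#' @param values numeric vector of the regionalized variable, one per point.
#' @param n_lags number of distance bins.
#' @param max_dist largest separation considered; default half the maximum
#'   pairwise distance, the conventional reliable-lag cutoff.
#' @param metric distance metric, see [pair_distances()].
#' @return object of class `"empirical_variogram"`: data frame with
#'   `lag` (bin center), `gamma` (NA for empty bins) and `n_pairs`.
#' @export
empirical_variogram <- function(coords, values, n_lags = 12, max_dist = NULL,
                                metric = c("planar", "equirectangular", "greatcircle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  if (nrow(coords) < 2L) stop("need at least 2 points")
  if (length(values) != nrow(coords)) stop("'values' length must match 'coords'")
  if (any(!is.finite(values))) stop("'values' must be finite")
  dm <- pair_distances(coords, metric = metric)
  d <- dm[lower.tri(dm)]
  if (all(d == 0)) stop("all points are coincident: degenerate geometry")
  if (is.null(max_dist)) max_dist <- max(d) / 2
  if (max_dist <= 0) stop("'max_dist' must be > 0")
  sq <- as.matrix(stats::dist(values))^2
  s <- sq[lower.tri(sq)]
  keep <- d > 0 & d <= max_dist
  bin <- findInterval(d[keep], seq(0, max_dist, length.out = n_lags + 1L),
                      rightmost.closed = TRUE, all.inside = TRUE)
  n_pairs <- tabulate(bin, nbins = n_lags)
  ssum <- vapply(seq_len(n_lags), function(b) sum(s[keep][bin == b]), numeric(1))
  gamma <- ifelse(n_pairs > 0, ssum / (2 * n_pairs), NA_real_)
  width <- max_dist / n_lags
  out <- data.frame(lag = width * (seq_len(n_lags) - 0.5),
                    gamma = gamma, n_pairs = n_pairs)
  structure(out, class = c("empirical_variogram", "data.frame"),
            metric = metric, max_dist = max_dist)
}

#' @export
plot.empirical_variogram <- function(x, model = NULL, ...) {
  graphics::plot(x$lag, x$gamma, xlab = "lag distance h",
                 ylab = expression(gamma(h)), pch = 16, ...)
  if (!is.null(model)) {
    hh <- seq(1e-9, max(x$lag), length.out = 200)
    graphics::lines(hh, predict(model, hh))
  }
  invisible(x)
}

#' Fit a variogram model to an experimental semivariogram
#'
#' Weighted least squares with the pair counts `N(h)` as weights. For a
#' fixed range the model is linear in `(C0, C)`, so those are profiled out
#' by constrained (non-negative) weighted linear least squares and the
#' range alone is optimized by a grid search refined with
#' [stats::optimize()]. This makes noise-free recovery exact to optimizer
#' tolerance and keeps flat (pure-nugget) variograms well-defined.
#'
#' @param emp an [empirical_variogram()] with at least 4 occupied lags.
#' @param family variogram family to fit.
#' @param range_grid optional candidate ranges searched before refinement;
#'   default 80 points spanning (0, 3 * max lag].
#' @return a `"variogram_model"` (subclass `"variogram_fit"`) with the
#'   weighted SSE in `$wsse` and the data in `$emp`. If no spatial
#'   structure is found (partial sill ~ 0) a warning is issued and a
#'   pure-nugget model returned.
#' @export
fit_variogram <- function(emp, family = c("spherical", "exponential", "gaussian"),
                          range_grid = NULL) {
  family <- match.arg(family)
  stopifnot(inherits(emp, "empirical_variogram"))
  ok <- emp$n_pairs > 0 & !is.na(emp$gamma)
  if (sum(ok) < 4L) stop("need at least 4 occupied lags to fit")
  h <- emp$lag[ok]; y <- emp$gamma[ok]; w <- emp$n_pairs[ok]

  base_shape <- function(u) switch(family,
    spherical   = ifelse(u >= 1, 1, 1.5 * u - 0.5 * u^3),
    exponential = 1 - exp(-3 * u),
    gaussian    = 1 - exp(-3 * u^2))
  # constrained WLS for (C0, C) at fixed range; returns weighted SSE
  prof <- function(a) {
    g <- base_shape(h / a)
    sw <- sum(w); swg <- sum(w * g); swgg <- sum(w * g^2)
    swy <- sum(w * y); swgy <- sum(w * g * y)
    det <- sw * swgg - swg^2
    if (det > .Machine$double.eps * sw * swgg) {
      c0 <- (swgg * swy - swg * swgy) / det
      cc <- (sw * swgy - swg * swy) / det
    } else { c0 <- -1; cc <- -1 }   # collinear -> fall through to boundary
    if (c0 < 0 || cc < 0) {
      # boundary solutions: C = 0 (pure nugget) preferred on ties, or C0 = 0
      cand <- list(c(max(swy / sw, 0), 0), c(0, max(swgy / swgg, 0)))
      sse <- vapply(cand, function(p) sum(w * (y - p[1] - p[2] * g)^2), numeric(1))
      p <- cand[[which.min(sse)]]
      c0 <- p[1]; cc <- p[2]
    }
    list(sse = sum(w * (y - c0 - cc * g)^2), c0 = c0, c = cc)
  }
  if (is.null(range_grid))
    range_grid <- seq(max(h) * 3 / 80, max(h) * 3, length.out = 80)
  sse_grid <- vapply(range_grid, function(a) prof(a)$sse, numeric(1))
  i <- which.min(sse_grid)
  lo <- range_grid[max(i - 1L, 1L)]; hi <- range_grid[min(i + 1L, length(range_grid))]
  a_hat <- if (hi > lo)
    stats::optimize(function(a) prof(a)$sse, c(lo, hi), tol = 1e-10)$minimum
  else range_grid[i]
  if (prof(range_grid[i])$sse < prof(a_hat)$sse) a_hat <- range_grid[i]
  fit <- prof(a_hat)
  if (fit$c <= 1e-10 * max(fit$c0, 1e-300))
    warning("no spatial structure detected: fitting a pure-nugget model",
            call. = FALSE)
  out <- variogram_model(family, nugget = fit$c0, psill = fit$c, range = a_hat)
  out$wsse <- fit$sse
  out$emp <- emp
  class(out) <- c("variogram_fit", class(out))
  out
}

#' @export
plot.variogram_fit <- function(x, ...) plot(x$emp, model = x, ...)
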