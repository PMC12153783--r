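#' Simulate a stationary Gaussian random field
#'
#' Draws realizations of a zero-mean-plus-constant Gaussian field whose
#' theoretical variogram is `model`, by dense Cholesky factorization of
#' the covariance matrix `C(h) = (C0 + C) - gamma(h)` (total sill on the
#' diagonal, so the nugget acts as independent white noise per location).
#' Exact for desk-scale point sets; the dense factorization is intended
#' for up to ~5000 locations.
#'
#' @param model a [variogram_model()] (the generating covariance).
#' @param coords two-column matrix of distinct locations.
#' @param mean constant field mean.
#' @param seed optional integer seed (RNG state is restored on exit).
#' @param n_sim number of independent realizations.
#' @param metric distance metric, see [pair_distances()].
#' @return numeric vector (`n_sim = 1`) or matrix with one column per
#'   realization. Identical inputs and seed give identical output.
#' @examples
#' m <- variogram_model("spherical", 0.1, 0.9, 0.3)
#' z <- grf_simulate(m, cbind(runif(50), runif(50)), mean = 1, seed = 7)
#' @export
grf_simulate <- function(model, coords, mean = 0, seed = NULL, n_sim = 1,
                         metric = c("planar", "equirectangular", "greatcircle")) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "variogram_model"))
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (anyDuplicated(coords)) stop("locations must be distinct")
  U <- .grf_factor(model, coords, metric)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  z <- mean + crossprod(U, matrix(stats::rnorm(n * n_sim), n, n_sim))
  if (n_sim == 1L) as.numeric(z) else z
}

# Cholesky factor (upper) of the covariance implied by a variogram model.
.grf_factor <- function(model, coords, metric) {
  s <- sill(model)
  Cm <- s - predict(model, pair_distances(coords, metric = metric))
  diag(Cm) <- s
  if (s == 0) return(matrix(0, nrow(Cm), ncol(Cm)))
  U <- tryCatch(chol(Cm), error = function(e) NULL)
  if (is.null(U))  # tiny ridge for numerically semi-definite cases
    U <- tryCatch(chol(Cm + diag(1e-10 * s, nrow(Cm))), error = function(e)
      stop("covariance matrix not positive definite: invalid model/locations",
           call. = FALSE))
  U
}

#' Configuration for the synthetic climate-field generator
#'
#' Defaults emulate the statistical shape of an annual tropical climate
#' grid over a Maranhao-sized domain: a warm mean state with a
#' north-positive latitudinal temperature gradient, spatially
#' autocorrelated temperature and wind fields, gamma-distributed annual
#' precipitation centred on 1623 mm, and injected drought years that
#' scale precipitation down and shift temperature up.
#'
#' @param grid_extent list with `lon` and `lat` length-2 ranges (degrees).
#' @param grid_step grid spacing in degrees (> 0).
#' @param years calendar years to generate (non-empty).
#' @param seed integer RNG seed.
#' @param base_tair mean air temperature, deg C.
#' @param tair_gradient deg C change per degree latitude (positive =
#'   warmer northwards).
#' @param variogram generating [variogram_model()] for the temperature
#'   field (units: degrees under the default planar metric).
#' @param ws_variogram generating model for the log-wind field.
#' @param precip_shape,precip_scale gamma parameters of annual
#'   precipitation (mm); both > 0.
#' @param drought_years subset of `years` treated as droughts.
#' @param drought_multiplier precipitation multiplier in drought years,
#'   in (0, 1).
#' @param drought_tair_offset deg C added to Tair in drought years.
#' @param metric distance metric used for field synthesis.
#' @return object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(grid_extent = list(lon = c(-48.5, -41.5),
                                                lat = c(-10.5, -1.0)),
                             grid_step = 0.5,
                             years = 2012:2023,
                             seed = 1L,
                             base_tair = 27.3,
                             tair_gradient = 0.35,
                             variogram = variogram_model("spherical",
                               nugget = 0.005, psill = 0.35, range = 2.5),
                             ws_variogram = variogram_model("exponential",
                               nugget = 0.002, psill = 0.08, range = 2.0),
                             precip_shape = 8,
                             precip_scale = 1623 / 8,
                             drought_years = c(2012, 2015, 2016, 2023),
                             drought_multiplier = 0.65,
                             drought_tair_offset = 0.3,
                             metric = "planar") {
  if (length(years) < 1L) stop("'years' must be non-empty")
  if (grid_step <= 0) stop("'grid_step' must be > 0")
  if (precip_shape <= 0 || precip_scale <= 0)
    stop("gamma precipitation parameters must be > 0")
  if (drought_multiplier <= 0 || drought_multiplier >= 1)
    stop("'drought_multiplier' must be in (0, 1)")
  stopifnot(inherits(variogram, "variogram_model"),
            inherits(ws_variogram, "variogram_model"))
  structure(list(grid_extent = grid_extent, grid_step = grid_step,
                 years = years, seed = as.integer(seed),
                 base_tair = base_tair, tair_gradient = tair_gradient,
                 variogram = variogram, ws_variogram = ws_variogram,
                 precip_shape = precip_shape, precip_scale = precip_scale,
                 drought_years = intersect(drought_years, years),
                 drought_multiplier = drought_multiplier,
                 drought_tair_offset = drought_tair_offset,
                 metric = metric),
            class = "synthetic_config")
}

#' Generate a synthetic multi-year climate field
#'
#' Per year: `Tair = base + gradient * (lat - mean(lat)) + GRF`
#' (+ offset in drought years); wind speed is `exp(GRF)` rescaled into
#' the 0.7-2.8 m/s band so positivity is structural; annual
#' precipitation is drawn per point from the configured gamma law
#' (times the drought multiplier in drought years). Points are labelled
#' `north` / `central` / `south` by latitude terciles. Bit-identical
#' under the same configuration.
#'
#' @param config a [synthetic_config()].
#' @return a `climate_field` data frame: `id`, `lon`, `lat`, `year`,
#'   `tair_c`, `ws_ms`, `precip_mm`, `region`.
#' @examples
#' f <- generate_climate_series(synthetic_config(years = 2012:2013))
#' head(f)
#' @export
generate_climate_series <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  lon <- seq(config$grid_extent$lon[1], config$grid_extent$lon[2],
             by = config$grid_step)
  lat <- seq(config$grid_extent$lat[1], config$grid_extent$lat[2],
             by = config$grid_step)
  pts <- expand.grid(lon = lon, lat = lat, KEEP.OUT.ATTRS = FALSE)
  n <- nrow(pts)
  U_t <- .grf_factor(config$variogram, as.matrix(pts), config$metric)
  U_w <- .grf_factor(config$ws_variogram, as.matrix(pts), config$metric)

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  tcl <- stats::quantile(pts$lat, c(1 / 3, 2 / 3))
  region <- ifelse(pts$lat > tcl[2], "north",
                   ifelse(pts$lat > tcl[1], "central", "south"))
  rows <- vector("list", length(config$years))
  for (k in seq_along(config$years)) {
    yr <- config$years[k]
    dry <- yr %in% config$drought_years
    tair <- config$base_tair +
      config$tair_gradient * (pts$lat - mean(pts$lat)) +
      as.numeric(crossprod(U_t, stats::rnorm(n))) +
      if (dry) config$drought_tair_offset else 0
    e <- exp(as.numeric(crossprod(U_w, stats::rnorm(n))))
    ws <- if (diff(range(e)) > 0)
      0.7 + 2.1 * (e - min(e)) / (max(e) - min(e)) else rep(1.4, n)
    precip <- stats::rgamma(n, shape = config$precip_shape,
                            scale = config$precip_scale) *
      if (dry) config$drought_multiplier else 1
    rows[[k]] <- data.frame(id = seq_len(n), lon = pts$lon, lat = pts$lat,
                            year = yr, tair_c = tair, ws_ms = ws,
                            precip_mm = precip, region = region)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("climate_field", "data.frame"))
}
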