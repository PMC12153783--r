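#' Descriptive statistics with coefficient of variation
#'
#' @param values numeric vector, n >= 2.
#' @return list with `mean`, `min`, `max`, `sd` (sample, n-1 denominator),
#'   `cv` (percent, `100 * sd / mean`; `NA` with `cv_undefined = TRUE`
#'   when the mean is zero with nonzero spread) and `cv_class`.
#' @examples
#' descriptive_stats(c(77.8, 76.1, 79.2))
#' @export
descriptive_stats <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (any(!is.finite(values))) stop("'values' must be finite")
  m <- mean(values); s <- stats::sd(values)
  undef <- m == 0 && s > 0
  cv <- if (undef) NA_real_ else if (s == 0) 0 else 100 * s / m
  list(mean = m, min = min(values), max = max(values), sd = s,
       cv = cv, cv_undefined = undef,
       cv_class = if (undef) NA_character_ else as.character(classify_cv(cv)))
}

#' Scenario specification for climate projections
#'
#' @param pathway emission pathway, `"RCP4.5"` or `"RCP8.5"`.
#' @param horizon `"short"` (2011-2040), `"mid"` (2041-2070) or `"long"`
#'   (2071-2100).
#' @param fields data frame with `id`, `lon`, `lat`, `tair_c`, `ws_ms`
#'   per point.
#' @return object of class `"scenario_spec"`.
#' @export
scenario_spec <- function(pathway, horizon, fields) {
  if (!pathway %in% c("RCP4.5", "RCP8.5"))
    stop("unknown pathway: ", pathway, " (expected RCP4.5 or RCP8.5)")
  if (!horizon %in% c("short", "mid", "long"))
    stop("unknown horizon: ", horizon, " (expected short, mid or long)")
  need <- c("id", "lon", "lat", "tair_c", "ws_ms")
  miss <- setdiff(need, names(fields))
  if (length(miss)) stop("scenario fields missing column(s): ",
                         paste(miss, collapse = ", "))
  structure(list(pathway = pathway, horizon = horizon, fields = fields),
            class = "scenario_spec")
}

# One analysis layer: indices -> variograms -> selection -> kriging ->
# classification. Shared by the historical and scenario pathways.
.zone_layer <- function(coords, tair, ws, np_levels, grid, thi_formula,
                        families, n_lags, n_neighbors, metric, cv_max_n,
                        krige_mode) {
  thi_pt <- as.numeric(thi(tair, ws, formula = thi_formula))
  dmp_pt <- lapply(np_levels, function(np) milk_loss(np, thi_pt)$dmp)
  names(dmp_pt) <- paste0("PL", np_levels)

  stats <- descriptive_stats(thi_pt)

  if (stats::sd(thi_pt) == 0) {
    # degenerate constant field: no spatial structure to model; surfaces
    # are the constant and the dependence diagnostics are undefined
    model <- variogram_model(families[1], nugget = 0, psill = 0, range = 1)
    fits <- stats::setNames(rep(list(model), length(families)), families)
    cvs <- NULL
    sel <- structure(families[1], ranking = data.frame(
      family = families, rmsse = NA_real_, rmse = NA_real_, ase = NA_real_,
      me = NA_real_, mse = NA_real_, dev1 = NA_real_, gap = NA_real_))
    dep <- list(dsd_percent = NA_real_, dsd_class = NA_character_)
  } else {
    # cross-validate the three families on (a deterministic subsample of)
    # the THI point data
    idx <- seq_len(nrow(coords))
    if (length(idx) > cv_max_n)
      idx <- unique(round(seq(1, length(idx), length.out = cv_max_n)))
    emp <- empirical_variogram(coords, thi_pt, n_lags = n_lags, metric = metric)
    fits <- lapply(families, function(f) fit_variogram(emp, f))
    names(fits) <- families
    cvs <- lapply(fits, function(m)
      loo_cv(coords[idx, , drop = FALSE], thi_pt[idx], m,
             n_neighbors = n_neighbors, metric = metric))
    sel <- select_model(cvs)
    model <- fits[[sel]]
    dep <- dsd(model)
  }

  krige_surf <- function(vals, mdl) {
    p <- krige(mdl, coords, vals, grid, n_neighbors = n_neighbors,
               metric = metric)
    data.frame(lon = grid[, 1], lat = grid[, 2],
               estimate = p$estimate, std_error = p$std_error)
  }
  refit <- function(vals) {
    e <- empirical_variogram(coords, vals, n_lags = n_lags, metric = metric)
    suppressWarnings(fit_variogram(e, sel))
  }
  if (krige_mode == "index") {
    thi_surf <- krige_surf(thi_pt, model)
    dmp_surf <- lapply(seq_along(np_levels), function(i)
      krige_surf(dmp_pt[[i]], refit(dmp_pt[[i]])))
  } else {  # krige Tair and Ws, then apply the index on the grid
    tair_g <- krige_surf(tair, refit(tair))
    ws_g <- krige_surf(ws, refit(ws))
    thi_g <- as.numeric(thi(tair_g$estimate, pmax(ws_g$estimate, 0),
                            formula = thi_formula))
    thi_surf <- data.frame(lon = grid[, 1], lat = grid[, 2],
                           estimate = thi_g, std_error = NA_real_)
    dmp_surf <- lapply(np_levels, function(np)
      data.frame(lon = grid[, 1], lat = grid[, 2],
                 estimate = milk_loss(np, thi_g)$dmp, std_error = NA_real_))
  }
  names(dmp_surf) <- paste0("PL", np_levels)

  frac <- function(f) {
    tab <- table(f)
    as.numeric(tab) / sum(tab)
  }
  lwsi_f <- classify_lwsi(thi_surf$estimate)
  dairy_f <- classify_dairy_stress(thi_surf$estimate)
  fractions <- rbind(
    data.frame(scheme = "lwsi", class = levels(lwsi_f), fraction = frac(lwsi_f)),
    data.frame(scheme = "dairy", class = levels(dairy_f), fraction = frac(dairy_f)))

  list(thi_pt = thi_pt, dmp_pt = dmp_pt, stats = stats, fits = fits,
       cvs = cvs, selected = as.character(sel),
       ranking = attr(sel, "ranking"), dsd = dep,
       thi_surface = thi_surf, dmp_surfaces = dmp_surf,
       fractions = fractions)
}

#' Run the bioclimatic zoning analysis
#'
#' For every year in the input field: compute per-point THI and milk-loss
#' (one column per production level), summarize THI dispersion, fit the
#' three variogram families to the THI semivariogram, choose the family
#' by leave-one-out cross-validation ([select_model()]), interpolate THI
#' and milk-loss surfaces by ordinary kriging onto the output grid, and
#' classify the surfaces into heat-safety (LWSI) and dairy-stress area
#' fractions. Fully deterministic for a given input and configuration.
#'
#' @param field a `climate_field` (see [read_points()] /
#'   [generate_climate_series()]).
#' @param np_levels potential production levels, kg/day/cow.
#' @param thi_formula THI registry key (see [thi_formulas()]).
#' @param grid optional two-column matrix of target locations; default is
#'   the set of input point locations (native spacing).
#' @param families variogram families to compare.
#' @param n_lags,n_neighbors,metric geostatistical settings, see
#'   [empirical_variogram()] and [krige()].
#' @param cv_max_n cap on points entering leave-one-out cross-validation
#'   (deterministic evenly-spaced subsample beyond it).
#' @param krige_mode `"index"` interpolates the per-point indices
#'   (index-then-krige, the default); `"variable"` interpolates Tair and
#'   Ws and applies the index formulas on the grid.
#' @param include_spi add a regional SPI analysis when precipitation and
#'   region columns are present.
#' @param out_dir optional directory: report tables, JSON and `.asc`
#'   rasters are written there.
#' @param verbose log the settings and per-year selections.
#' @return object of class `"zoning_report"`: tables `descriptive`,
#'   `cross_validation`, `spatial_dependence`, `area_fractions`,
#'   `milk_loss`; per-year `surfaces` and point-level `points`; optional
#'   `spi`; and `settings`.
#' @export
run_zoning <- function(field, np_levels = c(10, 25), thi_formula = "silva",
                       grid = NULL,
                       families = c("spherical", "exponential", "gaussian"),
                       n_lags = 12, n_neighbors = 16, metric = "planar",
                       cv_max_n = 400, krige_mode = c("index", "variable"),
                       include_spi = TRUE, out_dir = NULL, verbose = FALSE) {
  krige_mode <- match.arg(krige_mode)
  need <- c("id", "lon", "lat", "year", "tair_c", "ws_ms")
  miss <- setdiff(need, names(field))
  if (length(miss)) stop("field missing column(s): ", paste(miss, collapse = ", "))
  years <- sort(unique(field$year))
  if (length(years) < 1L) stop("need at least one year of data")
  if (verbose)
    message(sprintf("zoning: formula=%s metric=%s n_lags=%d n_neighbors=%s mode=%s",
                    thi_formula, metric, n_lags, format(n_neighbors), krige_mode))

  desc <- cvtab <- dsdtab <- fr <- ml <- list()
  surfaces <- points <- list()
  for (yr in years) {
    sub <- field[field$year == yr, ]
    if (anyDuplicated(sub$id)) stop("duplicate point ids within year ", yr)
    coords <- as.matrix(sub[, c("lon", "lat")])
    if (is.null(grid)) grid_y <- coords else grid_y <- as.matrix(grid)
    lay <- .zone_layer(coords, sub$tair_c, sub$ws_ms, np_levels, grid_y,
                       thi_formula, families, n_lags, n_neighbors, metric,
                       cv_max_n, krige_mode)
    if (verbose)
      message(sprintf("  %s: selected %s (RMSSE %s)", yr, lay$selected,
                      paste(sprintf("%s=%.3f", lay$ranking$family,
                                    lay$ranking$rmsse), collapse = " ")))
    s <- lay$stats
    desc[[length(desc) + 1L]] <- data.frame(
      year = yr, mean = s$mean, min = s$min, max = s$max, sd = s$sd,
      cv = s$cv, cv_class = s$cv_class, thi_formula = thi_formula)
    rk <- lay$ranking
    cvtab[[length(cvtab) + 1L]] <- data.frame(
      year = yr, family = rk$family, me = rk$me, mse = rk$mse, ase = rk$ase,
      rmse = rk$rmse, rmsse = rk$rmsse, selected = rk$family == lay$selected)
    m <- lay$fits[[lay$selected]]
    dsdtab[[length(dsdtab) + 1L]] <- data.frame(
      year = yr, family = lay$selected, nugget = m$nugget, psill = m$psill,
      sill = sill(m), range = m$range, dsd_percent = lay$dsd$dsd_percent,
      dsd_class = lay$dsd$dsd_class)
    fr[[length(fr) + 1L]] <- cbind(year = yr, lay$fractions)
    for (i in seq_along(np_levels)) {
      v <- lay$dmp_surfaces[[i]]$estimate
      ml[[length(ml) + 1L]] <- data.frame(
        year = yr, np = np_levels[i], mean_dmp = mean(v), max_dmp = max(v),
        frac_affected = mean(v > 0))
    }
    surfaces[[as.character(yr)]] <- c(list(thi = lay$thi_surface),
                                      lay$dmp_surfaces)
    pt <- data.frame(sub[, c("id", "lon", "lat", "year")], thi = lay$thi_pt)
    for (i in seq_along(np_levels))
      pt[[paste0("dmp_pl", np_levels[i])]] <- lay$dmp_pt[[i]]
    points[[as.character(yr)]] <- pt
  }

  spi <- NULL
  if (include_spi && all(c("precip_mm", "region") %in% names(field)) &&
      length(years) >= 2L)
    spi <- tryCatch(spi_by_region(field), error = function(e) NULL)

  report <- structure(list(
    descriptive = do.call(rbind, desc),
    cross_validation = do.call(rbind, cvtab),
    spatial_dependence = do.call(rbind, dsdtab),
    area_fractions = do.call(rbind, fr),
    milk_loss = do.call(rbind, ml),
    surfaces = surfaces, points = do.call(rbind, points), spi = spi,
    settings = list(thi_formula = thi_formula, metric = metric,
                    n_lags = n_lags, n_neighbors = n_neighbors,
                    cv_max_n = cv_max_n, krige_mode = krige_mode,
                    families = families, np_levels = np_levels)),
    class = "zoning_report")
  if (!is.null(out_dir)) {
    write_report(report, out_dir)
    for (yr in names(surfaces))
      for (b in names(surfaces[[yr]]))
        write_raster(surfaces[[yr]][[b]],
                     file.path(out_dir, sprintf("%s_%s.asc", b, yr)))
  }
  report
}

#' @export
print.zoning_report <- function(x, ...) {
  cat("bioclimatic zoning report\n")
  cat(sprintf("  years: %s | THI formula: %s | metric: %s\n",
              paste(x$descriptive$year, collapse = ", "),
              x$settings$thi_formula, x$settings$metric))
  cat("  THI descriptive statistics:\n")
  print(x$descriptive[, c("year", "mean", "min", "max", "sd", "cv", "cv_class")],
        row.names = FALSE, digits = 5)
  sel <- x$cross_validation[x$cross_validation$selected, c("year", "family", "rmsse")]
  cat("  selected variogram per year:\n")
  print(sel, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the zoning pathway on projected climate scenarios
#'
#' Each scenario's temperature and wind fields are processed with exactly
#' the historical pathway: THI and milk-loss per point, variogram
#' fitting/selection, kriging, classification.
#'
#' @param scenarios list of [scenario_spec()] objects.
#' @param np_levels,thi_formula,grid,families,n_lags,n_neighbors,metric,cv_max_n,krige_mode,out_dir
#'   as in [run_zoning()].
#' @return object of class `"scenario_report"`: the same tables keyed by
#'   `pathway` and `horizon` instead of year, plus per-scenario surfaces.
#' @export
run_scenarios <- function(scenarios, np_levels = c(10, 25),
                          thi_formula = "silva", grid = NULL,
                          families = c("spherical", "exponential", "gaussian"),
                          n_lags = 12, n_neighbors = 16, metric = "planar",
                          cv_max_n = 400, krige_mode = c("index", "variable"),
                          out_dir = NULL) {
  krige_mode <- match.arg(krige_mode)
  if (inherits(scenarios, "scenario_spec")) scenarios <- list(scenarios)
  stopifnot(all(vapply(scenarios, inherits, TRUE, "scenario_spec")))
  desc <- ml <- fr <- list(); surfaces <- list()
  for (sc in scenarios) {
    coords <- as.matrix(sc$fields[, c("lon", "lat")])
    grid_s <- if (is.null(grid)) coords else as.matrix(grid)
    lay <- .zone_layer(coords, sc$fields$tair_c, sc$fields$ws_ms, np_levels,
                       grid_s, thi_formula, families, n_lags, n_neighbors,
                       metric, cv_max_n, krige_mode)
    key <- paste(sc$pathway, sc$horizon, sep = ":")
    s <- lay$stats
    desc[[key]] <- data.frame(pathway = sc$pathway, horizon = sc$horizon,
                              mean_thi = s$mean, min_thi = s$min,
                              max_thi = s$max, sd_thi = s$sd, cv = s$cv)
    for (i in seq_along(np_levels)) {
      v <- lay$dmp_surfaces[[i]]$estimate
      ml[[paste(key, np_levels[i])]] <- data.frame(
        pathway = sc$pathway, horizon = sc$horizon, np = np_levels[i],
        mean_dmp = mean(v), max_dmp = max(v), frac_affected = mean(v > 0))
    }
    fr[[key]] <- cbind(pathway = sc$pathway, horizon = sc$horizon,
                       lay$fractions)
    surfaces[[key]] <- c(list(thi = lay$thi_surface), lay$dmp_surfaces)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      for (b in names(surfaces[[key]]))
        write_raster(surfaces[[key]][[b]],
                     file.path(out_dir, sprintf("%s_%s.asc", b,
                                                gsub("[^A-Za-z0-9._-]", "_", key))))
    }
  }
  structure(list(descriptive = do.call(rbind, desc),
                 milk_loss = do.call(rbind, ml),
                 area_fractions = do.call(rbind, fr),
                 surfaces = surfaces,
                 settings = list(thi_formula = thi_formula, metric = metric,
                                 krige_mode = krige_mode)),
            class = "scenario_report")
}

#' @export
print.scenario_report <- function(x, ...) {
  cat("climate-scenario zoning report\n")
  print(x$descriptive, row.names = FALSE, digits = 5)
  print(x$milk_loss, row.names = FALSE, digits = 4)
  invisible(x)
}
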