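#' Pairwise distances between georeferenced points
#'
#' All spatial computations in the package (semivariogram estimation,
#' kriging, field simulation) share one distance metric so that fitted
#' ranges, prediction weights and simulated covariances are expressed in
#' the same units.
#'
#' @param coords two-column matrix or data frame of lon/lat (degrees for
#'   the geographic metrics; arbitrary planar units for `"planar"`).
#' @param coords2 optional second point set; when given the result is the
#'   `nrow(coords) x nrow(coords2)` cross-distance matrix.
#' @param metric `"planar"` treats the columns as Euclidean coordinates
#'   (distances in the input units, e.g. degrees); `"equirectangular"`
#'   projects lon/lat to planar metres about the mean latitude of the
#'   points before the Euclidean distance; `"greatcircle"` uses the
#'   haversine great-circle distance in metres.
#' @return numeric distance matrix.
#' @export
pair_distances <- function(coords, coords2 = NULL,
                           metric = c("planar", "equirectangular", "greatcircle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  cross <- !is.null(coords2)
  if (cross) coords2 <- as.matrix(coords2)
  if (ncol(coords) != 2L || anyNA(coords) || !all(is.finite(coords)))
    stop("'coords' must be a finite two-column matrix", call. = FALSE)
  switch(metric,
    planar = {
      if (cross) .cross_euclid(coords, coords2)
      else as.matrix(stats::dist(coords))
    },
    equirectangular = {
      all_lat <- if (cross) c(coords[, 2], coords2[, 2]) else coords[, 2]
      p1 <- .equirect(coords, mean(all_lat))
      if (cross) .cross_euclid(p1, .equirect(coords2, mean(all_lat)))
      else as.matrix(stats::dist(p1))
    },
    greatcircle = {
      if (cross) geosphere::distm(coords, coords2, fun = geosphere::distHaversine)
      else geosphere::distm(coords, fun = geosphere::distHaversine)
    })
}

# equirectangular projection to metres about reference latitude
.equirect <- function(coords, lat0, radius = 6371008.8) {
  cbind(radius * cos(lat0 * pi / 180) * coords[, 1] * pi / 180,
        radius * coords[, 2] * pi / 180)
}

# direct differences (not the dot-product expansion) so coincident
# points give exactly zero
.cross_euclid <- function(a, b) {
  sqrt(outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2)
}
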