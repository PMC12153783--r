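#' Read a climate point table
#'
#' CSV dialect with header `id, lon, lat, year, tair_c, ws_ms, precip_mm,
#' region`; `precip_mm` and `region` are optional unless a downstream
#' stage needs them (the SPI stage requires both).
#'
#' @param path CSV file path.
#' @param require character vector of columns that must be present beyond
#'   the core `id/lon/lat/year/tair_c/ws_ms`.
#' @return a `climate_field` data frame.
#' @export
read_points <- function(path, require = character()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  core <- c("id", "lon", "lat", "year", "tair_c", "ws_ms")
  miss <- setdiff(c(core, require), names(df))
  if (length(miss))
    stop("malformed point table, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(!is.finite(df$lon)) || any(!is.finite(df$lat)))
    stop("non-finite coordinates in point table")
  structure(df, class = c("climate_field", "data.frame"))
}

#' Write a climate point table
#' @param field a `climate_field` (or compatible data frame).
#' @param path output CSV path.
#' @export
write_points <- function(field, path) {
  utils::write.csv(as.data.frame(field), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a prediction surface as georeferenced text rasters
#'
#' Surfaces are written in the ESRI ASCII grid format (`.asc`), a plain
#' text georeferenced raster readable by standard GIS software; the
#' kriging standard error goes to a companion `*_se.asc` band. The
#' surface must lie on a regular lon/lat grid.
#'
#' @param surface data frame with `lon`, `lat`, `estimate` and optionally
#'   `std_error` on a regular grid.
#' @param path output path for the estimate band (`.asc` appended if
#'   absent); the error band gets the `_se.asc` suffix.
#' @param nodata no-data sentinel value.
#' @return invisibly, the paths written.
#' @export
write_raster <- function(surface, path, nodata = -9999) {
  if (!grepl("\\.asc$", path)) path <- paste0(path, ".asc")
  lon <- sort(unique(surface$lon)); lat <- sort(unique(surface$lat))
  step_x <- if (length(lon) > 1) diff(lon)[1] else 1
  if (length(lon) > 2 && max(abs(diff(diff(lon)))) > 1e-9 * step_x)
    stop("surface is not on a regular lon grid")
  paths <- character()
  bands <- c("estimate", if ("std_error" %in% names(surface)) "std_error")
  for (b in bands) {
    m <- matrix(nodata, nrow = length(lat), ncol = length(lon))
    i <- match(surface$lat, lat); j <- match(surface$lon, lon)
    m[cbind(i, j)] <- surface[[b]]
    p <- if (b == "estimate") path else sub("\\.asc$", "_se.asc", path)
    hdr <- c(sprintf("ncols %d", length(lon)),
             sprintf("nrows %d", length(lat)),
             sprintf("xllcenter %.10g", min(lon)),
             sprintf("yllcenter %.10g", min(lat)),
             sprintf("cellsize %.10g", step_x),
             sprintf("nodata_value %g", nodata))
    body <- apply(m[rev(seq_along(lat)), , drop = FALSE], 1,
                  function(r) paste(format(r, digits = 10, trim = TRUE),
                                    collapse = " "))
    writeLines(c(hdr, body), p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read an ESRI ASCII grid back into a surface data frame
#' @param path `.asc` file path.
#' @return data frame with `lon`, `lat`, `value` (no-data cells dropped).
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(tolower(lines[1:6]), "\\s+")
  keys <- vapply(hdr, `[`, "", 1); vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  nc <- vals[["ncols"]]; nr <- vals[["nrows"]]
  m <- do.call(rbind, lapply(lines[-(1:6)],
                             function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  lon <- vals[["xllcenter"]] + (seq_len(nc) - 1) * vals[["cellsize"]]
  lat <- vals[["yllcenter"]] + (seq_len(nr) - 1) * vals[["cellsize"]]
  out <- expand.grid(lon = lon, lat = rev(lat), KEEP.OUT.ATTRS = FALSE)
  out$value <- as.numeric(t(m))
  out <- out[out$value != vals[["nodata_value"]], ]
  rownames(out) <- NULL
  out
}

#' Write a zoning report to CSV tables and a JSON summary
#'
#' @param report a `zoning_report` from [run_zoning()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "zoning_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- character()
  wr <- function(df, name) {
    f <- file.path(dir, name)
    utils::write.csv(df, f, row.names = FALSE, quote = FALSE)
    p <<- c(p, f)
  }
  wr(report$descriptive, "descriptive_stats.csv")
  wr(report$cross_validation, "cross_validation.csv")
  wr(report$spatial_dependence, "spatial_dependence.csv")
  wr(report$area_fractions, "area_fractions.csv")
  wr(report$milk_loss, "milk_loss.csv")
  f <- file.path(dir, "report.json")
  jsonlite::write_json(unclass(report)[c("descriptive", "cross_validation",
                                         "spatial_dependence", "area_fractions",
                                         "milk_loss", "settings")],
                       f, dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(c(p, f))
}
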