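#' Maximum-likelihood gamma fit for precipitation
#'
#' Fits shape `alpha` and scale `beta` of a gamma law to the strictly
#' positive precipitation values by maximum likelihood: the profile score
#' `log(alpha) - digamma(alpha) = log(mean(x)) - mean(log(x))` is solved
#' by Newton iteration from Thom's approximate estimator, then
#' `beta = mean(x) / alpha`. Zero observations are set aside and counted
#' in `q_zero` for the mixed-distribution SPI transform.
#'
#' @param values precipitation amounts in mm (finite, >= 0; at least 10
#'   strictly positive, not all equal).
#' @param tol convergence tolerance on the profile score.
#' @return object of class `"gamma_fit"`: list with `alpha`, `beta`,
#'   `q_zero`, `n`, `loglik`.
#' @examples
#' set.seed(1)
#' fit_gamma_mle(rgamma(200, shape = 2, scale = 800))
#' @export
fit_gamma_mle <- function(values, tol = 1e-8) {
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (any(values < 0)) stop("negative precipitation values")
  xp <- values[values > 0]
  if (length(xp) < 10L) stop("need at least 10 strictly positive values")
  if (stats::var(xp) == 0) stop("all positive values equal: unfittable series")
  s <- log(mean(xp)) - mean(log(xp))      # > 0 for non-constant samples
  alpha <- (1 + sqrt(1 + 4 * s / 3)) / (4 * s)   # Thom initializer
  for (it in seq_len(100L)) {
    f <- log(alpha) - digamma(alpha) - s
    if (abs(f) < tol) break
    alpha <- alpha - f / (1 / alpha - trigamma(alpha))
    if (alpha <= 0) { alpha <- .Machine$double.eps; break }
  }
  beta <- mean(xp) / alpha
  ll <- sum(stats::dgamma(xp, shape = alpha, scale = beta, log = TRUE))
  structure(list(alpha = alpha, beta = beta,
                 q_zero = mean(values == 0), n = length(values), loglik = ll),
            class = "gamma_fit")
}

#' @export
print.gamma_fit <- function(x, ...) {
  cat(sprintf("gamma MLE: shape %.4g, scale %.4g (q_zero %.3g, n %d, logLik %.4g)\n",
              x$alpha, x$beta, x$q_zero, x$n, x$loglik))
  invisible(x)
}

#' Standardized Precipitation Index
#'
#' Annual-scale SPI: a gamma law is fitted to the reference series, the
#' mixed cumulative probability `H(x) = q_zero + (1 - q_zero) * F(x)` is
#' evaluated for each year, and the SPI is the standard-normal quantile
#' `qnorm(H(x))`. Negative values indicate drier-than-typical years. The
#' index is invariant to rescaling all precipitation by a positive
#' constant.
#'
#' @param precip annual precipitation totals, mm.
#' @param years optional year labels (default sequential).
#' @param reference optional precipitation series used for the gamma fit
#'   (default: `precip` itself, the self-referenced index).
#' @return object of class `"spi_series"`: data frame with `year`,
#'   `precip`, `spi`, `class`, and the `"gamma_fit"` as attribute `"fit"`.
#' @examples
#' set.seed(1)
#' spi_series(rgamma(30, shape = 8, scale = 200), years = 1991:2020)
#' @export
spi_series <- function(precip, years = seq_along(precip), reference = precip) {
  if (length(years) != length(precip)) stop("'years' must match 'precip'")
  fit <- fit_gamma_mle(reference)
  h <- fit$q_zero + (1 - fit$q_zero) *
    stats::pgamma(precip, shape = fit$alpha, scale = fit$beta)
  spi <- stats::qnorm(h)
  out <- data.frame(year = years, precip = precip, spi = spi,
                    class = classify_spi(spi))
  structure(out, class = c("spi_series", "data.frame"), fit = fit)
}

#' SPI drought/wet classification
#'
#' Seven contiguous bands at the cut points -2, -1, -0.5, 0.5, 1, 2:
#' Extremely Dry (<= -2), Very Dry, Moderately Dry, Near Normal,
#' Moderately Wet, Very Wet, Extremely Wet (>= 2). Boundaries follow the
#' printed convention of the McKee scale (e.g. -0.50 is Moderately Dry,
#' 1.00 is Very Wet).
#'
#' @param spi finite SPI values (infinities from zero-precipitation years
#'   under a zero-free reference are classed at the corresponding
#'   extreme).
#' @return factor with the seven class labels, dry to wet.
#' @export
classify_spi <- function(spi) {
  if (any(is.na(spi))) stop("'spi' must not contain NA")
  cut(spi, breaks = c(-Inf, -2, -1, -0.5, 0.5, 1, 2, Inf), right = FALSE,
      labels = c("Extremely Dry", "Very Dry", "Moderately Dry", "Near Normal",
                 "Moderately Wet", "Very Wet", "Extremely Wet")) -> f
  # printed scale closes the dry bands on their upper boundary
  f[spi == -2] <- "Extremely Dry"
  f[spi == -1] <- "Very Dry"
  f[spi == -0.5] <- "Moderately Dry"
  f
}

#' Regional SPI from point precipitation
#'
#' Aggregates point precipitation to region means per year, then computes
#' a self-referenced [spi_series()] per region, plus an `"(all)"` series
#' from the mean over every point (the whole-domain index).
#'
#' @param field a `climate_field` (or data frame with `year`, `precip_mm`
#'   and `region` columns).
#' @return named list of `"spi_series"`, one per region plus `"(all)"`.
#' @export
spi_by_region <- function(field) {
  need <- c("year", "precip_mm", "region")
  if (!all(need %in% names(field)))
    stop("field must have columns: ", paste(need, collapse = ", "))
  regions <- unique(as.character(field$region))
  out <- list()
  for (r in regions) {
    sub <- field[field$region == r, ]
    if (nrow(sub) == 0L) { warning("empty region skipped: ", r); next }
    agg <- tapply(sub$precip_mm, sub$year, mean)
    out[[r]] <- spi_series(as.numeric(agg), years = as.numeric(names(agg)))
  }
  agg <- tapply(field$precip_mm, field$year, mean)
  out[["(all)"]] <- spi_series(as.numeric(agg), years = as.numeric(names(agg)))
  out
}
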