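# THI formula registry. Different THI parameterizations circulate in the
# bioclimatology literature; the registry keeps the choice explicit and
# recorded in every pipeline output.
.thi_registry <- new.env(parent = emptyenv())

#' Register a THI formula
#'
#' @param name registry key.
#' @param fn function of `(tair, ws)` returning the index, vectorized.
#' @export
thi_register <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .thi_registry)
  invisible(name)
}

#' List registered THI formulas
#' @export
thi_formulas <- function() sort(ls(.thi_registry))

#' Temperature-Humidity Index
#'
#' Default formula (`"silva"`): `THI = 6.3952 + 0.08964 * Tair +
#' 0.01018 * Ws^2`, a wind-adjusted annual-scale parameterization from
#' air temperature (deg C) and wind speed (m/s). The exponent on wind
#' speed is part of the published coefficient set. Strictly increasing in
#' `tair`, non-decreasing in `ws`.
#'
#' @param tair mean air temperature, deg C.
#' @param ws mean wind speed, m/s (>= 0).
#' @param formula registry key of the formula to apply (see
#'   [thi_formulas()]).
#' @return numeric THI values with the formula name in attribute
#'   `"thi_formula"`.
#' @examples
#' thi(27, 2)
#' @export
thi <- function(tair, ws, formula = "silva") {
  if (any(!is.finite(tair)) || any(!is.finite(ws)))
    stop("'tair' and 'ws' must be finite")
  if (any(ws < 0)) stop("'ws' must be >= 0")
  fn <- get0(formula, envir = .thi_registry)
  if (is.null(fn)) stop("unknown THI formula: ", formula)
  structure(fn(tair, ws), thi_formula = formula)
}

#' Decrease in milk production under heat stress
#'
#' Regression estimate of daily milk loss per cow as a function of the
#' potential production under thermal comfort (`np`, kg/day/cow) and the
#' THI: `dmp_raw = -1.075 - 1.736 * np + 0.02474 * np * thi`. A decrease
#' cannot be negative, so the reported loss is `dmp = max(dmp_raw, 0)`;
#' the raw regression value is kept for diagnostics. Linear in THI with
#' slope `0.02474 * np`.
#'
#' @param np potential production level, kg/day/cow (>= 0); the standard
#'   settings are 10 (PL10) and 25 (PL25).
#' @param thi Temperature-Humidity Index values.
#' @return data frame with columns `np`, `thi`, `dmp_raw`, `dmp`
#'   (kg/day/cow).
#' @examples
#' milk_loss(25, 80)   # danger-zone loss for a high-yield cow
#' @export
milk_loss <- function(np, thi) {
  if (any(!is.finite(np)) || any(np < 0)) stop("'np' must be finite and >= 0")
  if (any(!is.finite(thi))) stop("'thi' must be finite")
  raw <- -1.075 - 1.736 * np + 0.02474 * np * as.numeric(thi)
  data.frame(np = np, thi = as.numeric(thi), dmp_raw = raw, dmp = pmax(raw, 0))
}

#' Livestock Weather Safety Index class
#'
#' Heat-safety categories for cattle from THI cut points: normal
#' (THI <= 74), alert (74 < THI < 79), danger (79 <= THI < 84),
#' emergency (THI >= 84). The four bands partition the real line.
#'
#' @param thi finite THI values.
#' @return factor with levels normal, alert, danger, emergency.
#' @export
classify_lwsi <- function(thi) {
  if (any(!is.finite(thi))) stop("'thi' must be finite")
  cut(thi, breaks = c(-Inf, 74, 79, 84, Inf), right = FALSE,
      labels = c("normal", "alert", "danger", "emergency"),
      include.lowest = TRUE) -> f
  # cut(..., right = FALSE) puts 74 in the alert bin; the scheme is
  # normal for THI <= 74, so shift exact boundary values down.
  f[thi == 74] <- "normal"
  f
}

#' Dairy-cattle heat-stress class
#'
#' Stress-onset thresholds for dairy cattle (inclusive lower bounds):
#' none below 72, moderate from 72, high from 79, extreme from 89.
#'
#' @param thi finite THI values.
#' @return factor with levels none, moderate, high, extreme.
#' @export
classify_dairy_stress <- function(thi) {
  if (any(!is.finite(thi))) stop("'thi' must be finite")
  cut(thi, breaks = c(-Inf, 72, 79, 89, Inf), right = FALSE,
      labels = c("none", "moderate", "high", "extreme"))
}

#' Coefficient-of-variation dispersion class
#'
#' low (CV < 12%), medium (12-24%), high (CV > 24%).
#'
#' @param cv_percent coefficient of variation in percent (>= 0).
#' @return factor with levels low, medium, high.
#' @export
classify_cv <- function(cv_percent) {
  if (any(!is.finite(cv_percent)) || any(cv_percent < 0))
    stop("'cv_percent' must be finite and >= 0")
  cut(cv_percent, breaks = c(-Inf, 12, 24, Inf), right = TRUE,
      labels = c("low", "medium", "high")) -> f
  f[cv_percent == 12] <- "medium"   # medium band is inclusive: [12, 24]
  f
}
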