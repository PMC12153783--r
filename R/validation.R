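#' Leave-one-out cross-validation of a kriging model
#'
#' Each sample point is withheld in turn and predicted by ordinary
#' kriging from the remaining points. Five summary metrics are computed
#' from the held-out errors `e_i = Zhat(x_i) - Z(x_i)` and kriging
#' standard errors `s_i`:
#'
#' * `me` — mean error, `mean(e)`;
#' * `mse` — mean standardized error, `mean(e / s)` (a mean, not a mean
#'   of squares);
#' * `ase` — average standard error, `mean(s)`;
#' * `rmse` — root mean square error, `sqrt(mean(e^2))`;
#' * `rmsse` — root mean square standardized error,
#'   `sqrt(mean((e / s)^2))`; values near 1 indicate well-calibrated
#'   kriging standard errors.
#'
#' @param coords,values sample locations and values (>= 3 points).
#' @param model a [variogram_model()].
#' @param n_neighbors,metric passed to [krige()].
#' @return object of class `"loo_cv"`: list with the five metrics, `n`,
#'   and a `pointwise` data frame (observed, predicted, std_error,
#'   error).
#' @export
loo_cv <- function(coords, values, model, n_neighbors = 16,
                   metric = c("planar", "equirectangular", "greatcircle")) {
  metric <- match.arg(metric)
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (n < 3L) stop("need at least 3 points for cross-validation")
  pred <- se <- numeric(n)
  for (i in seq_len(n)) {
    p <- krige(model, coords[-i, , drop = FALSE], values[-i],
               coords[i, , drop = FALSE],
               n_neighbors = min(n_neighbors, n - 1L), metric = metric)
    pred[i] <- p$estimate; se[i] <- p$std_error
  }
  if (any(se == 0))
    stop("zero kriging standard error during standardization: ",
         "use a nonzero nugget or deduplicate points", call. = FALSE)
  e <- pred - values
  structure(list(me = mean(e), mse = mean(e / se), ase = mean(se),
                 rmse = sqrt(mean(e^2)), rmsse = sqrt(mean((e / se)^2)),
                 n = n,
                 pointwise = data.frame(observed = values, predicted = pred,
                                        std_error = se, error = e)),
            class = "loo_cv")
}

#' @export
print.loo_cv <- function(x, ...) {
  cat(sprintf("leave-one-out CV (n = %d): ME %.4g, MSE %.4g, ASE %.4g, RMSE %.4g, RMSSE %.4g\n",
              x$n, x$me, x$mse, x$ase, x$rmse, x$rmsse))
  invisible(x)
}

#' Select the best variogram family from cross-validation results
#'
#' The preferred model is the one whose RMSSE is closest to 1 (standard
#' errors neither over- nor under-stated). Ties within `1e-6` are broken
#' by the smaller gap between RMSE and ASE, then by smaller RMSE, then by
#' the fixed family order spherical, exponential, gaussian.
#'
#' @param candidates named list of [loo_cv()] results (names are the
#'   families).
#' @return the selected family name, with the full ranking table attached
#'   as attribute `"ranking"`.
#' @export
select_model <- function(candidates) {
  if (length(candidates) < 1L) stop("empty candidate set")
  fams <- names(candidates)
  if (is.null(fams) || any(!nzchar(fams))) stop("'candidates' must be named by family")
  order_pref <- c("spherical", "exponential", "gaussian")
  tab <- data.frame(
    family = fams,
    rmsse = vapply(candidates, function(x) x$rmsse, numeric(1)),
    rmse  = vapply(candidates, function(x) x$rmse, numeric(1)),
    ase   = vapply(candidates, function(x) x$ase, numeric(1)),
    me    = vapply(candidates, function(x) x$me, numeric(1)),
    mse   = vapply(candidates, function(x) x$mse, numeric(1)))
  tab$dev1 <- abs(tab$rmsse - 1)
  tab$gap <- abs(tab$rmse - tab$ase)
  pref <- match(tab$family, order_pref, nomatch = length(order_pref) + 1L)
  # lexicographic with 1e-6 tie bands on dev1
  key1 <- round(tab$dev1 / 1e-6)
  o <- order(key1, tab$gap, tab$rmse, pref)
  tab <- tab[o, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab$family[1L], ranking = tab)
}

#' Degree of spatial dependence (nugget-to-sill ratio)
#'
#' `100 * C0 / (C0 + C)` in percent, classed after Cambardella's bands:
#' strong spatial dependence below 25, moderate from 25 to 75, weak above
#' 75. Scale-invariant: rescaling both variance components leaves it
#' unchanged.
#'
#' @param model a [variogram_model()] with positive total sill.
#' @return list with `dsd_percent` and `dsd_class`.
#' @export
dsd <- function(model) {
  stopifnot(inherits(model, "variogram_model"))
  s <- sill(model)
  if (s <= 0) stop("zero total sill: degree of spatial dependence undefined")
  p <- 100 * model$nugget / s
  cls <- if (p < 25) "strong" else if (p <= 75) "moderate" else "weak"
  list(dsd_percent = p, dsd_class = cls)
}

#' Shapiro-Wilk normality check for residuals
#'
#' @param values numeric residuals, 3 <= n <= 5000, non-constant.
#' @param alpha significance level for the non-normality flag.
#' @return list with `statistic` (W), `p_value`, and `non_normal`
#'   (`TRUE` when `p < alpha`).
#' @export
residual_normality <- function(values, alpha = 0.05) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop("sample size must be between 3 and 5000")
  if (any(!is.finite(values))) stop("'values' must be finite")
  if (stats::var(values) == 0) stop("constant sample: zero variance")
  sw <- stats::shapiro.test(values)
  list(statistic = unname(sw$statistic), p_value = sw$p.value,
       non_normal = sw$p.value < alpha)
}
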