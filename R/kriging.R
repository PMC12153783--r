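#' Ordinary kriging prediction
#'
#' Best linear unbiased prediction under intrinsic stationarity. For each
#' target location the ordinary-kriging system is solved for weights
#' `lambda` (semivariance matrix among the neighbours, bordered by the
#' unbiasedness constraint `sum(lambda) = 1` via a Lagrange multiplier):
#' the estimate is `sum(lambda_i * z_i)` and the kriging variance
#' `sum(lambda_i * gamma(h_i0)) + mu`.
#'
#' @param model a [variogram_model()].
#' @param coords,values sample locations (two-column) and values.
#' @param new_coords target locations (two-column).
#' @param n_neighbors number of nearest samples used per target (local
#'   kriging); `Inf` uses every sample (global kriging, one factorization).
#'   Equidistant neighbours are broken by sample index (stable).
#' @param metric distance metric, see [pair_distances()].
#' @param keep_weights if `TRUE`, attach a list (one element per target)
#'   of weight vectors named by sample index as attribute `"weights"`.
#' @return data frame with one row per target: `estimate` and `std_error`
#'   (kriging standard error). Weights sum to 1 for every prediction.
#' @examples
#' m <- variogram_model("spherical", 0, 1, 2)
#' xy <- cbind(c(0, 1, 0), c(0, 0, 1))
#' krige(m, xy, c(1, 2, 3), cbind(0.5, 0.5))
#' @export
krige <- function(model, coords, values, new_coords, n_neighbors = 16,
                  metric = c("planar", "equirectangular", "greatcircle"),
                  keep_weights = FALSE) {
  metric <- match.arg(metric)
  stopifnot(inherits(model, "variogram_model"))
  coords <- as.matrix(coords); new_coords <- as.matrix(new_coords)
  n <- nrow(coords)
  if (n < 2L) stop("need at least 2 sample points")
  if (length(values) != n) stop("'values' length must match 'coords'")
  if (any(!is.finite(values))) stop("'values' must be finite")

  d0 <- pair_distances(coords, new_coords, metric = metric)  # n x m
  m <- nrow(new_coords)
  global <- !is.finite(n_neighbors) || n_neighbors >= n
  est <- se <- numeric(m)

  # degenerate zero-sill model: any convex weights are optimal; use the
  # (neighbourhood) mean with zero kriging error
  if (sill(model) == 0) {
    k <- if (global) n else min(as.integer(n_neighbors), n)
    W <- vector("list", m)
    for (j in seq_len(m)) {
      nb <- order(d0[, j])[seq_len(k)]
      est[j] <- mean(values[nb])
      W[[j]] <- stats::setNames(rep(1 / k, k), nb)
    }
    out <- data.frame(estimate = est, std_error = 0)
    if (keep_weights) attr(out, "weights") <- W
    return(out)
  }

  if (global) {
    G <- predict(model, pair_distances(coords, metric = metric))
    diag(G) <- 0
    A <- rbind(cbind(G, 1), c(rep(1, n), 0))
    B <- rbind(predict(model, d0), 1)
    sol <- tryCatch(solve(A, B), error = function(e)
      stop("singular kriging system: deduplicate sample locations or add a nugget",
           call. = FALSE))
    lambda <- sol[seq_len(n), , drop = FALSE]
    mu <- sol[n + 1L, ]
    est <- as.numeric(crossprod(lambda, values))
    kvar <- colSums(lambda * predict(model, d0)) + mu
    se <- sqrt(pmax(kvar, 0))
    W <- lapply(seq_len(m), function(j)
      stats::setNames(lambda[, j], seq_len(n)))
  } else {
    k <- as.integer(n_neighbors)
    if (k < 1L) stop("'n_neighbors' must be >= 1")
    W <- vector("list", m)
    for (j in seq_len(m)) {
      nb <- order(d0[, j])[seq_len(k)]   # stable: ties broken by index
      G <- predict(model, pair_distances(coords[nb, , drop = FALSE], metric = metric))
      diag(G) <- 0
      g0 <- predict(model, d0[nb, j])
      A <- rbind(cbind(G, 1), c(rep(1, k), 0))
      sol <- tryCatch(solve(A, c(g0, 1)), error = function(e)
        stop("singular kriging system: deduplicate sample locations or add a nugget",
             call. = FALSE))
      lambda <- sol[seq_len(k)]
      est[j] <- sum(lambda * values[nb])
      se[j] <- sqrt(max(sum(lambda * g0) + sol[k + 1L], 0))
      W[[j]] <- stats::setNames(lambda, nb)
    }
  }
  # kriging exactness: a zero-nugget model interpolates its data exactly;
  # targets coinciding with a sample are copied through rather than
  # extracted from the (there ill-conditioned) bordered system
  if (model$nugget == 0) {
    for (j in seq_len(m)) {
      i0 <- which(d0[, j] == 0)
      if (length(i0)) {
        est[j] <- values[i0[1L]]; se[j] <- 0
        W[[j]] <- stats::setNames(1, i0[1L])
      }
    }
  }
  out <- data.frame(estimate = est, std_error = se)
  if (keep_weights) attr(out, "weights") <- W
  out
}
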