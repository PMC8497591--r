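# Fractional pre-scan, robust background normalization and bright-point
# detection. The normalized signal r = (s - a_hat) / (a_hat * sigma_hat) is
# expected to be ~N(0, 1) on background voxels, so bright points can be
# declared by a pure significance test r > T with T set from a chosen
# probability of false alarm.

#' Draw a fractional pre-scan
#'
#' Samples `round(eta * nx*ny*nz)` distinct voxels uniformly over the volume.
#'
#' @param shape Integer vector (nx, ny, nz).
#' @param eta Sampling fraction in (0, 1\]; must yield at least one voxel.
#' @param seed Integer seed (draws are reproducible given it).
#' @return Integer matrix of voxel coordinates (columns x, y, z).
#' @export
draw_prescan <- function(shape, eta, seed = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, eta > 0, eta <= 1)
  n_tot <- prod(shape)
  n <- round(eta * n_tot)
  if (n < 1) stop("eta yields zero pre-scan points")
  idx <- with_seed(seed, sample.int(n_tot, n))
  ci <- arrayInd(idx, shape)
  colnames(ci) <- c("x", "y", "z")
  storage.mode(ci) <- "integer"
  ci
}

# Tensor polynomial design: (1, u, v, u^2, uv, v^2) x (1, w, w^2), with
# u, v, w the coordinates rescaled to [-1, 1]. 18 columns.
bg_design <- function(coords, shape) {
  u <- norm_coord(coords[, 1], shape[1])
  v <- norm_coord(coords[, 2], shape[2])
  w <- norm_coord(coords[, 3], shape[3])
  lat <- cbind(1, u, v, u^2, u * v, v^2)
  ax <- cbind(1, w, w^2)
  X <- matrix(0, nrow(lat), 18L)
  k <- 0L
  for (j in 1:3) for (i in 1:6) {
    k <- k + 1L
    X[, k] <- lat[, i] * ax[, j]
  }
  X
}

#' Fit the background normalization model from pre-scan samples
#'
#' Fits a smooth low-order (tensor quadratic in x, y; quadratic in z)
#' polynomial `a_hat` to the sampled intensities by iteratively trimmed least
#' squares, robust to the bright tail: at each of `iterations` passes the
#' relative residual `rho = s / a_hat - 1` is computed and samples above
#' `median(rho) + clip * 1.4826 * MAD(rho)` (statistics over the currently
#' retained set) are set aside before refitting. The one-sided high cut
#' rejects the bright tail while leaving the background distribution —
#' and hence the calibration of the significance test — essentially intact.
#' `sigma_hat` is `1.4826 * MAD` of `rho` on the retained samples (floored at
#' 1e-6 for noise-free inputs).
#'
#' @param samples A `sample_set` data.frame (needs `x`, `y`, `z`, `value`).
#' @param shape Stack shape (nx, ny, nz) the coordinates live on.
#' @param iterations Trimming iterations (default 3).
#' @param clip Rejection threshold in robust standard deviations (default 3.5).
#' @return An object of class `bg_model`: list with `coef`, `shape`,
#'   `sigma_hat`, `fit_meta` (iterations, clip, n, n_retained).
#' @export
fit_background <- function(samples, shape, iterations = 3L, clip = 3.5) {
  shape <- as.integer(shape)
  n <- nrow(samples)
  if (n < 18L * 10L)
    stop("fit_background needs at least ", 180L, " samples, got ", n)
  coords <- as_coords(samples)
  if (nrow(unique(coords)) < 18L)
    stop("degenerate samples: too few distinct coordinates")
  X <- bg_design(coords, shape)
  s <- samples$value
  keep <- rep(TRUE, n)
  rho <- NULL
  for (it in seq_len(iterations)) {
    fit <- stats::lm.fit(X[keep, , drop = FALSE], s[keep])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    a <- drop(X %*% beta)
    # samples where the current fit is non-positive are treated as outliers
    rho <- ifelse(a > 0, s / a - 1, Inf)
    ok <- keep & is.finite(rho)
    if (sum(ok) < 18L) stop("background fit degenerate: too few usable samples")
    med <- stats::median(rho[ok])
    sc <- stats::mad(rho[ok])
    keep <- is.finite(rho) & rho <= med + clip * max(sc, 1e-12)
    if (sum(keep) < 18L) stop("trimming removed too many samples")
  }
  if (any(!is.finite(rho[keep])))
    stop("background fit is non-positive at retained samples")
  sigma_hat <- max(stats::mad(rho[keep]), 1e-6)
  structure(list(coef = beta, shape = shape, sigma_hat = sigma_hat,
                 fit_meta = list(iterations = iterations, clip = clip,
                                 n = n, n_retained = sum(keep))),
            class = "bg_model")
}

#' Evaluate the fitted background field at voxel coordinates
#'
#' @param model A [fit_background()] model.
#' @param coords Integer matrix or data.frame with columns x, y, z.
#' @return Numeric vector of `a_hat` values.
#' @export
predict_background <- function(model, coords) {
  coords <- as_coords(coords)
  n <- nrow(coords)
  out <- numeric(n)
  chunk <- 200000L
  for (s in seq(1L, max(1L, n), by = chunk)) {
    e <- min(s + chunk - 1L, n)
    if (s > n) break
    out[s:e] <- drop(bg_design(coords[s:e, , drop = FALSE], model$shape) %*% model$coef)
  }
  out
}

#' Normalize sampled intensities
#'
#' Applies `r = (s - a_hat) / (a_hat * sigma_hat)` at each sample's
#' coordinates, filling the `normalized` column.
#'
#' @param samples A `sample_set` data.frame.
#' @param model A [fit_background()] model.
#' @return `samples` with the `normalized` column filled.
#' @export
normalize_samples <- function(samples, model) {
  if (nrow(samples) == 0L) return(samples)
  a <- predict_background(model, samples)
  if (any(a <= 0))
    stop("background estimate non-positive at ", sum(a <= 0), " coordinate(s)")
  samples$normalized <- (samples$value - a) / (a * model$sigma_hat)
  samples
}

#' Detection threshold from a probability of false alarm
#'
#' Solves `pfa = (1/2) * (1 - erf(T / sqrt(2)))`, i.e. the upper-tail
#' standard-normal quantile: a background voxel with ~N(0,1) normalized
#' intensity exceeds T with probability `pfa`.
#'
#' @param pfa Probability of false alarm, in (0, 0.5).
#' @return The threshold T (e.g. `pfa = 0.01` gives T ~ 2.33).
#' @export
threshold_from_pfa <- function(pfa) {
  if (!is.numeric(pfa) || length(pfa) < 1L || any(pfa <= 0) || any(pfa >= 0.5))
    stop("pfa must lie strictly between 0 and 0.5")
  stats::qnorm(pfa, lower.tail = FALSE)
}

#' Probability of false alarm of a threshold (inverse of [threshold_from_pfa()])
#' @param T Detection threshold.
#' @return Upper-tail standard-normal probability.
#' @export
pfa_from_threshold <- function(T) {
  stats::pnorm(T, lower.tail = FALSE)
}

#' Detect bright points by significance test
#'
#' Returns exactly the samples whose normalized intensity strictly exceeds T.
#'
#' @param samples A normalized `sample_set`.
#' @param T Detection threshold.
#' @return The bright subset of `samples`.
#' @export
detect_bright <- function(samples, T) {
  if (any(is.na(samples$normalized)))
    stop("samples must be normalized before detection")
  samples[samples$normalized > T, , drop = FALSE]
}
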