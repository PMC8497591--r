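# Surface-of-interest estimation from detected bright points: overlapping
# lateral windows, per-window second-order polynomial RANSAC fits, fusion of
# the fits to filter inliers and denoise their z-coordinates, biharmonic
# spline interpolation to a full height field, and conversion to a thin
# shell with a per-voxel layer index.

#' Build an overlapping lateral window grid
#'
#' Axis-aligned rectangles of width `width_fraction * extent` stepping by
#' `width * (1 - overlap_fraction)`; an extra window is appended per axis if
#' needed so the grid always covers the full lateral extent.
#'
#' @param nx,ny Lateral extent in pixels.
#' @param width_fraction Window width as a fraction of the extent (default 1/3).
#' @param overlap_fraction Overlap between consecutive windows (default 0.5).
#' @return A `window_grid` data.frame with columns `x0`, `x1`, `y0`, `y1`,
#'   `cx`, `cy`, `hw`, `hh` (centres and half-sizes).
#' @export
make_windows <- function(nx, ny, width_fraction = 1 / 3, overlap_fraction = 0.5) {
  stopifnot(width_fraction > 0, width_fraction <= 1,
            overlap_fraction >= 0, overlap_fraction < 1)
  axis_starts <- function(L) {
    w <- min(L, max(1L, ceiling(width_fraction * L)))
    step <- max(1L, round(w * (1 - overlap_fraction)))
    starts <- seq(1L, by = step, length.out = max(1L, ceiling((L - w) / step) + 1L))
    starts <- starts[starts <= L - w + 1L]
    if (max(starts) + w - 1L < L) starts <- c(starts, L - w + 1L)
    list(starts = as.integer(starts), w = as.integer(w))
  }
  ax <- axis_starts(nx); ay <- axis_starts(ny)
  g <- expand.grid(x0 = ax$starts, y0 = ay$starts)
  g$x1 <- g$x0 + ax$w - 1L
  g$y1 <- g$y0 + ay$w - 1L
  g$cx <- (g$x0 + g$x1) / 2; g$cy <- (g$y0 + g$y1) / 2
  g$hw <- ax$w / 2; g$hh <- ay$w / 2
  # coverage postcondition
  if (min(g$x0) > 1L || max(g$x1) < nx || min(g$y0) > 1L || max(g$y1) < ny)
    stop("window layout does not cover the lateral extent")
  class(g) <- c("window_grid", class(g))
  g
}

quad_design <- function(x, y) cbind(1, x, y, x^2, x * y, y^2)

#' Robust second-order polynomial fit of bright-point heights (RANSAC)
#'
#' Fits `z = c0 + c1 x + c2 y + c3 x^2 + c4 xy + c5 y^2` (z in um, x/y in
#' pixels) by random sample consensus: draw 6 points, interpolate them
#' exactly, count points within `inlier_tol` of the model, keep the largest
#' consensus set and refit it by least squares. The number of trials adapts
#' to the best inlier ratio seen so far (standard early termination at the
#' given `confidence`), capped at `n_trials`.
#'
#' @param pts Data.frame with `x`, `y` (pixels) and `z_um`.
#' @param inlier_tol Consensus tolerance on |z residual| in um (default 1.5,
#'   the shell half-thickness, so inliers are exactly shell-compatible).
#' @param n_trials Trial cap (default 10000).
#' @param min_inliers Minimum consensus size for a valid fit; default
#'   `6 + ceil(0.1 * n)`.
#' @param confidence Probability of having seen one all-inlier sample before
#'   stopping (default 0.999).
#' @param seed Optional seed.
#' @return A `local_fit` (list with `coef`, `center`, `scale`, `inlier_idx`,
#'   `n_inliers`) or `NULL` when no valid fit exists (fewer than 6 points or
#'   consensus below `min_inliers`).
#' @export
ransac_fit_window <- function(pts, inlier_tol = 1.5, n_trials = 10000L,
                              min_inliers = NULL, confidence = 0.999,
                              seed = NULL) {
  n <- nrow(pts)
  if (is.null(n) || n < 6L) return(NULL)
  min_inliers <- min_inliers %||% (6L + ceiling(0.1 * n))
  cx <- (min(pts$x) + max(pts$x)) / 2
  cy <- (min(pts$y) + max(pts$y)) / 2
  sx <- max(1, (max(pts$x) - min(pts$x)) / 2)
  sy <- max(1, (max(pts$y) - min(pts$y)) / 2)
  X <- quad_design((pts$x - cx) / sx, (pts$y - cy) / sy)
  z <- pts$z_um
  tol2 <- inlier_tol^2
  with_seed(seed, {
    best_n <- 0L; best_in <- NULL
    best_score <- Inf     # MSAC score: sum of truncated squared residuals
    t <- 0L; needed <- n_trials
    while (t < min(n_trials, needed)) {
      t <- t + 1L
      idx <- sample.int(n, 6L)
      b <- tryCatch(solve(X[idx, , drop = FALSE], z[idx]),
                    error = function(e) NULL)
      if (is.null(b)) next
      r2v <- (drop(X %*% b) - z)^2
      score <- sum(pmin(r2v, tol2))
      if (score < best_score && sum(r2v <= tol2) >= 6L) {
        # local optimization: refit on the consensus and rescore, so that a
        # semi-clean minimal sample still converges to the dominant surface
        inl <- which(r2v <= tol2)
        for (lo in 1:3) {
          fit <- stats::lm.fit(X[inl, , drop = FALSE], z[inl])
          bb <- fit$coefficients; bb[is.na(bb)] <- 0
          rr2 <- (drop(X %*% bb) - z)^2
          inl2 <- which(rr2 <= tol2)
          if (length(inl2) < 6L || identical(inl2, inl)) break
          inl <- inl2
        }
        fit <- stats::lm.fit(X[inl, , drop = FALSE], z[inl])
        bb <- fit$coefficients; bb[is.na(bb)] <- 0
        rr2 <- (drop(X %*% bb) - z)^2
        cand_score <- min(score, sum(pmin(rr2, tol2)))
        cand_in <- which(rr2 <= tol2)
        # truncated squared loss (MSAC) rather than a bare inlier count:
        # a warped surface padded with chance inliers at the edge of the
        # tolerance band scores worse than the exactly-consistent one even
        # when their consensus counts tie
        if (cand_score < best_score && length(cand_in) >= 6L) {
          best_score <- cand_score; best_n <- length(cand_in); best_in <- cand_in
          # adaptive stop on the consensus ratio *discounted for chance
          # inliers*: any quadratic catches ~2 tol / z-range of scattered
          # points, so the raw ratio overstates the structured inlier rate
          # and would quit before an all-inlier sample is likely
          rho <- min(0.5, 2 * inlier_tol / max(diff(range(z)), 1e-9))
          w <- max((best_n / n - rho) / (1 - rho), 0)
          w6 <- w^6
          needed <- if (w6 >= 1) 1L
            else if (w6 <= 1e-12) n_trials
            else ceiling(log(1 - confidence) / log(1 - w6))
        }
      }
    }
    if (best_n < max(6L, min_inliers)) return(NULL)
    # final polish: scale-adaptive trimmed least squares on the consensus,
    # so that chance inliers at the edge of the tolerance band do not tilt
    # the model away from the exactly-consistent core
    inl <- best_in
    for (po in 1:3) {
      fit <- stats::lm.fit(X[inl, , drop = FALSE], z[inl])
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      r <- abs(drop(X %*% beta) - z)
      sc <- stats::mad(r[inl])
      keep <- which(r <= min(inlier_tol, max(3.5 * sc, 1e-6)))
      if (length(keep) < 6L || length(keep) == length(inl)) break
      inl <- keep
    }
    r <- abs(drop(X %*% beta) - z)
    inl <- which(r <= inlier_tol)
    list(coef = beta, center = c(cx, cy), scale = c(sx, sy),
         inlier_idx = inl, n_inliers = length(inl), trials = t)
  })
}

#' Evaluate a local window fit at lateral positions
#' @param fit A `local_fit` from [ransac_fit_window()].
#' @param x,y Pixel coordinates.
#' @return Predicted heights in um.
#' @export
predict_local_fit <- function(fit, x, y) {
  drop(quad_design((x - fit$center[1]) / fit$scale[1],
                   (y - fit$center[2]) / fit$scale[2]) %*% fit$coef)
}

#' Fuse window fits: filter inlier bright points and denoise their heights
#'
#' The valid window fits are fused into a single consensus height at each
#' bright point's lateral position: the average of the covering fits'
#' predictions, weighted by a tent (triangular) profile peaking at each
#' window's centre — so overlapping windows blend smoothly — multiplied by
#' each fit's consensus size, so that a marginal fit supported by few points
#' cannot dominate a well-supported neighbour. A bright point is retained
#' iff its height lies within `inlier_tol` of the fused surface (it is an
#' inlier of the most populated surface); its denoised height is the fused
#' prediction at its position.
#'
#' @param fits List of `local_fit` (or `NULL`) entries, one per window.
#' @param windows The [make_windows()] grid the fits were computed on.
#' @param pts Bright points data.frame (`x`, `y`, `z_um`).
#' @param inlier_tol Consistency tolerance in um (default 1.5); `Inf` keeps
#'   every point (used when outlier removal is disabled).
#' @return Data.frame `x`, `y`, `z_um` (denoised) for the retained points.
#' @export
fuse_and_filter <- function(fits, windows, pts, inlier_tol = 1.5) {
  if (all(vapply(fits, is.null, logical(1))))
    stop("no valid window fit: surface cannot be estimated")
  n <- nrow(pts)
  num <- numeric(n); den <- numeric(n)
  for (w in seq_len(nrow(windows))) {
    fit <- fits[[w]]
    if (is.null(fit)) next
    inw <- which(pts$x >= windows$x0[w] & pts$x <= windows$x1[w] &
                 pts$y >= windows$y0[w] & pts$y <= windows$y1[w])
    if (!length(inw)) next
    pred <- predict_local_fit(fit, pts$x[inw], pts$y[inw])
    wt <- fit$n_inliers *
      pmax(0.05, (1 - abs(pts$x[inw] - windows$cx[w]) / (windows$hw[w] + 0.5)) *
                 (1 - abs(pts$y[inw] - windows$cy[w]) / (windows$hh[w] + 0.5)))
    num[inw] <- num[inw] + wt * pred
    den[inw] <- den[inw] + wt
  }
  fused <- num / den
  keep <- den > 0 & (is.infinite(inlier_tol) |
                     abs(fused - pts$z_um) <= inlier_tol)
  keep[is.na(keep)] <- FALSE
  data.frame(x = pts$x[keep], y = pts$y[keep], z_um = fused[keep])
}

#' Biharmonic spline interpolation of scattered heights to the full grid
#'
#' Exact scattered-data interpolation with the biharmonic Green's function
#' `G(r) = r^2 (log r - 1)` plus an affine part (a thin-plate spline with no
#' smoothing): the interpolant passes through every input point. Duplicate
#' lateral positions are averaged first; if more than `max_points` points are
#' supplied a deterministic subsample is used (the interpolation system is
#' dense). The support mask is the convex hull of the input points
#' intersected with the union of disks of radius twice the median
#' nearest-neighbour spacing around them; the height field is `NA` outside
#' it, so laterally empty regions (no tissue, no bright points) stay out of
#' the shell.
#'
#' @param pts Data.frame with `x`, `y` (pixels) and `z_um`.
#' @param nx,ny Lateral grid extent.
#' @param max_points Cap on interpolation centres (default 1500).
#' @return A `surface_model`: list with `Z_hat` (nx-by-ny matrix, um, NA
#'   outside support) and `support` (logical matrix).
#' @export
interpolate_surface <- function(pts, nx, ny, max_points = 1500L) {
  # average duplicated lateral positions (exact interpolation needs distinct centres)
  key <- paste(pts$x, pts$y)
  if (anyDuplicated(key)) {
    z <- tapply(pts$z_um, key, mean)
    xy <- do.call(rbind, strsplit(names(z), " "))
    pts <- data.frame(x = as.numeric(xy[, 1]), y = as.numeric(xy[, 2]),
                      z_um = as.numeric(z))
  }
  n <- nrow(pts)
  if (n < 3L) stop("interpolation needs at least 3 non-collinear points")
  if (qr(cbind(1, pts$x, pts$y))$rank < 3L)
    stop("bright points are collinear in (x, y): surface is underdetermined")
  if (n > max_points) {
    o <- order(pts$x, pts$y)
    pts <- pts[o[round(seq(1L, n, length.out = max_points))], , drop = FALSE]
    n <- nrow(pts)
  }
  L <- max(nx, ny)
  px <- pts$x / L; py <- pts$y / L
  G <- function(r) { g <- r^2 * (log(r) - 1); g[r == 0] <- 0; g }
  K <- G(sqrt(outer(px, px, `-`)^2 + outer(py, py, `-`)^2))
  P <- cbind(1, px, py)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  rhs <- c(pts$z_um, 0, 0, 0)
  sol <- tryCatch(solve(A, rhs), error = function(e) {
    diag(A)[seq_len(n)] <- diag(A)[seq_len(n)] + 1e-8
    solve(A, rhs)
  })
  w <- sol[seq_len(n)]; cc <- sol[n + 1:3]
  Z <- matrix(NA_real_, nx, ny)
  gy <- seq_len(ny) / L
  gx <- seq_len(nx) / L
  chunk <- max(1L, floor(5e6 / n))
  for (s in seq(1L, nx, by = chunk)) {
    e <- min(s + chunk - 1L, nx)
    xs <- gx[s:e]
    # rows: grid x in chunk crossed with all y
    DX2 <- outer(xs, px, `-`)^2
    for (j in seq_len(ny)) {
      D <- sqrt(DX2 + matrix((gy[j] - py)^2, nrow = length(xs), ncol = n, byrow = TRUE))
      Z[s:e, j] <- G(D) %*% w + cc[1] + cc[2] * xs + cc[3] * gy[j]
    }
  }
  hull <- grDevices::chull(pts$x, pts$y)
  bnd <- cbind(pts$x[hull], pts$y[hull])
  grid_xy <- cbind(rep(seq_len(nx), ny), rep(seq_len(ny), each = nx))
  support <- matrix(mgcv::in.out(rbind(bnd, bnd[1, ]), grid_xy), nx, ny)
  # restrict to local data support: the estimate is only trusted within a
  # data-driven radius (2x the median nearest-neighbour spacing) of an
  # interpolation centre, so laterally empty regions (no tissue) and
  # isolated stray points do not open large shell areas
  nn <- rep(Inf, n)
  for (i in seq_len(n)) {
    d2 <- (pts$x - pts$x[i])^2 + (pts$y - pts$y[i])^2
    nn[i] <- sqrt(min(d2[-i]))
  }
  R <- max(3, 2 * stats::median(nn))
  rb <- ceiling(R)
  near <- matrix(FALSE, nx, ny)
  # isolated points (no companion within R) are not evidence of a surface
  # patch: they interpolate but do not open support
  for (i in which(nn <= R)) {
    x0 <- max(1L, round(pts$x[i]) - rb); x1 <- min(nx, round(pts$x[i]) + rb)
    y0 <- max(1L, round(pts$y[i]) - rb); y1 <- min(ny, round(pts$y[i]) + rb)
    D <- outer((x0:x1 - pts$x[i])^2, (y0:y1 - pts$y[i])^2, `+`)
    near[x0:x1, y0:y1] <- near[x0:x1, y0:y1] | (D <= R^2)
  }
  support <- support & near
  # every interpolation centre keeps its own pixel (exact interpolation
  # stays observable even for isolated points)
  support[cbind(round(pts$x), round(pts$y))] <- TRUE
  Z[!support] <- NA_real_
  structure(list(Z_hat = Z, support = support, points = pts),
            class = "surface_model")
}

#' Estimate the surface of interest from bright points
#'
#' Full estimation chain: overlapping windows, per-window RANSAC polynomial
#' fits (plain least-squares fits when `ransac = FALSE`, which disables
#' outlier removal), fusion/denoising, biharmonic interpolation.
#'
#' @param bright Data.frame of bright points with `x`, `y` (pixels) and
#'   either `z_um` or `z` (plane index, converted using `dz`).
#' @param nx,ny Lateral grid extent.
#' @param dz Axial pitch in um (used if `z_um` is absent).
#' @param width_fraction,overlap_fraction Window layout (see [make_windows()]).
#' @param inlier_tol,n_trials,confidence RANSAC settings
#'   (see [ransac_fit_window()]).
#' @param ransac Set `FALSE` to disable RANSAC outlier removal (every window
#'   point then counts as an inlier of a plain least-squares fit).
#' @param seed Optional seed for the RANSAC draws.
#' @param max_points Interpolation centre cap (see [interpolate_surface()]).
#' @return A `surface_model` (see [interpolate_surface()]); the denoised
#'   inliers are attached as `$points`.
#' @export
estimate_surface <- function(bright, nx, ny, dz = 0.5,
                             width_fraction = 1 / 3, overlap_fraction = 0.5,
                             inlier_tol = 1.5, n_trials = 10000L,
                             confidence = 0.999, ransac = TRUE, seed = NULL,
                             max_points = 1500L) {
  if (is.null(bright$z_um)) bright$z_um <- (bright$z - 1) * dz
  windows <- make_windows(nx, ny, width_fraction, overlap_fraction)
  fits <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    inw <- bright[bright$x >= windows$x0[w] & bright$x <= windows$x1[w] &
                  bright$y >= windows$y0[w] & bright$y <= windows$y1[w], ,
                  drop = FALSE]
    if (nrow(inw) < 6L) next
    if (ransac) {
      # note fits[w] <- list(...): a NULL (no-fit) must not shrink the list
      fits[w] <- list(ransac_fit_window(inw, inlier_tol = inlier_tol,
                                        n_trials = n_trials,
                                        confidence = confidence,
                                        seed = if (is.null(seed)) NULL else seed + w))
    } else {
      cx <- (windows$x0[w] + windows$x1[w]) / 2
      cy <- (windows$y0[w] + windows$y1[w]) / 2
      sx <- max(1, windows$hw[w]); sy <- max(1, windows$hh[w])
      X <- quad_design((inw$x - cx) / sx, (inw$y - cy) / sy)
      fit <- stats::lm.fit(X, inw$z_um)
      beta <- fit$coefficients; beta[is.na(beta)] <- 0
      fits[[w]] <- list(coef = beta, center = c(cx, cy), scale = c(sx, sy),
                        inlier_idx = seq_len(nrow(inw)),
                        n_inliers = nrow(inw))
    }
  }
  denoised <- if (ransac) {
    fuse_and_filter(fits, windows, bright, inlier_tol = inlier_tol)
  } else {
    # outlier removal disabled: every point is kept, tol is irrelevant
    fuse_and_filter(fits, windows, bright, inlier_tol = Inf)
  }
  interpolate_surface(denoised, nx, ny, max_points = max_points)
}

#' Build a thin shell around an estimated surface
#'
#' The surface is snapped to its nearest z-plane `k0 = round(Z_hat/dz) + 1`
#' and the shell is the set of planes within `eps/2` of that plane:
#' layer index `l = k - k0` with `|l| <= floor(eps / (2 dz))`, clipped to the
#' stack. At the defaults (eps = 3 um, dz = 0.5 um) every supported column
#' holds 7 layers; the degenerate `eps = dz` case yields a single layer (the
#' snapped plane itself). Columns outside the surface support are empty.
#'
#' @param surface A `surface_model` (or a bare matrix of heights in um).
#' @param epsilon Shell thickness in um (default 3, slightly larger than the
#'   thickness of adherens junctions).
#' @param dz Axial pitch in um.
#' @param nz Number of z-planes in the stack.
#' @return An object of class `shell`: list with `k0` (nearest-plane index
#'   matrix), `half` (layer half-count), `nx`, `ny`, `nz`, `epsilon`, `dz`,
#'   `support`, `n_voxels`.
#' @export
build_shell <- function(surface, epsilon = 3, dz = 0.5, nz) {
  stopifnot(epsilon > 0)
  Z <- if (inherits(surface, "surface_model")) surface$Z_hat else surface
  support <- !is.na(Z)
  k0 <- matrix(NA_integer_, nrow(Z), ncol(Z))
  k0[support] <- as.integer(round(Z[support] / dz)) + 1L
  # clip columns whose snapped plane falls entirely off the stack
  off <- support & (k0 < 1L - floor(epsilon / (2 * dz)) |
                    k0 > nz + floor(epsilon / (2 * dz)))
  support[which(off)] <- FALSE
  half <- as.integer(floor(epsilon / (2 * dz)))
  lo <- pmax(1L, k0 - half); hi <- pmin(as.integer(nz), k0 + half)
  nvox <- sum(pmax(0L, hi[support] - lo[support] + 1L))
  structure(list(k0 = k0, half = half, nx = nrow(Z), ny = ncol(Z),
                 nz = as.integer(nz), epsilon = epsilon, dz = dz,
                 support = support, n_voxels = nvox),
            class = "shell")
}

#' All voxel coordinates of a shell
#' @param shell A [build_shell()] shell.
#' @return Integer matrix with columns x, y, z.
#' @export
shell_voxels <- function(shell) {
  cols <- which(shell$support)
  if (!length(cols))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  x <- ((cols - 1L) %% shell$nx) + 1L
  y <- ((cols - 1L) %/% shell$nx) + 1L
  k0 <- shell$k0[cols]
  out <- vector("list", 2L * shell$half + 1L)
  for (l in -shell$half:shell$half) {
    z <- k0 + l
    ok <- z >= 1L & z <= shell$nz
    out[[l + shell$half + 1L]] <- cbind(x = x[ok], y = y[ok], z = z[ok])
  }
  do.call(rbind, out)
}

#' Shell membership test
#' @param shell A [build_shell()] shell.
#' @param coords Voxel coordinates (matrix or data.frame x, y, z).
#' @return Logical vector.
#' @export
in_shell <- function(shell, coords) {
  coords <- as_coords(coords)
  col <- coords[, 1] + shell$nx * (coords[, 2] - 1L)
  sup <- shell$support[col]
  l <- coords[, 3] - shell$k0[col]
  sup & !is.na(l) & abs(l) <= shell$half
}

#' Signed layer index of voxels relative to the shell's surface
#'
#' `layer = 0` exactly on the plane nearest to the estimated surface;
#' positive layers are deeper (larger z). NA outside the surface support.
#' @param shell A [build_shell()] shell.
#' @param coords Voxel coordinates.
#' @return Integer vector of signed offsets.
#' @export
layer_index <- function(shell, coords) {
  coords <- as_coords(coords)
  col <- coords[, 1] + shell$nx * (coords[, 2] - 1L)
  as.integer(coords[, 3] - shell$k0[col])
}
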