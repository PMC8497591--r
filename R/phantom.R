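# Synthetic epithelial phantoms: curved surface, Voronoi cell-contour mesh,
# smooth multiplicative background, Gaussian-like noise, optional decoy
# surface, off-surface outliers and per-column photobleaching bookkeeping.
# Every downstream stage is validated against these known ground truths.

#' Phantom configuration
#'
#' Describes a synthetic epithelial volume: grid geometry, surface shape, cell
#' mesh, intensity model and noise. Defaults reproduce the acquisition
#' geometry used throughout the package: voxel pitch 0.27 x 0.27 x 0.5 um and
#' a 50-plane stack, with wing-disc-like 2.5 um cells.
#'
#' @param nx,ny,nz Voxel counts along x, y, z.
#' @param dx,dy,dz Voxel pitch in micrometres.
#' @param surface_kind One of `"flat"`, `"quadratic"`, `"sinusoidal"`,
#'   `"step"`, `"double"`. `"double"` adds a second, less populated decoy
#'   surface above the primary one.
#' @param surface_params Named list of surface coefficients in micrometres;
#'   missing entries take kind-specific defaults (see [make_surface()]).
#' @param cell_diameter Target mean cell diameter in micrometres.
#' @param contour_width Width of the junctional belt in micrometres; also
#'   sets the Gaussian blur emulating the excitation spot (sigma =
#'   contour_width / 3).
#' @param contour_amplitude Brightness of the junction mesh as a multiple of
#'   the local background intensity.
#' @param junction_thickness Axial extent (um) over which the contour mesh is
#'   extruded around the surface, half above and half below; default 2 um,
#'   slightly thinner than the 3 um shell scanned around the surface.
#' @param background_params Named list describing the smooth positive
#'   background `a(x,y,z) = b0 * (1 + gx*u + gy*v + gz*w + gzz*w^2)` with
#'   u, v, w the grid coordinates rescaled to \[-1, 1\].
#' @param noise_cv Coefficient of variation of the multiplicative background
#'   noise (`s = a * (1 + noise_cv * g)`, `g ~ N(0,1)`).
#' @param outlier_fraction Fraction of volume voxels set bright at random
#'   off-surface locations.
#' @param tissue_xy_coverage Fraction of the lateral field occupied by tissue
#'   (a centred ellipse of that area; 1 = full field).
#' @param bleach_rate Per-exposure fractional fluorescence loss applied by a
#'   bleaching oracle (0 disables; see [oracle_from_stack()]).
#' @param seed Integer seed; all phantom generation is reproducible given it.
#' @return An object of class `phantom_config`.
#' @seealso [phantom()], [make_surface()], [make_cell_mesh()], [render_stack()]
#' @export
phantom_config <- function(nx = 128L, ny = 128L, nz = 50L,
                           dx = 0.27, dy = 0.27, dz = 0.5,
                           surface_kind = c("quadratic", "flat", "sinusoidal",
                                            "step", "double"),
                           surface_params = list(),
                           cell_diameter = 2.5,
                           contour_width = 0.8,
                           contour_amplitude = 3,
                           junction_thickness = 2,
                           background_params = list(b0 = 100, gx = 0.25,
                                                    gy = -0.15, gz = 0.3,
                                                    gzz = -0.1),
                           noise_cv = 0.15,
                           outlier_fraction = 0,
                           tissue_xy_coverage = 1,
                           bleach_rate = 0,
                           seed = 1L) {
  surface_kind <- match.arg(surface_kind)
  cfg <- list(nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz),
              dx = dx, dy = dy, dz = dz,
              surface_kind = surface_kind, surface_params = surface_params,
              cell_diameter = cell_diameter, contour_width = contour_width,
              contour_amplitude = contour_amplitude,
              junction_thickness = junction_thickness,
              background_params = background_params,
              noise_cv = noise_cv, outlier_fraction = outlier_fraction,
              tissue_xy_coverage = tissue_xy_coverage,
              bleach_rate = bleach_rate, seed = as.integer(seed))
  validate_phantom_config(cfg)
  class(cfg) <- "phantom_config"
  cfg
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$nx >= 1L, cfg$ny >= 1L, cfg$nz >= 1L,
            cfg$dx > 0, cfg$dy > 0, cfg$dz > 0,
            cfg$noise_cv >= 0,
            cfg$outlier_fraction >= 0, cfg$outlier_fraction < 1,
            cfg$tissue_xy_coverage > 0, cfg$tissue_xy_coverage <= 1,
            cfg$contour_amplitude > 0,
            cfg$junction_thickness > 0,
            cfg$bleach_rate >= 0, cfg$bleach_rate < 1)
  invisible(cfg)
}

# Normalised grid coordinate in [-1, 1] (0 when n == 1).
norm_coord <- function(i, n) if (n == 1L) rep(0, length(i)) else 2 * (i - 1) / (n - 1) - 1

#' Tissue occupancy mask for a configuration
#'
#' A centred ellipse covering `tissue_xy_coverage` of the lateral field
#' (the whole field when coverage is ~1).
#' @noRd
tissue_mask <- function(cfg) {
  if (cfg$tissue_xy_coverage >= 0.999)
    return(matrix(TRUE, cfg$nx, cfg$ny))
  a <- cfg$nx * sqrt(cfg$tissue_xy_coverage / pi)
  b <- cfg$ny * sqrt(cfg$tissue_xy_coverage / pi)
  cx <- (cfg$nx + 1) / 2; cy <- (cfg$ny + 1) / 2
  u <- (seq_len(cfg$nx) - cx) / a
  v <- (seq_len(cfg$ny) - cy) / b
  outer(u^2, v^2, `+`) <= 1
}

#' Generate the ground-truth height field of a phantom
#'
#' Heights are in micrometres relative to the first z-plane (plane k sits at
#' physical depth (k-1)*dz). Lateral positions outside the tissue mask are
#' `NA`. For `surface_kind = "double"` a secondary decoy surface `Z2` is
#' returned alongside the primary field.
#'
#' Kind-specific `surface_params` (all in um unless noted):
#' * `flat`: `offset` (default mid-stack).
#' * `quadratic`: `zmin`, `zmax` — an inverted paraboloid with apex `zmax` at
#'   the field centre falling to `zmin` at the tissue edge.
#' * `sinusoidal`: `offset`, `amplitude`, `period`.
#' * `step`: `z_low`, `z_high`, `step_width` (lateral extent of the ramp),
#'   `center_frac` (ramp centre as a fraction of the x extent) — a plateau at
#'   `z_low`, a linear ramp of width `step_width`, a plateau at `z_high`.
#' * `double`: primary quadratic parameters plus `offset2` (decoy height
#'   above the primary surface) and `density2` (decoy mesh population
#'   relative to the primary, used by [render_stack()]).
#'
#' @param config A [phantom_config()].
#' @return List with `Z` (nx-by-ny matrix, um, NA off-tissue), `tissue`
#'   (logical matrix) and `Z2` (decoy height field or `NULL`).
#' @export
make_surface <- function(config) {
  cfg <- validate_phantom_config(config)
  p <- cfg$surface_params
  depth <- (cfg$nz - 1) * cfg$dz
  tis <- tissue_mask(cfg)
  u <- norm_coord(seq_len(cfg$nx), cfg$nx)
  v <- norm_coord(seq_len(cfg$ny), cfg$ny)
  Z2 <- NULL
  Z <- switch(cfg$surface_kind,
    flat = matrix(p$offset %||% (depth / 2), cfg$nx, cfg$ny),
    quadratic = ,
    double = {
      zmin <- p$zmin %||% (0.08 * depth)
      zmax <- p$zmax %||% (0.92 * depth)
      # rho = 1 at the tissue edge so the field spans [zmin, zmax] on tissue
      rr <- if (cfg$tissue_xy_coverage >= 0.999) 2 else 4 / pi * cfg$tissue_xy_coverage
      rho2 <- outer(u^2, v^2, `+`) / rr
      zmin + (zmax - zmin) * pmax(1 - rho2, 0)
    },
    sinusoidal = {
      off <- p$offset %||% (depth / 2)
      amp <- p$amplitude %||% (0.25 * depth)
      per <- p$period %||% (0.5 * min(cfg$nx * cfg$dx, cfg$ny * cfg$dy))
      xs <- (seq_len(cfg$nx) - 1) * cfg$dx
      ys <- (seq_len(cfg$ny) - 1) * cfg$dy
      off + amp * outer(sin(2 * pi * xs / per), sin(2 * pi * ys / per))
    },
    step = {
      z_lo <- p$z_low %||% (0.3 * depth)
      z_hi <- p$z_high %||% (0.3 * depth + 5)
      w <- p$step_width %||% 10
      cfrac <- p$center_frac %||% 0.5
      xs <- (seq_len(cfg$nx) - 1) * cfg$dx
      x0 <- cfrac * (cfg$nx - 1) * cfg$dx
      t <- pmin(1, pmax(0, (xs - x0) / w + 0.5))
      matrix(rep(z_lo + (z_hi - z_lo) * t, cfg$ny), cfg$nx, cfg$ny)
    },
    stop("unknown surface_kind: ", cfg$surface_kind)
  )
  if (cfg$surface_kind == "double") {
    off2 <- p$offset2 %||% 6
    Z2 <- pmin(Z + off2, depth)
    Z2[!tis] <- NA_real_
  }
  Z <- matrix(pmin(pmax(Z, 0), depth), cfg$nx, cfg$ny)
  Z[!tis] <- NA_real_
  list(Z = Z, tissue = tis, Z2 = Z2)
}

#' Poisson-disc samples on a lateral mask
#'
#' Dart throwing to saturation with a spatial hash; exclusion radius in
#' pixels. Returns a two-column matrix of (x, y) pixel positions.
#' @noRd
poisson_disc <- function(mask, r_px) {
  idx <- which(mask)
  if (!length(idx)) return(matrix(numeric(0), 0, 2))
  nx <- nrow(mask)
  cand <- sample(idx)          # caller controls the RNG seed
  cx <- ((cand - 1L) %% nx) + 1L
  cy <- ((cand - 1L) %/% nx) + 1L
  r2 <- r_px^2
  # spatial hash with cell size r/sqrt(2): at most one accepted point per cell
  cell <- r_px / sqrt(2)
  gx_n <- floor(nx / cell) + 1L
  gy_n <- floor(ncol(mask) / cell) + 1L
  grid <- matrix(0L, gx_n, gy_n)
  gxs <- floor((cx - 1) / cell) + 1L
  gys <- floor((cy - 1) / cell) + 1L
  off <- as.matrix(expand.grid(dx = -2:2, dy = -2:2))
  nmax <- length(cand)
  acc_x <- numeric(nmax); acc_y <- numeric(nmax); n_acc <- 0L
  for (i in seq_along(cand)) {
    ax <- gxs[i] + off[, 1]; ay <- gys[i] + off[, 2]
    ok <- ax >= 1L & ax <= gx_n & ay >= 1L & ay <= gy_n
    ids <- grid[cbind(ax[ok], ay[ok])]
    ids <- ids[ids > 0L]
    if (length(ids) &&
        any((acc_x[ids] - cx[i])^2 + (acc_y[ids] - cy[i])^2 < r2)) next
    n_acc <- n_acc + 1L
    acc_x[n_acc] <- cx[i]; acc_y[n_acc] <- cy[i]
    grid[gxs[i], gys[i]] <- n_acc
  }
  cbind(x = acc_x[seq_len(n_acc)], y = acc_y[seq_len(n_acc)])
}

#' Generate a cell-contour mesh by planar Voronoi partition
#'
#' Seeds a Poisson-disc point process on the tissue mask (exclusion radius
#' 0.74 * cell_diameter, calibrated so the mean equivalent cell diameter
#' matches `cell_diameter`), labels every tissue pixel by its nearest seed
#' and marks label boundaries, dilated to `contour_width`. The resulting
#' belt-like mesh of closed cell outlines emulates adherens junctions.
#'
#' @param config A [phantom_config()]; `cell_diameter` must be at least two
#'   pixels, otherwise cells would be unresolvable.
#' @param tissue Optional logical lateral mask (defaults to the config's
#'   tissue ellipse).
#' @param seed Optional seed override (defaults to `config$seed`).
#' @return List with `contour` (logical nx-by-ny mask of the dilated mesh),
#'   `labels` (integer matrix, NA off-tissue) and `seeds` (seed coordinates).
#' @export
make_cell_mesh <- function(config, tissue = NULL, seed = NULL) {
  cfg <- validate_phantom_config(config)
  d_px <- cfg$cell_diameter / cfg$dx
  if (d_px < 2)
    stop("cell_diameter smaller than 2 pixels: cells would be unresolvable")
  tis <- tissue %||% tissue_mask(cfg)
  with_seed(seed %||% cfg$seed, {
    pts <- poisson_disc(tis, 0.74 * d_px)
    labels <- matrix(NA_integer_, cfg$nx, cfg$ny)
    if (nrow(pts) >= 1L) {
      # at saturation every pixel lies within r of a seed, so a local box
      # around each seed suffices to find all pixels it can claim
      r_box <- ceiling(1.6 * 0.74 * d_px) + 1L
      bestd <- matrix(Inf, cfg$nx, cfg$ny)
      for (s in seq_len(nrow(pts))) {
        x0 <- max(1L, pts[s, 1] - r_box); x1 <- min(cfg$nx, pts[s, 1] + r_box)
        y0 <- max(1L, pts[s, 2] - r_box); y1 <- min(cfg$ny, pts[s, 2] + r_box)
        D <- outer((x0:x1 - pts[s, 1])^2, (y0:y1 - pts[s, 2])^2, `+`)
        upd <- D < bestd[x0:x1, y0:y1]
        if (any(upd)) {
          bestd[x0:x1, y0:y1][upd] <- D[upd]
          lb <- labels[x0:x1, y0:y1]; lb[upd] <- s
          labels[x0:x1, y0:y1] <- lb
        }
      }
      labels[!tis] <- NA_integer_
    }
    contour <- matrix(FALSE, cfg$nx, cfg$ny)
    if (nrow(pts) >= 2L) {
      lr <- shift_mat(labels, -1L, 0L); ld <- shift_mat(labels, 0L, -1L)
      thin <- (!is.na(labels) & !is.na(lr) & labels != lr) |
              (!is.na(labels) & !is.na(ld) & labels != ld)
      w_px <- max(1L, round(cfg$contour_width / cfg$dx))
      if (w_px > 1L) {
        r <- (w_px - 1) / 2
        b <- ceiling(r)
        for (ox in -b:b) for (oy in -b:b) {
          if (ox^2 + oy^2 <= (r + 0.5)^2)
            contour <- contour | shift_mat(thin, ox, oy, fill = FALSE)
        }
      } else contour <- thin
      contour <- contour & tis
    }
    list(contour = contour, labels = labels, seeds = pts)
  })
}

#' Render a phantom volume from its ground-truth components
#'
#' Builds the intensity stack `s = a * (1 + noise_cv * g + A * B)` where `a`
#' is the smooth positive background field, `g` is unit-variance Gaussian
#' noise, `A` is `contour_amplitude` and `B` is the junction structure
#' (contour mesh extruded axially over `junction_thickness`, plus decoy-mesh
#' and outlier voxels) blurred by an isotropic Gaussian emulating the
#' excitation spot. Intensities are clamped at zero.
#'
#' @param config A [phantom_config()].
#' @param surface Output of [make_surface()] (generated if missing).
#' @param mesh Output of [make_cell_mesh()] (generated if missing).
#' @return A `ground_truth` object: list with `volume` (class `scan_volume`:
#'   `data` array and `pitch`), `Z_true`, `tissue`, `contour_mask`,
#'   `bright_mask` (ground-truth epithelial bright voxels), `outlier_mask`,
#'   `decoy_mask` (bright voxels of the secondary surface, if any), `Z2`,
#'   and the `config`.
#' @export
render_stack <- function(config, surface = NULL, mesh = NULL) {
  cfg <- validate_phantom_config(config)
  surface <- surface %||% make_surface(cfg)
  mesh <- mesh %||% make_cell_mesh(cfg, tissue = surface$tissue)
  nx <- cfg$nx; ny <- cfg$ny; nz <- cfg$nz
  half_t <- cfg$junction_thickness / 2

  # ground-truth bright voxels: contour columns extruded +/- half_t around Z
  bright <- array(FALSE, c(nx, ny, nz))
  zphys <- (seq_len(nz) - 1) * cfg$dz
  extrude <- function(mask2d, Z) {
    out <- array(FALSE, c(nx, ny, nz))
    cols <- which(mask2d & !is.na(Z))
    if (length(cols)) {
      zc <- Z[cols]
      for (k in seq_len(nz)) {
        hit <- abs(zphys[k] - zc) <= half_t
        if (any(hit)) out[cols[hit] + nx * ny * (k - 1L)] <- TRUE
      }
    }
    out
  }
  bright <- extrude(mesh$contour, surface$Z)

  decoy <- array(FALSE, c(nx, ny, nz))
  with_seed(cfg$seed + 1L, {
    if (!is.null(surface$Z2)) {
      dens <- cfg$surface_params$density2 %||% 0.25
      mesh2 <- make_cell_mesh(cfg, tissue = surface$tissue, seed = cfg$seed + 7L)
      thin2 <- mesh2$contour & (matrix(stats::runif(nx * ny), nx, ny) < dens)
      decoy <- extrude(thin2, surface$Z2)
    }
    outl <- array(FALSE, c(nx, ny, nz))
    n_out <- round(cfg$outlier_fraction * nx * ny * nz)
    if (n_out > 0) {
      # off-surface: rejection-sample away from the primary junction band
      cand <- sample.int(nx * ny * nz, min(nx * ny * nz, 4L * n_out))
      ci <- arrayInd(cand, c(nx, ny, nz))
      zs <- surface$Z[ci[, 1] + nx * (ci[, 2] - 1L)]
      far <- is.na(zs) | abs((ci[, 3] - 1) * cfg$dz - zs) > cfg$junction_thickness
      keep <- cand[far][seq_len(min(n_out, sum(far)))]
      outl[keep] <- TRUE
    }

    B <- array(0, c(nx, ny, nz))
    B[bright | decoy | outl] <- 1
    sig_um <- cfg$contour_width / 3
    B <- gauss_blur3(B, c(sig_um / cfg$dx, sig_um / cfg$dy, sig_um / cfg$dz))

    a <- background_field(cfg)
    g <- array(stats::rnorm(nx * ny * nz), c(nx, ny, nz))
    dat <- a * (1 + cfg$noise_cv * g + cfg$contour_amplitude * B)
    dat[dat < 0] <- 0

    structure(list(
      volume = structure(list(data = dat, pitch = c(cfg$dx, cfg$dy, cfg$dz)),
                         class = "scan_volume"),
      Z_true = surface$Z, tissue = surface$tissue, Z2 = surface$Z2,
      contour_mask = mesh$contour, bright_mask = bright,
      decoy_mask = decoy, outlier_mask = outl,
      config = cfg), class = "ground_truth")
  })
}

#' Smooth positive background field of a configuration
#' @noRd
background_field <- function(cfg) {
  p <- cfg$background_params
  b0 <- p$b0 %||% 100
  u <- norm_coord(seq_len(cfg$nx), cfg$nx)
  v <- norm_coord(seq_len(cfg$ny), cfg$ny)
  w <- norm_coord(seq_len(cfg$nz), cfg$nz)
  lat <- 1 + outer((p$gx %||% 0) * u, (p$gy %||% 0) * v, `+`)
  ax <- (p$gz %||% 0) * w + (p$gzz %||% 0) * w^2
  arr <- array(0, c(cfg$nx, cfg$ny, cfg$nz))
  for (k in seq_len(cfg$nz)) arr[, , k] <- b0 * (lat + ax[k])
  if (any(arr <= 0)) stop("background_params produce non-positive intensities")
  arr
}

#' Generate a complete phantom (surface, mesh, rendered stack)
#'
#' Convenience wrapper calling [make_surface()], [make_cell_mesh()] and
#' [render_stack()] under the configuration's seed.
#' @param config A [phantom_config()].
#' @return A `ground_truth` object (see [render_stack()]).
#' @export
phantom <- function(config) {
  cfg <- validate_phantom_config(config)
  with_seed(cfg$seed, {
    surface <- make_surface(cfg)
    mesh <- make_cell_mesh(cfg, tissue = surface$tissue)
    render_stack(cfg, surface = surface, mesh = mesh)
  })
}
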