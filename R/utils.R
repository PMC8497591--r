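# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed`, then restores the
#' caller's RNG state, so that seeded package functions do not disturb user
#' simulations. A `NULL` seed leaves the RNG alone.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a matrix by an integer offset, padding with `fill`
#'
#' `out[x, y] == M[x - dx, y - dy]`, i.e. the content moves by (+dx, +dy).
#' @noRd
shift_mat <- function(M, dx, dy, fill = NA_real_) {
  nx <- nrow(M); ny <- ncol(M)
  out <- matrix(fill, nx, ny)
  x0 <- max(1L, 1L + dx); x1 <- min(nx, nx + dx)
  y0 <- max(1L, 1L + dy); y1 <- min(ny, ny + dy)
  if (x0 <= x1 && y0 <= y1)
    out[x0:x1, y0:y1] <- M[(x0 - dx):(x1 - dx), (y0 - dy):(y1 - dy), drop = FALSE]
  out
}

#' Shift a 3D array along one axis, padding with `fill`
#' @noRd
shift_arr <- function(arr, s, axis, fill = 0) {
  d <- dim(arr)
  if (s == 0L) return(arr)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  dst <- (max(1L, 1L + s)):(min(n, n + s))
  src <- dst - s
  idx_dst <- vector("list", 3L); idx_src <- vector("list", 3L)
  for (k in 1:3) { idx_dst[[k]] <- seq_len(d[k]); idx_src[[k]] <- seq_len(d[k]) }
  idx_dst[[axis]] <- dst; idx_src[[axis]] <- src
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]], drop = FALSE]
  out
}

#' Separable Gaussian blur of a 3D array (zero-padded borders)
#'
#' `sigma` is given per axis in voxels; a non-positive sigma skips that axis.
#' @noRd
gauss_blur3 <- function(arr, sigma) {
  for (axis in 1:3) {
    s <- sigma[axis]
    if (is.na(s) || s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- stats::dnorm(seq(-r, r), sd = s)
    k <- k / sum(k)
    acc <- array(0, dim(arr))
    for (i in seq(-r, r))
      acc <- acc + k[i + r + 1L] * shift_arr(arr, i, axis, fill = 0)
    arr <- acc
  }
  arr
}

#' Element-wise max of a list of matrices, ignoring NA
#' @noRd
pmax_list <- function(ms) {
  out <- ms[[1L]]
  if (length(ms) > 1L)
    for (k in 2:length(ms)) out <- pmax(out, ms[[k]], na.rm = TRUE)
  out
}

#' Column-wise maximum of values grouped by a lateral column id
#'
#' Returns an nx-by-ny matrix with NA for columns that received no value.
#' @noRd
column_max <- function(x, y, val, nx, ny) {
  mip <- matrix(NA_real_, nx, ny)
  if (length(val) == 0L) return(mip)
  col <- x + nx * (y - 1L)
  o <- order(col, val)
  last <- !duplicated(col[o], fromLast = TRUE)
  mip[col[o][last]] <- val[o][last]
  mip
}

#' Integer lateral offsets within a Euclidean radius, grouped by distance
#'
#' Excludes (0, 0). Groups are returned in increasing distance order; each
#' group is a matrix with columns dx, dy.
#' @noRd
offsets_by_distance <- function(beta) {
  b <- ceiling(beta)
  g <- expand.grid(dx = -b:b, dy = -b:b)
  d <- sqrt(g$dx^2 + g$dy^2)
  keep <- d > 0 & d <= beta + 1e-9
  g <- g[keep, , drop = FALSE]; d <- d[keep]
  dr <- round(d, 9)
  lapply(split(seq_len(nrow(g)), dr), function(i)
    cbind(dx = g$dx[i], dy = g$dy[i]))
}

#' Bounds check for voxel coordinates; errors name the first offender
#' @noRd
check_bounds <- function(coords, shape) {
  bad <- which(coords[, 1] < 1L | coords[, 1] > shape[1] |
               coords[, 2] < 1L | coords[, 2] > shape[2] |
               coords[, 3] < 1L | coords[, 3] > shape[3])
  if (length(bad)) {
    b <- coords[bad[1L], ]
    stop(sprintf("voxel coordinate out of bounds: (%d, %d, %d) for a %d x %d x %d stack",
                 b[1], b[2], b[3], shape[1], shape[2], shape[3]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Coerce a coordinate input (matrix or data.frame with x,y,z) to an integer matrix
#' @noRd
as_coords <- function(coords) {
  if (is.data.frame(coords)) coords <- cbind(coords$x, coords$y, coords$z)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  storage.mode(coords) <- "integer"
  colnames(coords) <- c("x", "y", "z")
  coords
}
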