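# Voxel-oracle abstraction and dose accounting. The oracle answers intensity
# queries on demand (emulating a microscope that can acquire an arbitrary set
# of voxels); the ledger makes "light dose = number of uniquely scanned
# voxels" a first-class quantity.

#' Create a dose ledger for a stack shape
#'
#' Tracks the set of uniquely acquired voxels (Omega) and the total number of
#' queries including repeats. Dose comparisons count unique voxels; repeated
#' exposures only show up in `n_queries`.
#'
#' @param shape Integer vector (nx, ny, nz).
#' @return An environment of class `dose_ledger` with fields `acquired`
#'   (logical array), `n_unique`, `n_queries`, `shape`.
#' @export
new_dose_ledger <- function(shape) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  e <- new.env(parent = emptyenv())
  e$acquired <- array(FALSE, shape)
  e$n_unique <- 0L
  e$n_queries <- 0L
  e$shape <- shape
  class(e) <- "dose_ledger"
  e
}

ledger_record <- function(ledger, coords) {
  if (is.null(ledger)) return(invisible(NULL))
  idx <- coords[, 1] + ledger$shape[1] *
    ((coords[, 2] - 1L) + ledger$shape[2] * (coords[, 3] - 1L))
  u <- unique(idx)
  new <- u[!ledger$acquired[u]]
  ledger$acquired[new] <- TRUE
  ledger$n_unique <- ledger$n_unique + length(new)
  ledger$n_queries <- ledger$n_queries + nrow(coords)
  invisible(NULL)
}

#' Fraction of the voxel space acquired so far
#'
#' `card(Omega) / (nx * ny * nz)`, in \[0, 1\].
#' @param ledger A [new_dose_ledger()] environment.
#' @return Numeric scalar.
#' @export
dose_fraction <- function(ledger) {
  ledger$n_unique / prod(ledger$shape)
}

#' Wrap a dense stack as a voxel oracle
#'
#' The oracle returns the stored voxel value for any in-bounds coordinate.
#' With `bleach_rate > 0` every query increments the exposure count of the
#' queried voxel's (x, y) column, and a voxel's returned value decays as
#' `(1 - bleach_rate)^exposures` with the column's exposure count at query
#' time — out-of-focus excitation irradiates the whole column, so exposure
#' anywhere along z bleaches the entire column.
#'
#' @param volume A `scan_volume` (list with `data` array and `pitch`) or a
#'   bare 3D array.
#' @param bleach_rate Per-exposure fractional fluorescence loss in \[0, 1).
#' @return An object of class `voxel_oracle`: list with `shape`, `pitch`,
#'   `bleach_rate` and a `query(coords)` function. Out-of-bounds queries are
#'   an error, never clamped.
#' @export
oracle_from_stack <- function(volume, bleach_rate = 0) {
  if (inherits(volume, "scan_volume")) {
    dat <- volume$data; pitch <- volume$pitch
  } else {
    dat <- volume; pitch <- c(1, 1, 1)
  }
  stopifnot(length(dim(dat)) == 3L, all(is.finite(dat)))
  shape <- dim(dat)
  env <- new.env(parent = emptyenv())
  env$colexp <- matrix(0L, shape[1], shape[2])
  query <- function(coords) {
    coords <- as_coords(coords)
    check_bounds(coords, shape)
    if (nrow(coords) == 0L) return(numeric(0))
    vals <- dat[coords]
    if (bleach_rate > 0) {
      colid <- coords[, 1] + shape[1] * (coords[, 2] - 1L)
      within <- stats::ave(seq_len(nrow(coords)), colid, FUN = seq_along) - 1L
      prior <- env$colexp[colid] + within
      vals <- vals * (1 - bleach_rate)^prior
      tab <- table(colid)
      ids <- as.integer(names(tab))
      env$colexp[ids] <- env$colexp[ids] + as.integer(tab)
    }
    vals
  }
  structure(list(shape = shape, pitch = pitch, bleach_rate = bleach_rate,
                 query = query, .env = env),
            class = "voxel_oracle")
}

#' Acquire a list of voxels through an oracle
#'
#' Returns the coordinates paired with the (possibly bleached) intensities
#' and updates the dose ledger. Duplicated coordinates are acquired (and
#' counted as queries) as many times as listed, but contribute once to the
#' unique dose.
#'
#' @param oracle A [oracle_from_stack()] oracle.
#' @param coords Integer matrix or data.frame with columns x, y, z.
#' @param ledger Optional [new_dose_ledger()]; updated in place.
#' @param iteration Tag stored alongside the samples (e.g. scan iteration).
#' @return A `sample_set` data.frame with columns `x`, `y`, `z`, `value`,
#'   `normalized` (NA until [normalize_samples()]) and `iteration`.
#' @export
acquire <- function(oracle, coords, ledger = NULL, iteration = NA_integer_) {
  coords <- as_coords(coords)
  if (nrow(coords) == 0L) {
    return(data.frame(x = integer(0), y = integer(0), z = integer(0),
                      value = numeric(0), normalized = numeric(0),
                      iteration = integer(0)))
  }
  vals <- oracle$query(coords)
  ledger_record(ledger, coords)
  data.frame(x = coords[, 1], y = coords[, 2], z = coords[, 3],
             value = vals, normalized = NA_real_,
             iteration = as.integer(iteration))
}
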