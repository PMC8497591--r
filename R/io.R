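# Plain interchange formats: multi-page TIFF stacks (one page per z-plane),
# single-page float TIFF height maps, tabular sample sets and YAML
# configurations.

#' Write a volume as a multi-page 16-bit TIFF
#'
#' One page per z-plane. Intensities are scaled to the 16-bit range; the
#' scale factor is stored in a sidecar text file `<path>.meta` together with
#' the voxel pitch so that [read_volume_tiff()] can restore physical values.
#'
#' @param volume A `scan_volume` or 3D array.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_volume_tiff <- function(volume, path) {
  if (inherits(volume, "scan_volume")) {
    dat <- volume$data; pitch <- volume$pitch
  } else {
    dat <- volume; pitch <- c(1, 1, 1)
  }
  mx <- max(dat, 1e-12)
  pages <- lapply(seq_len(dim(dat)[3]), function(k) t(dat[, , k]) / mx)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  writeLines(c(sprintf("scale: %.10g", mx / 65535),
               sprintf("pitch: %g %g %g", pitch[1], pitch[2], pitch[3]),
               sprintf("shape: %d %d %d", dim(dat)[1], dim(dat)[2], dim(dat)[3])),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a multi-page TIFF volume written by [write_volume_tiff()]
#'
#' Also accepts arbitrary multi-page TIFF stacks (no sidecar): values are
#' then returned as stored, with unit pitch.
#'
#' @param path TIFF path.
#' @return A `scan_volume`.
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.list(pages)) {
    dat <- simplify2array(lapply(pages, t))
  } else {
    dat <- array(t(pages), c(ncol(pages), nrow(pages), 1L))
  }
  pitch <- c(1, 1, 1); scale <- NULL
  meta <- paste0(path, ".meta")
  if (file.exists(meta)) {
    ln <- readLines(meta)
    sc <- sub("scale: ", "", ln[startsWith(ln, "scale:")])
    if (length(sc)) scale <- as.numeric(sc)
    pt <- sub("pitch: ", "", ln[startsWith(ln, "pitch:")])
    if (length(pt)) pitch <- as.numeric(strsplit(pt, " ")[[1]])
  }
  if (!is.null(scale)) dat <- dat * 65535 * scale
  structure(list(data = dat, pitch = pitch), class = "scan_volume")
}

#' Write an estimated height map as a 32-bit float TIFF
#'
#' Heights are rescaled to \[0, 1\] (the float TIFF range); the offset and
#' scale are stored in a `<path>.meta` sidecar. Unsupported positions are
#' stored as 0 and flagged in the sidecar-readable support convention used
#' by [read_surface_tiff()].
#'
#' @param surface A `surface_model` (or height matrix in um).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_surface_tiff <- function(surface, path) {
  Z <- if (inherits(surface, "surface_model")) surface$Z_hat else surface
  zmin <- min(Z, na.rm = TRUE); zmax <- max(Z, na.rm = TRUE)
  scale <- max(zmax - zmin, 1e-12)
  W <- (Z - zmin) / scale
  # NA (no support) is encoded as -1 before rescale, i.e. below the range
  W[is.na(W)] <- -1
  W <- (W + 1) / 2   # map [-1, 1] -> [0, 1]
  tiff::writeTIFF(t(W), path, bits.per.sample = 32L, reduce = FALSE)
  writeLines(c(sprintf("zmin: %.10g", zmin), sprintf("scale: %.10g", scale)),
             paste0(path, ".meta"))
  invisible(path)
}

#' Read a height map written by [write_surface_tiff()]
#' @param path TIFF path.
#' @return A `surface_model` with `Z_hat` (um, NA where unsupported).
#' @export
read_surface_tiff <- function(path) {
  W <- t(tiff::readTIFF(path))
  ln <- readLines(paste0(path, ".meta"))
  zmin <- as.numeric(sub("zmin: ", "", ln[startsWith(ln, "zmin:")]))
  scale <- as.numeric(sub("scale: ", "", ln[startsWith(ln, "scale:")]))
  V <- W * 2 - 1
  Z <- V * scale + zmin
  Z[V < -0.5] <- NA_real_
  structure(list(Z_hat = Z, support = !is.na(Z)), class = "surface_model")
}

#' Write a sample set as tab-separated text
#'
#' Columns: x, y, z, raw intensity, normalized intensity (may be NA),
#' iteration tag.
#' @param samples A `sample_set` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample set written by [write_samples()]
#' @param path Input path.
#' @return A `sample_set` data.frame.
#' @export
read_samples <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}

#' Read a phantom configuration from a YAML file
#'
#' Top-level keys are [phantom_config()] arguments; `surface_params` and
#' `background_params` are nested maps.
#' @param path YAML path.
#' @return A `phantom_config`.
#' @export
read_phantom_config <- function(path) {
  do.call(phantom_config, yaml::read_yaml(path))
}

#' Write a phantom configuration to YAML
#' @param config A `phantom_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phantom_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
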