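# Ground-truth evaluation of the scanning strategies: shell-capture of
# epithelial bright voxels, contour capture in maximum-intensity
# projections, dose accounting and photobleaching comparison.

#' Ground-truth shell around the true surface
#'
#' Builds a [build_shell()] shell from the phantom's true height field, with
#' the same voxelization convention as the estimated shell.
#'
#' @param gt A `ground_truth` phantom.
#' @param epsilon Shell thickness in um (default 3).
#' @return A `shell`.
#' @export
gt_shell <- function(gt, epsilon = 3) {
  build_shell(gt$Z_true, epsilon = epsilon, dz = gt$config$dz,
              nz = gt$config$nz)
}

#' Percentage of epithelial bright voxels captured by an estimated shell
#'
#' `100 * |GT-bright  ^  GT-shell  ^  S_hat| / |GT-bright  ^  GT-shell|`:
#' of the ground-truth bright voxels lying in the ground-truth shell, the
#' share that also falls in the estimated shell.
#'
#' @param est_shell The estimated [build_shell()] shell.
#' @param gt A `ground_truth` phantom.
#' @param epsilon Thickness of the ground-truth shell (default: the
#'   estimated shell's).
#' @return Percentage in \[0, 100\].
#' @export
bright_capture <- function(est_shell, gt, epsilon = est_shell$epsilon) {
  idx <- which(gt$bright_mask)
  if (!length(idx)) stop("ground truth has no bright voxels")
  coords <- arrayInd(idx, dim(gt$bright_mask))
  gsh <- gt_shell(gt, epsilon = epsilon)
  denom <- in_shell(gsh, coords)
  if (!any(denom)) stop("no ground-truth bright voxel lies in the ground-truth shell")
  num <- denom & in_shell(est_shell, coords)
  100 * sum(num) / sum(denom)
}

#' Percentage of ground-truth bright contour pixels recovered in a MIP
#'
#' Both projections are thresholded at T (bright = normalized value > T; NA
#' counts as not bright). Returns
#' `100 * |bright(MIP_strategy)  ^  bright(MIP_GT)| / |bright(MIP_GT)|`.
#'
#' @param mip Strategy maximum-intensity projection (normalized values).
#' @param mip_gt Ground-truth projection on the same lateral grid.
#' @param T Detection threshold.
#' @return Percentage in \[0, 100\].
#' @export
contour_capture <- function(mip, mip_gt, T) {
  stopifnot(all(dim(mip) == dim(mip_gt)))
  bg <- !is.na(mip_gt) & mip_gt > T
  if (!any(bg)) stop("ground-truth projection has no bright pixels")
  bs <- !is.na(mip) & mip > T
  100 * sum(bs & bg) / sum(bg)
}

#' Ground-truth maximum-intensity projection over a shell
#'
#' Normalizes the full stack inside the given shell with the pre-scan model
#' and projects the per-column maximum.
#'
#' @param gt A `ground_truth` phantom.
#' @param shell The shell to project over (typically [gt_shell()]).
#' @param model The pre-scan [fit_background()] model.
#' @return nx-by-ny matrix (NA outside the shell support).
#' @export
gt_mip <- function(gt, shell, model) {
  vox <- shell_voxels(shell)
  a <- predict_background(model, vox)
  r <- (gt$volume$data[vox] - a) / (a * model$sigma_hat)
  column_max(vox[, 1], vox[, 2], r, shell$nx, shell$ny)
}

#' Dose accounting table
#'
#' Scanned-volume percentages relative to the full stack for a set of
#' completed runs, plus the tight-bounding-box reference computed from the
#' ground-truth shell extents (the product of the per-axis occupied extents).
#'
#' @param ledgers Named list of [new_dose_ledger()] ledgers.
#' @param gt A `ground_truth` phantom.
#' @param epsilon Shell thickness used for the bounding-box z-extent.
#' @return Data.frame with columns `strategy`, `n_voxels`, `pct`.
#' @export
dose_table <- function(ledgers, gt, epsilon = 3) {
  cfg <- gt$config
  n_tot <- cfg$nx * cfg$ny * as.double(cfg$nz)
  gsh <- gt_shell(gt, epsilon = epsilon)
  vox <- shell_voxels(gsh)
  rows <- data.frame(
    strategy = c("full", "bounding_box"),
    n_voxels = c(n_tot,
                 if (nrow(vox)) (diff(range(vox[, 1])) + 1) *
                   (diff(range(vox[, 2])) + 1) * (diff(range(vox[, 3])) + 1)
                 else 0))
  for (nm in names(ledgers))
    rows <- rbind(rows, data.frame(strategy = nm,
                                   n_voxels = ledgers[[nm]]$n_unique))
  rows$pct <- 100 * rows$n_voxels / n_tot
  rows
}

#' Photobleaching comparison: hybrid half full-scan / half shell-scan imaging
#'
#' Repeatedly images a bleaching phantom with a hybrid strategy — one lateral
#' half of the field with a full scan (all z-planes), the other half with a
#' shell-scan — and tracks the mean raw maximum-intensity projection of each
#' half over time, relative to the first frame. Out-of-focus excitation
#' bleaches whole columns, so the fully scanned half accumulates `nz`
#' exposures per column and frame while the shell-scanned half accumulates
#' only the shell height, and decays correspondingly slower.
#'
#' @param gt A `ground_truth` phantom (its config's `bleach_rate` is used).
#' @param shell The shell to scan on the shell-scan half (typically
#'   [gt_shell()] or an estimated shell).
#' @param n_frames Number of consecutive frames to image.
#' @return Data.frame with columns `frame`, `region` ("full" or "shell"),
#'   `mean_mip`, `rel` (mean MIP relative to frame 1).
#' @export
bleaching_curves <- function(gt, shell, n_frames = 10L) {
  cfg <- gt$config
  oracle <- oracle_from_stack(gt$volume, bleach_rate = cfg$bleach_rate)
  half_x <- cfg$nx %/% 2L
  full_coords <- as.matrix(expand.grid(x = seq_len(half_x),
                                       y = seq_len(cfg$ny),
                                       z = seq_len(cfg$nz)))
  vox <- shell_voxels(shell)
  shell_coords <- vox[vox[, 1] > half_x, , drop = FALSE]
  svox_full <- vox[vox[, 1] <= half_x, , drop = FALSE]
  out <- list()
  tmp <- array(NA_real_, c(cfg$nx, cfg$ny, cfg$nz))
  for (f in seq_len(n_frames)) {
    vals_full <- oracle$query(full_coords)
    vals_shell <- oracle$query(shell_coords)
    # compare like with like: MIP over the shell voxels on both halves
    tmp[full_coords] <- vals_full
    mip_full <- column_max(svox_full[, 1], svox_full[, 2], tmp[svox_full],
                           cfg$nx, cfg$ny)
    mip_shell <- column_max(shell_coords[, 1], shell_coords[, 2], vals_shell,
                            cfg$nx, cfg$ny)
    out[[f]] <- data.frame(
      frame = f,
      region = c("full", "shell"),
      mean_mip = c(mean(mip_full, na.rm = TRUE), mean(mip_shell, na.rm = TRUE)))
  }
  res <- do.call(rbind, out)
  first <- res$mean_mip[match(paste(1, res$region), paste(res$frame, res$region))]
  res$rel <- res$mean_mip / first
  res
}
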