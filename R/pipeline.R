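# End-to-end convenience wrapper: pre-scan -> normalization -> detection ->
# surface -> shell -> (shell-scan | propagative scan). This is the entry
# point used by the command-line script and by most evaluation runs.

#' Run the full smart-scanning pipeline against a voxel oracle
#'
#' Draws the fractional pre-scan, fits the background normalization, detects
#' bright points by significance test, estimates the surface of interest
#' with windowed RANSAC fits and biharmonic interpolation, builds the
#' epsilon-thick shell, and executes the requested scanning strategy.
#'
#' @param oracle A [oracle_from_stack()] oracle (or a `scan_volume` /
#'   3D array, which is wrapped automatically without bleaching).
#' @param strategy `"shell"` or `"propagative"`.
#' @param eta Pre-scan sampling fraction (default 0.001, i.e. 0.1%).
#' @param pfa Probability of false alarm for bright-point detection
#'   (default 0.01).
#' @param epsilon Shell thickness in um (default 3).
#' @param beta Maximum NN prediction distance in pixels (propagative scan).
#' @param n0 In-shell seed count at iteration 1; default the pre-scan size.
#' @param dz Axial pitch in um (taken from the oracle's pitch if available).
#' @param seed Master seed; sub-draws (pre-scan, RANSAC, seeding) derive
#'   from it.
#' @param width_fraction,overlap_fraction,ransac,n_trials Surface-estimation
#'   settings passed to [estimate_surface()].
#' @param max_iterations Propagative-scan safety cap.
#' @return List with `prescan` (normalized `sample_set`), `model`, `T`,
#'   `bright`, `surface`, `shell`, `result` (a `scan_result`), `ledger`
#'   (includes the pre-scan dose) and `scan_ledger` (the strategy's own
#'   dose, without the pre-scan).
#' @export
run_smart_scan <- function(oracle, strategy = c("shell", "propagative"),
                           eta = 0.001, pfa = 0.01, epsilon = 3,
                           beta = 1, n0 = NULL, dz = NULL, seed = 1L,
                           width_fraction = 1 / 3, overlap_fraction = 0.5,
                           ransac = TRUE, n_trials = 10000L,
                           max_iterations = 100L) {
  strategy <- match.arg(strategy)
  if (!inherits(oracle, "voxel_oracle")) oracle <- oracle_from_stack(oracle)
  shape <- oracle$shape
  dz <- dz %||% oracle$pitch[3]

  coords <- draw_prescan(shape, eta, seed = seed)
  ledger <- new_dose_ledger(shape)
  prescan <- acquire(oracle, coords, ledger = ledger, iteration = 0L)
  model <- fit_background(prescan, shape)
  prescan <- normalize_samples(prescan, model)
  T <- threshold_from_pfa(pfa)
  bright <- detect_bright(prescan, T)
  surface <- estimate_surface(bright, nx = shape[1], ny = shape[2], dz = dz,
                              width_fraction = width_fraction,
                              overlap_fraction = overlap_fraction,
                              ransac = ransac, n_trials = n_trials,
                              seed = seed + 1000L)
  shell <- build_shell(surface, epsilon = epsilon, dz = dz, nz = shape[3])
  scan_ledger <- new_dose_ledger(shape)
  result <- if (strategy == "shell") {
    r <- shell_scan(oracle, shell, model, ledger = scan_ledger)
    ledger_record(ledger, shell_voxels(shell))
    r
  } else {
    params <- propagative_params(beta = beta,
                                 n0 = n0 %||% nrow(prescan),
                                 T = T, max_iterations = max_iterations,
                                 seed = seed + 2000L)
    r <- propagative_scan(oracle, shell, model, params, prescan,
                          ledger = ledger)
    ledger_record(scan_ledger, as_coords(r$samples))
    r
  }
  list(prescan = prescan, model = model, T = T, bright = bright,
       surface = surface, shell = shell, result = result,
       ledger = ledger, scan_ledger = scan_ledger)
}
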