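# The two smart-scanning strategies, executed against a voxel oracle:
# the exhaustive shell-scan, and the iterative propagative scan that follows
# cell outlines by nearest-neighbor extrapolation of the normalized
# intensity within shell layers.

#' Parameters of the propagative scan
#'
#' @param beta Maximum nearest-neighbor prediction distance in xy pixels
#'   (predictions further than `beta` from their NN are not made).
#' @param n0 Number of additional random in-shell seed voxels acquired at
#'   iteration 1; defaults (elsewhere) to the pre-scan size.
#' @param T Detection threshold shared with the pre-scan significance test.
#' @param max_iterations Safety cap; convergence (an iteration without new
#'   acquisitions) is the primary stop.
#' @param seed Integer seed for the in-shell seeding.
#' @return A `propagative_params` list.
#' @export
propagative_params <- function(beta = 1, n0 = 0L, T = threshold_from_pfa(0.01),
                               max_iterations = 100L, seed = NULL) {
  stopifnot(beta >= 1, n0 >= 0)
  structure(list(beta = beta, n0 = as.integer(n0), T = T,
                 max_iterations = as.integer(max_iterations), seed = seed),
            class = "propagative_params")
}

# ---- internal layered state ---------------------------------------------

# The scan state is a list of per-layer matrices of acquired normalized
# values (NA = unexplored) plus the per-column best acquired value.
state_init <- function(shell) {
  nl <- 2L * shell$half + 1L
  inlayer <- vector("list", nl)
  V <- vector("list", nl)
  for (l in -shell$half:shell$half) {
    k <- shell$k0 + l
    m <- shell$support & k >= 1L & k <= shell$nz
    m[is.na(m)] <- FALSE
    inlayer[[l + shell$half + 1L]] <- m
    V[[l + shell$half + 1L]] <- matrix(NA_real_, shell$nx, shell$ny)
  }
  list(V = V, inlayer = inlayer,
       best = matrix(NA_real_, shell$nx, shell$ny))
}

# Insert acquired in-shell samples (keeps the max where duplicated).
state_add <- function(state, shell, samples) {
  if (nrow(samples) == 0L) return(state)
  col <- samples$x + shell$nx * (samples$y - 1L)
  l <- samples$z - shell$k0[col]
  ok <- !is.na(l) & abs(l) <= shell$half
  for (li in unique(l[ok])) {
    sel <- ok & l == li
    M <- state$V[[li + shell$half + 1L]]
    idx <- col[sel]
    M[idx] <- pmax(M[idx], samples$normalized[sel], na.rm = TRUE)
    state$V[[li + shell$half + 1L]] <- M
  }
  state$best <- pmax(state$best, column_max(samples$x[ok], samples$y[ok],
                                            samples$normalized[ok],
                                            shell$nx, shell$ny), na.rm = TRUE)
  state
}

# Per-layer NN prediction by increasing-distance matrix shifts. At each
# distance ring the proposal is the max over equidistant acquired neighbors
# (the tie rule: the tied point with highest normalized intensity wins);
# once a voxel has a prediction from a nearer ring it is never overwritten.
nn_predict_layers <- function(state, shell, beta) {
  offs <- offsets_by_distance(beta)
  preds <- vector("list", length(state$V))
  for (li in seq_along(state$V)) {
    M <- state$V[[li]]
    inl <- state$inlayer[[li]]
    P <- matrix(NA_real_, shell$nx, shell$ny)
    if (any(!is.na(M))) {
      for (grp in offs) {
        prop <- NULL
        for (r in seq_len(nrow(grp))) {
          sh <- shift_mat(M, grp[r, 1], grp[r, 2])
          prop <- if (is.null(prop)) sh else pmax(prop, sh, na.rm = TRUE)
        }
        fill <- is.na(P) & !is.na(prop) & inl & is.na(M)
        P[fill] <- prop[fill]
      }
    }
    preds[[li]] <- P
  }
  preds
}

#' Nearest-neighbor prediction of normalized intensity in the shell
#'
#' For every unexplored shell voxel, finds the acquired voxel in the same
#' shell layer at smallest xy-Euclidean distance (ties broken by highest
#' normalized intensity) and proposes its normalized value as the
#' prediction. Voxels whose nearest same-layer neighbor is farther than
#' `beta` pixels receive no prediction.
#'
#' @param acquired A `sample_set` of acquired voxels with `normalized`
#'   values (only in-shell samples act as neighbors).
#' @param shell A [build_shell()] shell.
#' @param beta Maximum NN distance in pixels.
#' @return Data.frame `x`, `y`, `z`, `layer`, `r_pred` for predicted voxels.
#' @export
nn_predict <- function(acquired, shell, beta) {
  state <- state_init(shell)
  state <- state_add(state, shell, acquired)
  preds <- nn_predict_layers(state, shell, beta)
  out <- vector("list", length(preds))
  for (li in seq_along(preds)) {
    idx <- which(!is.na(preds[[li]]))
    if (!length(idx)) next
    l <- li - shell$half - 1L
    x <- ((idx - 1L) %% shell$nx) + 1L
    y <- ((idx - 1L) %/% shell$nx) + 1L
    out[[li]] <- data.frame(x = x, y = y, z = shell$k0[idx] + l,
                            layer = l, r_pred = preds[[li]][idx])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      layer = integer(0), r_pred = numeric(0))
  res[order(res$x, res$y, res$z), , drop = FALSE]
}

# Brute-force reference NN prediction (exhaustive pairwise distances);
# used as an oracle in tests, never in production paths.
nn_predict_bruteforce <- function(acquired, shell, beta) {
  col <- acquired$x + shell$nx * (acquired$y - 1L)
  lay <- acquired$z - shell$k0[col]
  ok <- !is.na(lay) & abs(lay) <= shell$half
  acq <- data.frame(x = acquired$x[ok], y = acquired$y[ok],
                    layer = lay[ok], r = acquired$normalized[ok])
  vox <- shell_voxels(shell)
  vcol <- vox[, 1] + shell$nx * (vox[, 2] - 1L)
  vlay <- vox[, 3] - shell$k0[vcol]
  explored <- paste(acquired$x[ok], acquired$y[ok], acquired$z[ok])
  res <- list()
  for (i in seq_len(nrow(vox))) {
    if (paste(vox[i, 1], vox[i, 2], vox[i, 3]) %in% explored) next
    cand <- acq[acq$layer == vlay[i], , drop = FALSE]
    if (!nrow(cand)) next
    d <- sqrt((cand$x - vox[i, 1])^2 + (cand$y - vox[i, 2])^2)
    dmin <- min(d)
    if (dmin > beta + 1e-9) next
    r <- max(cand$r[abs(d - dmin) < 1e-9])
    res[[length(res) + 1L]] <- data.frame(x = vox[i, 1], y = vox[i, 2],
                                          z = vox[i, 3], layer = vlay[i],
                                          r_pred = r)
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(x = integer(0), y = integer(0), z = integer(0),
               layer = integer(0), r_pred = numeric(0))
  out[order(out$x, out$y, out$z), , drop = FALSE]
}

# Selection rule on layer-matrix predictions. Keeps predictions above T,
# one voxel per lateral column (the highest prediction; ties resolved to
# the layer closest to the surface), and drops columns where an acquired
# in-shell voxel already matches or beats the best prediction.
select_from_layers <- function(preds, best, shell, T) {
  bestpred <- pmax_list(preds)
  sel <- !is.na(bestpred) & bestpred > T &
    (is.na(best) | best < bestpred)
  idx <- which(sel)
  if (!length(idx))
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  nl <- length(preds)
  lorder <- order(abs(seq_len(nl) - (shell$half + 1L)), seq_len(nl))
  chosen_l <- rep(NA_integer_, length(idx))
  for (li in lorder) {
    hit <- is.na(chosen_l) & !is.na(preds[[li]][idx]) &
      preds[[li]][idx] == bestpred[idx]
    chosen_l[hit] <- li - shell$half - 1L
  }
  x <- ((idx - 1L) %% shell$nx) + 1L
  y <- ((idx - 1L) %/% shell$nx) + 1L
  cbind(x = x, y = y, z = shell$k0[idx] + chosen_l)
}

#' Select the voxels to acquire at a propagative iteration
#'
#' Applies the acquisition rule to NN predictions: keep predictions above
#' the threshold; within each lateral column keep only the voxel with the
#' highest prediction; drop the column entirely if a voxel with equal or
#' higher normalized intensity has already been acquired in the shell there.
#'
#' @param predictions Data.frame from [nn_predict()].
#' @param acquired In-shell acquired samples (`sample_set` with `normalized`).
#' @param shell A [build_shell()] shell.
#' @param T Detection threshold.
#' @return Integer coordinate matrix of voxels to acquire.
#' @export
select_new_acquisitions <- function(predictions, acquired, shell, T) {
  state <- state_init(shell)
  state <- state_add(state, shell, acquired)
  preds <- vector("list", length(state$V))
  for (li in seq_along(preds)) preds[[li]] <- matrix(NA_real_, shell$nx, shell$ny)
  if (nrow(predictions)) {
    col <- predictions$x + shell$nx * (predictions$y - 1L)
    l <- predictions$z - shell$k0[col]
    for (li in unique(l)) {
      sel <- l == li
      preds[[li + shell$half + 1L]][col[sel]] <- predictions$r_pred[sel]
    }
  }
  select_from_layers(preds, state$best, shell, T)
}

#' Draw random seed voxels inside the shell
#'
#' @param shell A [build_shell()] shell (must be non-empty).
#' @param n Number of distinct shell voxels to draw.
#' @param seed Integer seed.
#' @return Integer coordinate matrix (n rows).
#' @export
seed_in_shell <- function(shell, n, seed = NULL) {
  vox <- shell_voxels(shell)
  if (nrow(vox) == 0L) stop("shell is empty")
  if (n > nrow(vox))
    stop("cannot seed ", n, " voxels in a shell of ", nrow(vox))
  if (n == 0L) return(vox[integer(0), , drop = FALSE])
  vox[with_seed(seed, sample.int(nrow(vox), n)), , drop = FALSE]
}

#' Exhaustive scan of the shell
#'
#' Acquires every shell voxel exactly once, normalizes the intensities with
#' the pre-scan's background model and returns the result with its
#' maximum-intensity projection.
#'
#' @param oracle A [oracle_from_stack()] oracle.
#' @param shell A non-empty [build_shell()] shell.
#' @param model The pre-scan [fit_background()] model.
#' @param ledger Optional dose ledger, updated in place.
#' @return A `scan_result`: list with `samples`, `mip` (per-column max
#'   normalized value over the shell, NA where no acquisition), `n_acquired`,
#'   `strategy`.
#' @export
shell_scan <- function(oracle, shell, model, ledger = NULL) {
  vox <- shell_voxels(shell)
  if (nrow(vox) == 0L) stop("shell is empty")
  samples <- acquire(oracle, vox, ledger = ledger, iteration = 0L)
  samples <- normalize_samples(samples, model)
  mip <- column_max(samples$x, samples$y, samples$normalized,
                    shell$nx, shell$ny)
  structure(list(samples = samples, mip = mip, n_acquired = nrow(samples),
                 strategy = "shell"),
            class = "scan_result")
}

#' Iterative propagative scan of cell outlines
#'
#' Starting from the pre-scan (iteration 0; its in-shell points are carried
#' into the state with their normalized values) and `n0` random in-shell
#' seeds (iteration 1), repeatedly predicts the normalized intensity of
#' unexplored shell voxels by same-layer nearest-neighbor extrapolation
#' (capped at distance `beta`), acquires only the voxels predicted bright
#' (prediction > T, one per lateral column, unless a brighter voxel was
#' already acquired in that column), and stops at the first iteration
#' without new acquisitions (or at `max_iterations`).
#'
#' The background normalization is frozen from the pre-scan model for all
#' iterations.
#'
#' @param oracle A [oracle_from_stack()] oracle.
#' @param shell A non-empty [build_shell()] shell.
#' @param model The pre-scan [fit_background()] model.
#' @param params A [propagative_params()] list.
#' @param prescan_samples Normalized pre-scan `sample_set` (iteration 0).
#' @param ledger Optional dose ledger, updated in place (the pre-scan should
#'   already be recorded on it by the caller).
#' @return A `scan_result` with `samples` (acquisitions from iteration 1 on,
#'   tagged by iteration), `mip`, `per_iteration_counts`, `iterations`,
#'   `converged`, `acq_per_column` (z-acquisition counts per lateral
#'   position, including carried pre-scan points), `strategy`.
#' @export
propagative_scan <- function(oracle, shell, model, params, prescan_samples,
                             ledger = NULL) {
  if (is.null(model)) stop("a pre-scan normalization model is required")
  if (any(is.na(prescan_samples$normalized)))
    stop("prescan samples must be normalized")
  state <- state_init(shell)
  state <- state_add(state, shell, prescan_samples)

  all_samples <- list()
  counts <- integer(0)

  # iteration 1: random in-shell seeding
  seeds <- seed_in_shell(shell, min(params$n0, shell$n_voxels),
                         seed = params$seed)
  s1 <- acquire(oracle, seeds, ledger = ledger, iteration = 1L)
  s1 <- normalize_samples(s1, model)
  state <- state_add(state, shell, s1)
  all_samples[[1L]] <- s1
  counts[1L] <- nrow(s1)

  it <- 1L
  converged <- FALSE
  while (it < params$max_iterations) {
    it <- it + 1L
    preds <- nn_predict_layers(state, shell, params$beta)
    coords <- select_from_layers(preds, state$best, shell, params$T)
    counts[it] <- nrow(coords)
    if (nrow(coords) == 0L) { converged <- TRUE; break }
    si <- acquire(oracle, coords, ledger = ledger, iteration = it)
    si <- normalize_samples(si, model)
    state <- state_add(state, shell, si)
    all_samples[[it]] <- si
  }
  samples <- do.call(rbind, all_samples)
  acq <- rbind(prescan_samples[, c("x", "y")], samples[, c("x", "y")])
  acq_map <- matrix(0L, shell$nx, shell$ny)
  tab <- table(acq$x + shell$nx * (acq$y - 1L))
  acq_map[as.integer(names(tab))] <- as.integer(tab)
  structure(list(samples = samples, mip = state$best,
                 per_iteration_counts = counts, iterations = it,
                 converged = converged, acq_per_column = acq_map,
                 strategy = "propagative"),
            class = "scan_result")
}

#' Maximum-intensity projection of a scan result over the shell
#'
#' Per lateral column, the maximum normalized value among acquired shell
#' voxels; columns without any acquisition are NA (flagged missing, not 0).
#'
#' @param result A `scan_result`.
#' @param shell The shell the scan ran on.
#' @return nx-by-ny matrix with NA for unacquired columns.
#' @export
max_intensity_projection <- function(result, shell) {
  s <- result$samples
  keep <- in_shell(shell, s)
  column_max(s$x[keep], s$y[keep], s$normalized[keep], shell$nx, shell$ny)
}
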