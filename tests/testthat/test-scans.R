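# Shell-scan and propagative scan dynamics.

make_norm_model <- function(sigma = 1) {
  # background model of a constant unit background: r = (s - 1) / sigma
  co <- draw_prescan(c(30, 30, 50), 0.3, seed = 2)
  m <- fit_background(sample_set(co[, 1], co[, 2], co[, 3], value = 1),
                      c(30, 30, 50))
  m$sigma_hat <- sigma
  m
}

test_that("shell-scan acquires the whole shell exactly once", {
  sh <- flat_shell(nx = 30, ny = 30, nz = 50, z_um = 12)
  vol <- array(1, c(30, 30, 50))
  vol[, , 25] <- 5    # bright on the central plane
  o <- oracle_from_stack(vol)
  led <- new_dose_ledger(c(30, 30, 50))
  m <- make_norm_model()
  res <- shell_scan(o, sh, m, ledger = led)
  expect_equal(res$n_acquired, 30 * 30 * 7)
  expect_equal(dose_fraction(led), 7 / 50)
  expect_equal(led$n_queries, led$n_unique)
  # emulation fidelity
  expect_identical(res$samples$value,
                   vol[cbind(res$samples$x, res$samples$y, res$samples$z)])
  # MIP picks the brightest plane everywhere
  expect_true(all(abs(res$mip - 4) < 1e-9))
  expect_error(shell_scan(o, build_shell(matrix(NA_real_, 3, 3), 3, 0.5, 50),
                          m), "empty")
})

test_that("in-shell seeding is uniform, exact and reproducible", {
  sh <- flat_shell(nx = 12, ny = 12, nz = 40, z_um = 10)
  expect_equal(nrow(seed_in_shell(sh, 0, seed = 1)), 0L)
  all_vox <- seed_in_shell(sh, sh$n_voxels, seed = 1)
  expect_equal(nrow(all_vox), 12 * 12 * 7)
  expect_true(all(in_shell(sh, all_vox)))
  s1 <- seed_in_shell(sh, 50, seed = 3); s2 <- seed_in_shell(sh, 50, seed = 3)
  expect_identical(s1, s2)
  expect_error(seed_in_shell(sh, sh$n_voxels + 1, seed = 1), "cannot seed")
})

test_that("NN prediction follows layers, distance cap and the tie rule", {
  sh <- flat_shell(nx = 15, ny = 15, nz = 50, z_um = 12)
  acq <- sample_set(8, 8, 25, normalized = 5)   # one voxel in layer 0
  p <- nn_predict(acq, sh, beta = 2)
  expect_true(all(p$layer == 0L))
  d <- sqrt((p$x - 8)^2 + (p$y - 8)^2)
  expect_true(all(d <= 2 + 1e-9) && all(d > 0))
  expect_true(all(p$r_pred == 5))
  # equidistant neighbors: the brighter one wins
  acq2 <- sample_set(c(6, 10), c(8, 8), c(25, 25), normalized = c(2, 4))
  p2 <- nn_predict(acq2, sh, beta = 2)
  mid <- p2[p2$x == 8 & p2$y == 8 & p2$z == 25, ]
  expect_equal(mid$r_pred, 4)
  # out-of-shell acquisitions are never NN candidates
  p3 <- nn_predict(sample_set(8, 8, 2, normalized = 9), sh, beta = 3)
  expect_equal(nrow(p3), 0L)
})

test_that("NN prediction matches an exhaustive brute-force search", {
  set.seed(42)
  for (trial in 1:4) {
    Z <- matrix(5 + 0.01 * outer(1:30, 1:30, `+`), 30, 30)
    sh <- build_shell(Z, epsilon = 1.5, dz = 0.5, nz = 40)   # 3 layers
    vox <- shell_voxels(sh)
    idx <- sample(nrow(vox), 25)
    acq <- sample_set(vox[idx, 1], vox[idx, 2], vox[idx, 3],
                      normalized = round(runif(25) * 10, 3))
    beta <- sample(c(1, 2, 3.5, 5), 1)
    a <- nn_predict(acq, sh, beta)
    b <- smartscan:::nn_predict_bruteforce(acq, sh, beta)
    expect_equal(nrow(a), nrow(b))
    expect_equal(a$x, b$x); expect_equal(a$y, b$y); expect_equal(a$z, b$z)
    expect_equal(a$r_pred, b$r_pred)
  }
})

test_that("acquisition selection: threshold, per-column max, column veto", {
  sh <- flat_shell(nx = 10, ny = 10, nz = 50, z_um = 12)
  acq <- sample_set(2, 2, 25, normalized = 1)
  preds <- data.frame(x = c(5, 5, 7), y = c(5, 5, 7), z = c(24, 26, 25),
                      layer = c(-1, 1, 0), r_pred = c(2.5, 3.0, 2.0))
  sel <- select_new_acquisitions(preds, acq, sh, T = 2.33)
  expect_equal(nrow(sel), 1L)       # 2.0 below threshold; column keeps max
  expect_equal(unname(sel[1, ]), c(5L, 5L, 26L))
  # all predictions below threshold -> nothing (convergence trigger)
  sel0 <- select_new_acquisitions(preds, acq, sh, T = 5)
  expect_equal(nrow(sel0), 0L)
  # a brighter acquired voxel in the column vetoes it
  acq2 <- sample_set(c(2, 5), c(2, 5), c(25, 25), normalized = c(1, 3.5))
  sel2 <- select_new_acquisitions(preds, acq2, sh, T = 2.33)
  expect_equal(nrow(sel2), 0L)
})

test_that("propagative scan converges immediately without bright structure", {
  vol <- array(100, c(25, 25, 50))
  o <- oracle_from_stack(vol)
  led <- new_dose_ledger(c(25, 25, 50))
  ps_co <- draw_prescan(c(25, 25, 50), 0.01, seed = 7)
  ps <- acquire(o, ps_co, ledger = led)
  m <- fit_background(ps, c(25, 25, 50))
  ps <- normalize_samples(ps, m)
  sh <- flat_shell(nx = 25, ny = 25, nz = 50, z_um = 12)
  pars <- propagative_params(beta = 1, n0 = nrow(ps),
                             T = threshold_from_pfa(0.01), seed = 8)
  res <- propagative_scan(o, sh, m, pars, ps, ledger = led)
  expect_true(res$converged)
  expect_equal(res$iterations, 2L)
  expect_equal(res$per_iteration_counts[2], 0L)
  expect_lte(led$n_unique, nrow(ps_co) + nrow(ps))   # pre-scan + N0 only
})

test_that("propagative scan follows contours and converges on phantoms", {
  gt <- small_phantom()
  res <- run_smart_scan(gt$volume, "propagative", eta = 0.002, beta = 2,
                        seed = 17)
  counts <- res$result$per_iteration_counts
  expect_true(res$result$converged)
  expect_equal(counts[length(counts)], 0L)
  # acquisitions confined to the shell
  expect_true(all(in_shell(res$shell, res$result$samples)))
  # dose bounded by shell + pre-scan + seeds
  expect_lte(res$ledger$n_unique,
             res$shell$n_voxels + 2 * nrow(res$prescan))
  # the propagative scan is much sparser than the shell-scan
  expect_lt(res$scan_ledger$n_unique, res$shell$n_voxels)
})

test_that("propagative scans are reproducible under fixed seeds", {
  gt <- small_phantom()
  r1 <- run_smart_scan(gt$volume, "propagative", eta = 0.002, beta = 1,
                       seed = 23)
  r2 <- run_smart_scan(gt$volume, "propagative", eta = 0.002, beta = 1,
                       seed = 23)
  expect_identical(r1$result$samples, r2$result$samples)
  expect_identical(r1$result$per_iteration_counts,
                   r2$result$per_iteration_counts)
})

test_that("propagation reaches contour columns connected to seeds", {
  # noise-free phantom: junction signal enormous relative to the floor
  cfg <- phantom_config(nx = 80, ny = 80, nz = 30, surface_kind = "flat",
                        noise_cv = 0, cell_diameter = 4, seed = 19L)
  gt <- phantom(cfg)
  res <- run_smart_scan(gt$volume, "propagative", eta = 0.005, beta = 2,
                        seed = 19, max_iterations = 200L)
  # restrict to columns inside the estimated shell support: propagation can
  # only ever reach columns the shell contains
  bright_cols <- apply(gt$bright_mask, c(1, 2), any) & res$shell$support
  acq_cols <- matrix(FALSE, 80, 80)
  acq_cols[cbind(res$result$samples$x, res$result$samples$y)] <- TRUE
  expect_gt(mean(acq_cols[bright_cols]), 0.99)
})

test_that("maximum-intensity projection flags unacquired columns", {
  sh <- flat_shell(nx = 10, ny = 10, nz = 50, z_um = 12)
  s <- sample_set(c(2, 2, 5), c(3, 3, 5), c(25, 26, 24),
                  normalized = c(1.5, 0.5, -1))
  res <- structure(list(samples = s), class = "scan_result")
  mip <- max_intensity_projection(res, sh)
  expect_equal(mip[2, 3], 1.5)
  expect_equal(mip[5, 5], -1)
  expect_true(is.na(mip[1, 1]))
  expect_equal(sum(!is.na(mip)), 2L)
})
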