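# Windowed RANSAC surface estimation, fusion, interpolation and the shell.

test_that("window grids have the stated layout and always cover the field", {
  w <- make_windows(100, 100, width_fraction = 1, overlap_fraction = 0)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$x0, w$x1, w$y0, w$y1), c(1, 100, 1, 100))

  # closed form: 900 px, width 300, 50% overlap -> 5 starts stepping 150
  w <- make_windows(900, 900)
  expect_equal(nrow(w), 25L)
  expect_equal(sort(unique(w$x0)), c(1, 151, 301, 451, 601))
  expect_true(all(w$x1 - w$x0 + 1 == 300))

  # property: arbitrary layouts cover every pixel
  set.seed(2)
  for (i in 1:20) {
    nx <- sample(30:400, 1); ny <- sample(30:400, 1)
    wf <- runif(1, 0.15, 1); of <- runif(1, 0, 0.8)
    w <- make_windows(nx, ny, wf, of)
    covx <- rep(FALSE, nx); covy <- rep(FALSE, ny)
    for (k in seq_len(nrow(w))) {
      covx[w$x0[k]:w$x1[k]] <- TRUE; covy[w$y0[k]:w$y1[k]] <- TRUE
    }
    expect_true(all(covx) && all(covy))
  }
})

test_that("RANSAC recovers an exact polynomial from clean points", {
  set.seed(10)
  x <- runif(50, 0, 60); y <- runif(50, 0, 60)
  z <- 3 + 0.1 * x - 0.05 * y
  f <- ransac_fit_window(data.frame(x = x, y = y, z_um = z), seed = 1)
  expect_equal(f$n_inliers, 50L)
  expect_lt(max(abs(predict_local_fit(f, x, y) - z)), 1e-6)
  # quadratic terms recovered too
  z2 <- 1 + 0.02 * x + 0.01 * y - 0.002 * x^2 + 0.001 * x * y
  f2 <- ransac_fit_window(data.frame(x = x, y = y, z_um = z2), seed = 1)
  expect_lt(max(abs(predict_local_fit(f2, x, y) - z2)), 1e-6)
})

test_that("RANSAC refuses underdetermined input without raising", {
  expect_null(ransac_fit_window(data.frame(x = 1:5, y = 1:5, z_um = 1:5)))
})

test_that("RANSAC survives heavy contamination (sampled check)", {
  succ <- 0
  for (run in 1:20) {
    set.seed(run)
    x <- runif(100, 0, 100); y <- runif(100, 0, 100)
    z <- c(3 + 0.1 * x[1:30] - 0.05 * y[1:30], runif(70, 0, 25))
    f <- ransac_fit_window(data.frame(x = x, y = y, z_um = z),
                           inlier_tol = 1.5, seed = run * 7)
    if (is.null(f)) next
    set.seed(999); xs <- runif(200, 0, 100); ys <- runif(200, 0, 100)
    err <- max(abs(predict_local_fit(f, xs, ys) - (3 + 0.1 * xs - 0.05 * ys)))
    if (err < 0.75) succ <- succ + 1
  }
  expect_gte(succ, 18L)
})

test_that("fusion keeps consistent points and averages covering fits", {
  win <- make_windows(60, 60, 1, 0)
  set.seed(3)
  pts <- data.frame(x = runif(40, 1, 60), y = runif(40, 1, 60))
  pts$z_um <- 5 + 0.05 * pts$x
  f <- ransac_fit_window(pts, seed = 2)
  out <- fuse_and_filter(list(f), win, pts)
  expect_equal(nrow(out), 40L)
  expect_equal(out$z_um, predict_local_fit(f, out$x, out$y), tolerance = 1e-9)

  # a far-off point is rejected by the fused surface
  pts2 <- rbind(pts, data.frame(x = 30, y = 30, z_um = 20))
  f2 <- ransac_fit_window(pts2, seed = 2)
  out2 <- fuse_and_filter(list(f2), win, pts2)
  expect_false(any(abs(out2$z_um - 20) < 1))
  expect_equal(nrow(out2), 40L)

  # identical overlapping fits average to the common prediction
  win2 <- make_windows(60, 60, 0.6, 0.5)
  fits <- lapply(seq_len(nrow(win2)), function(i) f)
  out3 <- fuse_and_filter(fits, win2, pts)
  expect_equal(out3$z_um, predict_local_fit(f, out3$x, out3$y),
               tolerance = 1e-9)

  expect_error(fuse_and_filter(list(NULL, NULL), win2[1:2, ], pts),
               "no valid window fit")
})

test_that("biharmonic interpolation passes through its input points", {
  set.seed(4)
  pts <- data.frame(x = sample(5:55, 30), y = sample(5:55, 30))
  pts$z_um <- 10 + 0.1 * pts$x - 0.002 * pts$x * pts$y
  sm <- interpolate_surface(pts, 60, 60)
  expect_equal(sm$Z_hat[cbind(pts$x, pts$y)], pts$z_um, tolerance = 1e-6)

  # constant input -> constant interpolant on the support
  ptsc <- data.frame(x = c(5, 50, 8, 30, 44), y = c(5, 7, 50, 30, 41),
                     z_um = 10)
  smc <- interpolate_surface(ptsc, 60, 60)
  expect_lt(max(abs(smc$Z_hat - 10), na.rm = TRUE), 1e-6)

  expect_error(interpolate_surface(
    data.frame(x = 1:10, y = 2 * (1:10), z_um = 1:10), 30, 30), "collinear")
})

test_that("shell voxelization: layer structure, thickness and degeneracy", {
  sh <- flat_shell(nx = 20, ny = 20, nz = 50, z_um = 12)  # plane 25
  vox <- shell_voxels(sh)
  expect_setequal(unique(vox[, 3]), 22:28)                # 7 layers
  expect_equal(nrow(vox), 20 * 20 * 7)
  expect_equal(sh$n_voxels, nrow(vox))
  # membership predicate and layer index
  expect_true(all(in_shell(sh, vox)))
  expect_false(in_shell(sh, cbind(5, 5, 21)))
  expect_false(in_shell(sh, cbind(5, 5, 29)))
  expect_equal(layer_index(sh, cbind(5, 5, 25)), 0L)
  expect_equal(layer_index(sh, cbind(5, 5, 22)), -3L)
  # layer 0 is the nearest plane to the surface
  sh2 <- flat_shell(z_um = 12.2)  # 12.2/0.5 = 24.4 -> plane 25
  expect_equal(layer_index(sh2, cbind(1, 1, 25)), 0L)
  # documented degenerate case: epsilon = dz keeps one layer (the snapped plane)
  sh3 <- flat_shell(z_um = 12, epsilon = 0.5)
  expect_setequal(unique(shell_voxels(sh3)[, 3]), 25)
  # clipping at the stack boundary
  sh4 <- flat_shell(nz = 26, z_um = 12)
  expect_setequal(unique(shell_voxels(sh4)[, 3]), 22:26)
})

test_that("shell columns are empty where the surface is unsupported", {
  Z <- matrix(10, 15, 15); Z[1:5, ] <- NA
  sh <- build_shell(Z, epsilon = 3, dz = 0.5, nz = 40)
  vox <- shell_voxels(sh)
  expect_true(all(vox[, 1] >= 6))
  expect_false(any(in_shell(sh, cbind(2, 2, 21))))
})

test_that("end-to-end surface estimation recovers a curved phantom", {
  gt <- small_phantom()
  o <- oracle_from_stack(gt$volume)
  s <- acquire(o, draw_prescan(o$shape, 0.002, seed = 12))
  m <- fit_background(s, o$shape)
  br <- detect_bright(normalize_samples(s, m), threshold_from_pfa(0.01))
  sm <- estimate_surface(br, 120, 120, dz = 0.5, seed = 12)
  err <- sm$Z_hat - gt$Z_true
  expect_lt(sqrt(mean(err^2, na.rm = TRUE)), 1)
  expect_gt(mean(!is.na(err)), 0.5)
})
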