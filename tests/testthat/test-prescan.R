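# Pre-scan drawing, background normalization and significance-test detection.

test_that("pre-scan size, distinctness and determinism", {
  co <- draw_prescan(c(915, 915, 50), 0.001, seed = 4)
  expect_equal(nrow(co), 41861L)
  expect_equal(nrow(unique(co)), nrow(co))
  expect_identical(co, draw_prescan(c(915, 915, 50), 0.001, seed = 4))
  expect_false(identical(co, draw_prescan(c(915, 915, 50), 0.001, seed = 5)))
  # eta = 1 is the full scan
  expect_equal(nrow(draw_prescan(c(6, 5, 4), 1, seed = 1)), 120L)
  expect_error(draw_prescan(c(10, 10, 10), 1e-6, seed = 1), "zero")
})

test_that("threshold solves the erf false-alarm equation", {
  expect_equal(threshold_from_pfa(0.01), 2.3263, tolerance = 5e-5)
  expect_equal(round(threshold_from_pfa(0.01), 2), 2.33)
  # independent oracle: bisection on pfa = (1/2)(1 - erf(T/sqrt(2))) with
  # erf computed by numerical quadrature
  erf <- function(x) 2 / sqrt(pi) *
    stats::integrate(function(t) exp(-t^2), 0, x, rel.tol = 1e-12)$value
  pfa_eq <- function(T, pfa) 0.5 * (1 - erf(T / sqrt(2))) - pfa
  for (pfa in c(0.001, 0.01, 0.05, 0.2)) {
    T_ref <- stats::uniroot(pfa_eq, c(0, 8), pfa = pfa, tol = 1e-10)$root
    expect_equal(threshold_from_pfa(pfa), T_ref, tolerance = 1e-6)
  }
  expect_equal(threshold_from_pfa(0.001), 3.0902, tolerance = 1e-4)
  # T -> 0+ as pfa -> 0.5-
  expect_lt(threshold_from_pfa(0.4999), 1e-3)
  expect_error(threshold_from_pfa(0.5))
  expect_error(threshold_from_pfa(0))
  expect_error(threshold_from_pfa(-0.1))
})

test_that("threshold/pfa round-trip and monotonicity", {
  pfas <- c(1e-4, 1e-3, 0.01, 0.1, 0.4)
  Ts <- threshold_from_pfa(pfas)
  expect_true(all(diff(Ts) < 0))
  expect_equal(pfa_from_threshold(Ts), pfas, tolerance = 1e-9)
})

test_that("background fit recovers generating parameters (50 seeds)", {
  shape <- c(50L, 50L, 20L)
  err_a <- err_s <- numeric(50)
  grid <- as.matrix(expand.grid(x = seq(1, 50, 7), y = seq(1, 50, 7),
                                z = seq(1, 20, 4)))
  for (s in 1:50) {
    set.seed(s)
    co <- draw_prescan(shape, 0.2, seed = s)
    val <- 100 * (1 + 0.05 * rnorm(nrow(co)))
    m <- fit_background(sample_set(co[, 1], co[, 2], co[, 3], value = val),
                        shape)
    err_a[s] <- max(abs(predict_background(m, grid) - 100)) / 100
    err_s[s] <- abs(m$sigma_hat - 0.05) / 0.05
  }
  expect_lt(mean(err_a), 0.02)
  expect_gt(mean(err_a < 0.02), 0.85)
  expect_lt(stats::median(err_s), 0.10)
  expect_lt(mean(err_s > 0.10), 0.1)
})

test_that("a ramp background within the model class is reproduced exactly", {
  shape <- c(40L, 40L, 10L)
  co <- draw_prescan(shape, 0.5, seed = 3)
  a_true <- 50 + 2 * co[, 1] + 1 * co[, 2] + 3 * co[, 3]
  m <- fit_background(sample_set(co[, 1], co[, 2], co[, 3], value = a_true),
                      shape)
  expect_lt(max(abs(predict_background(m, co) - a_true) / a_true), 1e-8)
  expect_equal(m$sigma_hat, 1e-6)  # floor value for noise-free input
})

test_that("background fit is robust to a 10x bright tail", {
  shape <- c(50L, 50L, 20L)
  set.seed(21)
  co <- draw_prescan(shape, 0.3, seed = 21)
  val <- 100 * (1 + 0.05 * rnorm(nrow(co)))
  m0 <- fit_background(sample_set(co[, 1], co[, 2], co[, 3], value = val), shape)
  bad <- sample(nrow(co), round(0.1 * nrow(co)))
  val[bad] <- val[bad] * 10
  m1 <- fit_background(sample_set(co[, 1], co[, 2], co[, 3], value = val), shape)
  grid <- as.matrix(expand.grid(x = seq(1, 50, 7), y = seq(1, 50, 7),
                                z = seq(1, 20, 4)))
  rel <- abs(predict_background(m1, grid) - predict_background(m0, grid)) /
    predict_background(m0, grid)
  expect_lt(max(rel), 0.03)
})

test_that("fit preconditions are enforced", {
  expect_error(fit_background(sample_set(1:50, 1:50, 1, value = 1),
                              c(50, 50, 5)), "at least")
  co <- matrix(rep(c(3L, 4L, 2L), each = 200), ncol = 3)
  expect_error(fit_background(sample_set(co[, 1], co[, 2], co[, 3],
                                         value = rnorm(200, 100)),
                              c(10, 10, 5)), "degenerate")
})

test_that("normalization implements (s - a) / (a sigma) exactly", {
  gt <- background_phantom(nx = 40, ny = 40, nz = 25, seed = 5)
  o <- oracle_from_stack(gt$volume)
  s <- acquire(o, draw_prescan(o$shape, 0.05, seed = 5))
  m <- fit_background(s, o$shape)
  a <- predict_background(m, s)
  s1 <- s; s1$value <- a
  expect_equal(normalize_samples(s1, m)$normalized, rep(0, nrow(s)))
  s2 <- s; s2$value <- a * (1 + m$sigma_hat)
  expect_equal(normalize_samples(s2, m)$normalized, rep(1, nrow(s)))
})

test_that("normalized background is calibrated to ~N(0, 1)", {
  gt <- background_phantom(nx = 60, ny = 60, nz = 30, seed = 6)
  o <- oracle_from_stack(gt$volume)
  s <- acquire(o, draw_prescan(o$shape, 0.9, seed = 6))
  m <- fit_background(s, o$shape)
  r <- normalize_samples(s, m)$normalized
  n <- length(r)
  expect_lt(abs(mean(r)), 3 / sqrt(n))
  expect_lt(abs(stats::var(r) - 1), 3 * sqrt(2 / n))
})

test_that("normalization is invariant to global intensity rescaling", {
  gt <- small_phantom()
  o <- oracle_from_stack(gt$volume)
  s <- acquire(o, draw_prescan(o$shape, 0.002, seed = 9))
  m <- fit_background(s, o$shape)
  r1 <- normalize_samples(s, m)$normalized
  s2 <- s; s2$value <- 3.7 * s$value
  m2 <- fit_background(s2, o$shape)
  r2 <- normalize_samples(s2, m2)$normalized
  expect_equal(r1, r2, tolerance = 1e-6)
})

test_that("bright detection is a strict, monotone threshold rule", {
  s <- sample_set(1:5, 1, 1, normalized = c(-1, 0, 2.33, 2.34, 9))
  got <- detect_bright(s, 2.33)
  expect_equal(got$x, c(4L, 5L))       # strict inequality: 2.33 excluded
  expect_equal(nrow(detect_bright(s, 10)), 0L)
  for (T2 in c(0, 1, 3, 5)) {
    expect_true(all(detect_bright(s, T2 + 1)$x %in% detect_bright(s, T2)$x))
  }
  s$normalized <- NA_real_
  expect_error(detect_bright(s, 2), "normalized")
})

test_that("empirical false-alarm rate matches the nominal pfa", {
  set.seed(31)
  n <- 2e5
  s <- sample_set(rep(1L, n), 1L, 1L, normalized = rnorm(n))
  frac <- nrow(detect_bright(s, threshold_from_pfa(0.01))) / n
  expect_lt(abs(frac - 0.01), 3 * sqrt(0.01 * 0.99 / n))
})
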