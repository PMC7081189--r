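test_that("time-averaged velocity matches a per-pixel loop oracle", {
  set.seed(31)
  v <- array(rnorm(6 * 5 * 4), dim = c(6, 5, 4))
  ser <- pc_series(v, array(1, dim(v)), venc = 150, pixel_spacing = 2,
                   rr_interval = 800)
  got <- time_average_velocity(ser)
  for (i in 1:6) for (j in 1:5)
    expect_equal(got[i, j], mean(v[i, j, ]), tolerance = 1e-14)
  # two frames +v / -v cancel; constant-in-time equals any frame
  v2 <- array(c(v[, , 1], -v[, , 1]), dim = c(6, 5, 2))
  ser2 <- pc_series(v2, array(1, dim(v2)), 150, 2, 800)
  expect_true(all(abs(time_average_velocity(ser2)) < 1e-14))
})

test_that("constant and planar fields are fitted exactly", {
  mask <- matrix(TRUE, 5, 5)
  fit <- fit_background(matrix(2, 5, 5), mask, order = 1)
  expect_equal(unname(coef(fit)), c(2, 0, 0), tolerance = 1e-12)

  co <- pcflow:::normalized_coords(5, 5)
  plane <- 1 + 0.5 * co$x - 0.25 * co$y
  f1 <- fit_background(plane, mask, order = 1)
  expect_equal(unname(coef(f1)), c(1, 0.5, -0.25), tolerance = 1e-12)
  expect_lt(f1$rms_residual, 1e-12)
  f2 <- fit_background(plane, mask, order = 2)
  expect_equal(unname(coef(f2)), c(1, 0.5, -0.25, 0, 0, 0), tolerance = 1e-10)
})

test_that("least-squares solution equals the brute-force normal equations", {
  set.seed(13)
  for (rep in 1:25) {
    nr <- sample(5:9, 1); nc <- sample(5:9, 1)
    order <- sample(1:2, 1)
    vbar <- matrix(rnorm(nr * nc), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.7, nr, nc)
    if (sum(mask) < 8) next
    fit <- fit_background(vbar, mask, order = order)
    expect_equal(unname(coef(fit)), unname(ols_oracle(vbar, mask, order)),
                 tolerance = 1e-8)
  }
})

test_that("order-2 residual never exceeds order-1 on the same mask", {
  set.seed(99)
  for (rep in 1:10) {
    vbar <- matrix(rnorm(100), 10, 10)
    mask <- matrix(runif(100) < 0.6, 10, 10)
    if (sum(mask) < 10) next
    expect_lte(fit_background(vbar, mask, 2)$rms_residual,
               fit_background(vbar, mask, 1)$rms_residual + 1e-12)
  }
})

test_that("adding a constant shifts only the intercept", {
  set.seed(7)
  vbar <- matrix(rnorm(64), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  for (order in 1:2) {
    base <- coef(fit_background(vbar, mask, order))
    shifted <- coef(fit_background(vbar + 3.7, mask, order))
    expect_equal(shifted[["a00"]], base[["a00"]] + 3.7, tolerance = 1e-10)
    expect_equal(shifted[-1], base[-1], tolerance = 1e-10)
  }
})

test_that("rank-deficient designs and thin masks are rejected", {
  vbar <- matrix(rnorm(36), 6, 6)
  mask <- matrix(FALSE, 6, 6)
  mask[3, ] <- TRUE                       # one row: y constant -> collinear
  expect_error(fit_background(vbar, mask, order = 1), "rank-deficient")
  mask2 <- matrix(FALSE, 6, 6); mask2[1, 1:2] <- TRUE
  expect_error(fit_background(vbar, mask2, order = 1), "at least 3")
})

test_that("correction subtracts the surface, is idempotent, leaves magnitude", {
  ph <- make_phantom(tiny_params(background_order = 2,
                                 background_coeffs = c(1, 0.5, -0.3, 0.2, -0.1, 0.15),
                                 seed = 8))
  msk <- phantom_mask(ph, sd_threshold = 3)
  fit <- fit_background(ph$series, msk, order = 2)
  corr <- apply_correction(ph$series, fit)
  expect_identical(corr$magnitude, ph$series$magnitude)
  expect_equal(corr$meta$background_model$order, 2L)

  # zero model is a no-op
  zfit <- fit
  zfit$coefficients[] <- 0
  expect_equal(apply_correction(ph$series, zfit)$velocity, ph$series$velocity)

  # refit on the corrected series: coefficients collapse to ~0
  refit <- fit_background(corr, msk, order = 2)
  expect_true(all(abs(coef(refit)) < 1e-8))

  # grid mismatch rejected
  other <- make_phantom(phantom_params(grid_rows = 48, grid_cols = 48,
                                       pixel_spacing = 4, n_frames = 10))
  expect_error(apply_correction(other$series, fit), "grid")
})

test_that("coefficient error shrinks as the static fraction grows", {
  # parameter-recovery trend: more static tissue, better coefficients
  truth <- c(0.8, 0.4, -0.3)
  errs <- sapply(c(0.1, 0.3, 0.6), function(frac) {
    mean(sapply(1:20, function(s) {
      ph <- make_phantom(tiny_params(background_order = 1,
                                     background_coeffs = truth,
                                     snr_tissue = 20, seed = 100 + s))
      full <- phantom_mask(ph, sd_threshold = 4)
      idx <- which(full$mask)
      keep <- with_seed_keep(s, sample(idx, round(frac * length(idx))))
      sub <- matrix(FALSE, 32, 32); sub[keep] <- TRUE
      mean(abs(coef(fit_background(ph$series, sub, 1)) - truth))
    }))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("phase-to-velocity scaling follows the VENC convention", {
  expect_equal(velocity_from_phase(0, 150), 0)
  expect_equal(velocity_from_phase(pi, 150), 150)
  expect_equal(velocity_from_phase(-pi / 2, 200), -100)
  m <- matrix(c(0, pi / 4, -pi, pi), 2)
  expect_equal(velocity_from_phase(m, 100), m * 100 / pi)
  expect_error(velocity_from_phase(3.2, 100), "alias")
})
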