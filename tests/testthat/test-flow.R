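test_that("constant flow integrates by the rectangle rule", {
  # 10 cm/s over 5 cm^2 for a 1 s cycle -> 50 ml net, all forward
  v <- array(10, dim = c(10, 10, 8))
  ser <- pc_series(v, array(1, dim(v)), venc = 150, pixel_spacing = 10,
                   rr_interval = 1000)  # 1 cm^2 pixels
  roi <- matrix(FALSE, 10, 10); roi[3:3, 3:7] <- TRUE  # 5 pixels = 5 cm^2
  fr <- flow_curve(ser, roi)
  expect_equal(fr$net_volume, 50)
  expect_equal(fr$forward_volume, 50)
  expect_equal(fr$backward_volume, 0)
  expect_equal(unique(fr$flow), 50)  # ml/s
  # zero velocity -> zero volumes
  ser0 <- pc_series(array(0, dim(v)), array(1, dim(v)), 150, 10, 1000)
  fr0 <- flow_curve(ser0, roi)
  expect_equal(fr0$net_volume + fr0$forward_volume + fr0$backward_volume, 0)
})

test_that("net = forward - backward and constant offsets obey the bias law", {
  ph <- make_phantom(tiny_params(seed = 14))
  roi <- ph$truth$vessel_masks$aorta
  fr <- flow_curve(ph$series, roi)
  expect_equal(fr$net_volume, fr$forward_volume - fr$backward_volume,
               tolerance = 1e-12)

  shifted <- ph$series
  cshift <- -4.2
  shifted$velocity <- shifted$velocity + cshift
  fr2 <- flow_curve(shifted, roi)
  expected_shift <- cshift * fr$roi_area * ph$series$rr_interval / 1000
  expect_equal(fr2$net_volume - fr$net_volume, expected_shift,
               tolerance = 1e-9)
})

test_that("ROI forms agree and out-of-grid ROIs are rejected", {
  ph <- make_phantom(tiny_params(seed = 6))
  roi_logical <- ph$truth$vessel_masks$pa
  roi_pixels <- which(roi_logical, arr.ind = TRUE)
  expect_equal(flow_curve(ph$series, roi_logical)$net_volume,
               flow_curve(ph$series, roi_pixels)$net_volume)
  expect_error(flow_curve(ph$series, cbind(40, 2)), "outside")
  expect_error(flow_curve(ph$series, matrix(FALSE, 32, 32)), "no pixels")
})

test_that("Qp/Qs classification partitions ratios with inclusive bounds", {
  expect_equal(qpqs(90, 90)$ratio, 1)
  expect_equal(qpqs(90, 90)$classification, "normal")
  expect_equal(classify_qpqs(1.25), "left-to-right")
  expect_equal(classify_qpqs(0.85), "right-to-left")
  expect_equal(classify_qpqs(0.9), "normal")
  expect_equal(classify_qpqs(1.2), "normal")
  # partition: every finite positive ratio gets exactly one label
  r <- seq(0.05, 3, by = 0.05)
  lab <- classify_qpqs(r)
  expect_true(all(lab %in% c("normal", "left-to-right", "right-to-left")))
  expect_error(qpqs(50, 0), "positive")
  expect_error(qpqs(50, -10), "positive")
})

test_that("Qp/Qs is invariant to common velocity scaling", {
  ph <- make_phantom(tiny_params(seed = 3))
  ao <- flow_curve(ph$series, ph$truth$vessel_masks$aorta)
  pa <- flow_curve(ph$series, ph$truth$vessel_masks$pa)
  base <- qpqs(pa, ao)$ratio
  scaled <- ph$series
  scaled$velocity <- scaled$velocity * 2.5
  ao2 <- flow_curve(scaled, ph$truth$vessel_masks$aorta)
  pa2 <- flow_curve(scaled, ph$truth$vessel_masks$pa)
  expect_equal(qpqs(pa2, ao2)$ratio, base, tolerance = 1e-12)
})

test_that("R-R eligibility uses the strict 10% coefficient-of-variation rule", {
  expect_true(rr_eligibility(rep(1000, 20)))
  # SD exactly 10% of mean: still eligible ("exceeding" is strict)
  expect_false(rr_eligibility(c(900, 1100)))  # sd/mean ~14%
  # five-beat series with sd/mean exactly cv (sd computes exactly in floats)
  mk_cv <- function(cv) 1000 + 1000 * cv * c(-1, -1, 0, 1, 1)
  expect_equal(sd(mk_cv(0.10)) / mean(mk_cv(0.10)), 0.10)
  expect_true(rr_eligibility(mk_cv(0.10)))
  expect_false(rr_eligibility(mk_cv(0.11)))
  # every acquisition must pass
  expect_false(rr_eligibility(list(rep(1000, 5), mk_cv(0.2))))
  expect_error(rr_eligibility(list()), "empty")
  expect_error(rr_eligibility(1000), "2 beats")
})

test_that("DuBois BSA matches direct evaluation and its scaling law", {
  expect_equal(bsa_dubois(79, 174), 1.937564, tolerance = 1e-6)
  expect_equal(bsa_dubois(70, 170), 1.809708, tolerance = 1e-6)
  expect_equal(round(bsa_dubois(79, 174), 1), 1.9)  # typical-subject value
  expect_equal(bsa_dubois(2 * 70, 2 * 170) / bsa_dubois(70, 170), 2^1.15,
               tolerance = 1e-12)
  expect_error(bsa_dubois(-1, 170), "positive")
})
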