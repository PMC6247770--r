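# Autoradiography calibration, Kety CBF, projective alignment,
# positive-pixel counting and ROI statistics.

# saturating-exponential film response used as the synthetic forward model
film_reading <- function(activity, rmax = 220, a = 0.08, bg = 12) {
  bg + rmax * (1 - exp(-a * activity))
}

test_that("calibration is exact at the standards and monotone between them", {
  act <- seq(0, 35, by = 5)
  std <- calibration_standards(act, film_reading(act))
  cal <- fit_calibration(std)
  expect_equal(as.numeric(cal(std$reading)), act)
  mid <- cal((std$reading[3] + std$reading[4]) / 2)
  expect_gt(mid, act[3]); expect_lt(mid, act[4])
  # out-of-range readings are clamped and flagged
  out <- cal(c(0, 1e4))
  expect_identical(attr(out, "extrapolated"), c(TRUE, TRUE))
  expect_error(calibration_standards(c(0, 5), c(1, 2)), "at least 3")
  expect_error(calibration_standards(c(0, 5, 3), c(1, 2, 3)), "increasing")
  expect_error(calibration_standards(c(0, 5, 10), c(1, 4, 2)), "monotone")
})

test_that("calibration inverts a dense log-response film model to < 1%", {
  act <- seq(0, 35, length.out = 20)
  cal <- fit_calibration(calibration_standards(act, film_reading(act)))
  probe <- seq(0.2, 34.8, length.out = 200)
  rec <- cal(film_reading(probe))
  expect_lt(max(abs(rec - probe)), 0.01 * 35)
})

test_that("activity quantification subtracts background and clamps", {
  act <- seq(0, 35, by = 5)
  cal <- fit_calibration(calibration_standards(act, film_reading(act) -
                                                 film_reading(0)))
  truth <- matrix(c(0, 3, 11, 27), 2, 2)
  film <- film_reading(truth)
  out <- quantify_activity(film, cal, background = film_reading(0))
  expect_equal(as.numeric(out), as.numeric(truth), tolerance = 0.01 * 35)
  expect_equal(out[1, 1], 0)                     # background pixel
  neg <- quantify_activity(matrix(film_reading(0) - 5, 1, 1), cal,
                           background = film_reading(0))
  expect_identical(as.numeric(neg), 0)
  expect_true(attr(neg, "flagged")[1, 1])
  expect_error(quantify_activity(film, cal, background = -1), "non-negative")
})

test_that("Kety model round-trips and is monotone", {
  ca <- 3.2
  for (f in seq(20, 300, by = 40)) {
    ci <- kety_forward(f, ca_T = ca)
    expect_equal(kety_cbf(ci, ca_T = ca), f, tolerance = 1e-3)
  }
  expect_identical(kety_cbf(0, ca_T = ca), 0)
  cis <- kety_forward(seq(10, 400, by = 30), ca_T = ca)
  expect_true(all(diff(kety_cbf(cis, ca_T = ca)) > 0))
  expect_error(kety_cbf(ca * 2, ca_T = ca), "unphysical")
  # custom arterial input function agrees with the built-in ramp
  ramp <- function(t) ca / 120 * t
  expect_equal(kety_cbf(kety_forward(100, ca_T = ca), ca_T = ca,
                        input = ramp), 100, tolerance = 1e-3)
})

test_that("projective alignment recovers a known homography", {
  H <- matrix(c(1.02, 0.03, 0.1,
                -0.02, 0.98, 0.2,
                1e-4, -5e-5, 1), 3, 3, byrow = TRUE)
  film <- outer(1:128, 1:128, function(x, y) sin(x / 9) + cos(y / 11))
  src <- rbind(c(10, 10), c(10, 100), c(100, 10), c(100, 100), c(60, 50))
  dst <- t(apply(src, 1, function(p) { q <- H %*% c(p, 1); q[1:2] / q[3] }))
  ad <- align_downsample(film, src, dst, target = c(64, 64))
  back <- cbind(dst, 1) %*% t(ad$H)
  back <- back[, 1:2] / back[, 3]
  expect_lt(max(abs(back - src)), 0.1)           # < 0.1 px at controls
  # identity control points reduce to pure block-mean downsampling
  id <- align_downsample(film, src, src, target = c(64, 64))
  manual <- 0.25 * (film[seq(1, 127, 2), seq(1, 127, 2)] +
                      film[seq(2, 128, 2), seq(1, 127, 2)] +
                      film[seq(1, 127, 2), seq(2, 128, 2)] +
                      film[seq(2, 128, 2), seq(2, 128, 2)])
  expect_equal(id$aligned, manual, tolerance = 1e-10)
  # constant image stays constant (mean preserved)
  cim <- align_downsample(array(5, c(128, 128)), src, dst,
                          target = c(64, 64))
  vals <- cim$aligned[!is.na(cim$aligned)]
  expect_equal(range(vals), c(5, 5), tolerance = 1e-9)
  expect_error(align_downsample(film, src[c(1, 1, 1, 1), ],
                                dst[c(1, 1, 1, 1), ]), "degenerate")
})

test_that("positive-pixel fraction is exact, disjoint and order-free", {
  img <- array(255, c(100, 100))
  expect_equal(as.numeric(positive_pixel_fraction(img)), 0)
  # constructed fixture: exactly 7.7% positive (mirrors tumour-scale values)
  img[seq_len(500)] <- 190          # moderate [185, 202]
  img[501:770] <- 5                 # strong < 10
  expect_equal(as.numeric(positive_pixel_fraction(img)), 7.7)
  r <- positive_pixel_fraction(img)
  expect_equal(attr(r, "moderate") + attr(r, "strong"), 7.7)
  # permutation invariance
  set.seed(2)
  img2 <- array(sample(img), dim(img))
  expect_equal(as.numeric(positive_pixel_fraction(img2)), 7.7)
  expect_error(positive_pixel_fraction(img, region = array(FALSE, dim(img))),
               "empty")
})

test_that("ROI statistics match hand computation and detect variance", {
  a <- array(rep(c(1, 2, 3, 4, 5), 2), c(5, 2))
  roi <- array(c(rep(TRUE, 5), rep(FALSE, 5)), c(5, 2))
  # identical inputs: t = 0, p = 1
  st0 <- roi_stats(a, a, list(r = roi))
  expect_equal(st0$t, 0); expect_equal(st0$p, 1)
  # hand-computed paired t on a 5-value fixture: d = (1,0,1,-1,1), t = 1
  b <- a; b[1:5, 1] <- c(2, 2, 4, 3, 6)
  st <- roi_stats(a, b, list(r = roi), paired = TRUE)
  expect_equal(abs(st$t), 1, tolerance = 1e-12)
  expect_equal(st$mean_b - st$mean_a, 0.4)
  # variance ratio of 4 is recovered on large samples
  set.seed(8)
  n <- 4000
  x <- array(stats::rnorm(n, 0, 2), c(n, 1))
  y <- array(stats::rnorm(n, 0, 1), c(n, 1))
  stv <- roi_stats(x, y, list(all = array(TRUE, c(n, 1))), paired = FALSE)
  expect_equal(stv$f, 4, tolerance = 0.35)
  expect_lt(stv$f_p, 1e-10)
  # Bonferroni adjustment across ROIs
  rois <- list(r1 = roi, r2 = !roi)
  st2 <- roi_stats(a, b, rois, paired = TRUE)
  expect_equal(st2$p_bonferroni, pmin(st2$p * 2, 1))
  expect_error(roi_stats(a, array(2, c(5, 2)), list(r = roi)),
               "zero variance")
})
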