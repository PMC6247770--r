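# Multiphase analysis chain: Fermi response and fits, circular smoothing,
# supervoxel clustering, cluster re-fit, amplitude mapping, SNR and the
# composed pipeline.

test_that("modified Fermi response has the printed semantics", {
  expect_equal(fermi_response(70), 0.5)                  # half max at alpha
  expect_equal(fermi_response(60), fermi_response(-60))  # even
  expect_equal(fermi_response(0), 1 / (1 + exp(-70 / 19)))
  d <- fermi_response(seq(0, 180, by = 5))
  expect_true(all(diff(d) <= 0))                         # non-increasing
  expect_error(fermi_response(0, beta_f = 0), "positive")
})

test_that("voxel Fermi fit recovers generative parameters exactly", {
  for (th0 in c(-120, 0, 35, 90, 180)) {
    s <- fermi_signal(A = 10, theta0 = th0, C = 100)
    ft <- fit_fermi_voxel(s)
    expect_equal(ft$amplitude, 10, tolerance = 1e-6)
    expect_equal(ft$offset, 100, tolerance = 1e-6)
    expect_lt(abs(wrap_deg(ft$theta0 - th0)), 1e-6)
  }
  # wrap invariance: relabelling the phase axis by 360 changes nothing
  s <- fermi_signal(8, 45, 50)
  f1 <- fit_fermi_voxel(s, seq(0, 315, by = 45))
  f2 <- fit_fermi_voxel(s, seq(0, 315, by = 45) + 360)
  expect_equal(f1$theta0, f2$theta0, tolerance = 1e-9)
  # constant signal is flagged undefined
  fc <- fit_fermi_voxel(rep(3, 8))
  expect_true(fc$undefined)
  expect_identical(fc$amplitude, 0)
  expect_true(is.na(fc$theta0))
})

test_that("voxel Fermi fit keeps the median phase error under 10 degrees", {
  set.seed(7)
  A <- 10
  errs <- vapply(seq_len(500), function(i) {
    th0 <- stats::runif(1, -180, 180)
    s <- fermi_signal(A, th0, 100) + stats::rnorm(8, 0, A / 15)
    abs(wrap_deg(fit_fermi_voxel(s)$theta0 - th0))
  }, numeric(1))
  expect_lt(stats::median(errs), 10)
})

test_that("phase smoothing is circular and mask-aware", {
  mask <- array(TRUE, c(8, 8, 1))
  ph <- array(20, c(8, 8, 1))
  expect_equal(smooth_phase_map(ph, 0, mask)[, , 1], ph[, , 1])   # identity
  expect_equal(smooth_phase_map(ph, 3, mask)[, , 1], ph[, , 1],
               tolerance = 1e-10)                                 # constant
  # step map across the wrap point: result equals the brute-force circular
  # mean of the Gaussian-weighted neighbourhood
  ph[] <- rep(c(rep(170, 4), rep(-170, 4)), times = 8)
  sm <- smooth_phase_map(ph, 2, mask)
  fwhm <- 2; sigma <- fwhm / (2 * sqrt(2 * log(2)))
  rad <- ceiling(3 * sigma)            # kernel support is truncated at 3 sigma
  at <- c(4, 5, 1)
  num_s <- 0; num_c <- 0
  for (i in 1:8) for (j in 1:8) {
    if (abs(i - at[1]) > rad || abs(j - at[2]) > rad) next
    w <- exp(-((i - at[1])^2 + (j - at[2])^2) / (2 * sigma^2))
    num_s <- num_s + w * sin(ph[i, j, 1] * pi / 180)
    num_c <- num_c + w * cos(ph[i, j, 1] * pi / 180)
  }
  expect_equal(sm[at[1], at[2], 1], atan2(num_s, num_c) * 180 / pi,
               tolerance = 1e-9)
  # step across the wrap smooths through 180, never toward 0
  expect_true(all(abs(sm[phantom_ok <- !is.na(sm)]) > 90))
  expect_error(smooth_phase_map(ph, -1, mask), "non-negative")
})

test_that("supervoxels partition the mask into connected clusters", {
  set.seed(3)
  mask <- array(TRUE, c(12, 12, 2))
  ph <- array(stats::runif(288, -30, 30), c(12, 12, 2))
  seg <- supervoxel_cluster(ph, mask, k = 6)
  lab <- seg$labels[mask]
  expect_false(anyNA(lab))                       # every masked voxel labelled
  expect_true(all(is.na(seg$labels[!mask])))
  expect_identical(sum(seg$sizes), sum(mask))    # partition
  # each cluster is one connected component
  for (l in unique(lab)) {
    one <- seg$labels == l & mask
    comp <- mpcasl:::.components(array(1L, dim(one)), one)
    expect_identical(length(unique(comp)), 1L)
  }
  # k = 1 returns the mask itself
  seg1 <- supervoxel_cluster(ph, mask, k = 1)
  expect_identical(unique(seg1$labels[mask]), 1L)
  expect_error(supervoxel_cluster(ph, mask, k = 1e5), "exceeds")
})

test_that("two separated constant-phase blobs split exactly at k = 2", {
  mask <- array(FALSE, c(20, 10, 1))
  mask[2:6, 3:8, 1] <- TRUE      # blob A
  mask[14:18, 3:8, 1] <- TRUE    # blob B
  ph <- array(NA_real_, dim(mask))
  ph[2:6, , 1] <- 10; ph[14:18, , 1] <- -120
  seg <- supervoxel_cluster(ph, mask, k = 2)
  la <- unique(as.integer(seg$labels[2:6, 3:8, 1]))
  lb <- unique(as.integer(seg$labels[14:18, 3:8, 1]))
  expect_length(la, 1); expect_length(lb, 1)
  expect_false(la == lb)
})

test_that("cluster re-fit pools signal and reduces phase error", {
  # uniform phantom: cluster-mean fit equals the single-voxel fit
  s <- fermi_signal(5, 60, 40)
  sig <- array(rep(s, each = 64), c(8, 8, 1, 8))
  raw <- multiphase_series(sig)
  mask <- array(TRUE, c(8, 8, 1))
  seg <- supervoxel_cluster(array(0, dim(mask)), mask, k = 2)
  rf <- refit_supervoxels(raw, seg)
  expect_equal(unique(as.numeric(rf$phase)), fit_fermi_voxel(s)$theta0,
               tolerance = 1e-9)
  # definitional: cluster fit is the fit of the arithmetic mean signal
  expect_equal(rf$clusters$theta0[1],
               fit_fermi_voxel(colMeans(matrix(sig, ncol = 8)[
                 which(seg$labels == 1), ]))$theta0)
  # variance reduction under noise, 20 seeded realisations
  wins <- 0
  for (rep in 1:20) {
    set.seed(rep)
    noisy <- sig + array(stats::rnorm(length(sig), 0, 5 / 10), dim(sig))
    nraw <- multiphase_series(noisy)
    ff <- fit_fermi_map(nraw, mask)
    seg2 <- supervoxel_cluster(smooth_phase_map(ff$theta0, 2, mask), mask,
                               k = 2)
    rf2 <- refit_supervoxels(nraw, seg2)
    rmse_before <- sqrt(mean(wrap_deg(ff$theta0[mask] - 60)^2))
    rmse_after <- sqrt(mean(wrap_deg(rf2$phase[mask] - 60)^2))
    wins <- wins + (rmse_after < rmse_before)
  }
  expect_gte(wins, 19)
})

test_that("fixed-phase amplitude map reproduces the generative amplitude", {
  set.seed(11)
  A <- array(stats::runif(32, 1, 6), c(4, 4, 2))
  A[1, 1, 1] <- 0
  th <- array(stats::runif(32, -170, 170), c(4, 4, 2))
  sig <- array(0, c(4, 4, 2, 8))
  phases <- seq(0, 315, by = 45)
  for (j in 1:8)
    sig[, , , j] <- 30 - A * fermi_response(phases[j] - th)
  dm <- perfusion_weighted_map(multiphase_series(sig), th)
  expect_equal(as.numeric(dm), as.numeric(A), tolerance = 1e-6)
  expect_identical(dm[1, 1, 1], 0)              # zero-amplitude voxel
  expect_true(all(dm >= 0))                     # constrained non-negative
  # undefined phase propagates NA
  th[2, 2, 2] <- NA
  dm2 <- perfusion_weighted_map(multiphase_series(sig), th)
  expect_true(is.na(dm2[2, 2, 2]))
})

test_that("series SNR behaves like mean(signal)/sd(noise)", {
  set.seed(5)
  sig <- array(0, c(10, 10, 1, 8))
  roi_s <- array(FALSE, c(10, 10, 1)); roi_s[1:5, , 1] <- TRUE
  roi_n <- array(FALSE, c(10, 10, 1)); roi_n[6:10, , 1] <- TRUE
  sig[1:5, , , ] <- 4
  noise <- stats::rnorm(sum(roi_n) * 8)
  sig[rep(roi_n, 8)] <- noise
  s1 <- series_snr(sig, roi_s, roi_n)
  sig2 <- sig
  sig2[rep(roi_n, 8)] <- 2 * noise
  expect_equal(series_snr(sig2, roi_s, roi_n), s1 / 2)   # sd doubled
  expect_error(series_snr(sig, roi_s, roi_s), "disjoint")
  expect_error(series_snr(array(1, c(4, 4, 1, 2)),
                          array(c(TRUE, FALSE), c(4, 4, 1)),
                          array(c(FALSE, TRUE), c(4, 4, 1))), "variance")
  # a pure-noise signal ROI gives SNR near zero
  sig3 <- array(stats::rnorm(800), c(10, 10, 1, 8))
  expect_lt(abs(series_snr(sig3, roi_s, roi_n)), 0.2)
})

test_that("the composed pipeline is linear, deterministic and validated", {
  phan <- small_phantom(seed = 21, shape = c(24, 24, 2))
  sim <- simulate_multiphase(phan, acquisition_config(target_snr = 30,
                                                      seed = 21))
  conf <- pipeline_config(delta_t = phan$bat, k_per_slice = 20)
  res1 <- run_pipeline(sim$series, sim$m0, sim$mask, conf)
  # determinism: identical config -> bit-identical CBF map
  res2 <- run_pipeline(sim$series, sim$m0, sim$mask, conf)
  expect_identical(res1$cbf, res2$cbf)
  # end-to-end linearity: scaling raw and M0 together leaves CBF unchanged
  scaled <- multiphase_series(sim$series$signal * 3.7,
                              sim$series$phase_angles)
  res3 <- run_pipeline(scaled, sim$m0 * 3.7, sim$mask, conf)
  expect_equal(res3$cbf, res1$cbf, tolerance = 1e-6)
  expect_error(run_pipeline(sim$series, sim$m0,
                            array(FALSE, dim(sim$mask)), conf), "empty mask")
})
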