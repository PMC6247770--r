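# Digital phantom generator: geometry, ground truth, tumour lesions and the
# forward multiphase / multi-delay simulators.

test_that("the phantom is deterministic and partitions the brain", {
  p1 <- make_mouse_phantom(seed = 4, shape = c(32, 32, 4))
  p2 <- make_mouse_phantom(seed = 4, shape = c(32, 32, 4))
  expect_identical(p1, p2)
  p3 <- make_mouse_phantom(seed = 5, shape = c(32, 32, 4))
  expect_false(identical(p1$bat, p3$bat))
  # region volumes sum to the brain mask volume
  rm <- region_means(p1$f, p1)
  expect_identical(sum(rm$n), sum(p1$mask))
  # default regional perfusion means
  expect_equal(rm$mean[rm$region == "cortex"], 103)
  expect_equal(rm$mean[rm$region == "striatum"], 90)
  expect_equal(rm$mean[rm$region == "corpus_callosum"], 77)
  # arrival field: most voxels arrive within 0.4 s, phase field bandlimited
  expect_gte(arrival_fraction(p1$bat, p1$mask), 0.95)
  expect_lte(max(abs(p1$phase_offset)), 60 + 1e-9)
  dph <- abs(diff(p1$phase_offset[, 16, 1]))
  expect_lt(max(dph), 45)                     # no voxel-to-voxel jumps
  expect_error(make_mouse_phantom(shape = c(8, 8, 1)), "too small")
})

test_that("tumour lesions override the striatum locally", {
  phan <- make_mouse_phantom(seed = 6)
  pt <- add_tumour(phan)
  regs <- PHANTOM_REGIONS
  expect_gt(sum(pt$labels == regs["tumour_core"]), 0)
  expect_gt(sum(pt$labels == regs["tumour_rim"]), 0)
  # contralateral striatum untouched
  right <- pt$labels == regs["striatum"] &
    array(rep(seq_len(64) > 32, times = 64 * 8), pt$shape)
  expect_equal(pt$f[right], phan$f[right])
  # rim-only lesion
  pr <- add_tumour(phan, radius_core = 0, radius_rim = 1.2)
  expect_identical(sum(pr$labels == regs["tumour_core"]), 0L)
  expect_gt(sum(pr$labels == regs["tumour_rim"]), 0)
  # ventricle overlap rejected
  expect_error(add_tumour(phan, centre = c(32, 32, 4), radius_rim = 2),
               "ventricle")
})

test_that("tumour variance excess is detected by the F-test", {
  # tumour voxels (core + rim) carry inflated voxelwise variance relative to
  # the contralateral striatum, sampled by left-right mirroring
  detected <- 0
  for (s in 1:100) {
    phan <- add_tumour(make_mouse_phantom(seed = s, shape = c(48, 48, 4),
                                          f_jitter_sd = 5))
    tum <- phan$labels == PHANTOM_REGIONS["tumour_core"] |
      phan$labels == PHANTOM_REGIONS["tumour_rim"]
    mirror <- phan$f[dim(phan$f)[1]:1, , ]    # contralateral sampling
    mirror_lab <- phan$labels[dim(phan$f)[1]:1, , ]
    roi <- tum & mirror_lab == PHANTOM_REGIONS["striatum"]
    st <- roi_stats(phan$f, mirror, list(tumour = roi), paired = FALSE)
    detected <- detected + (st$f > 1 && st$f_p < 0.05)
  }
  expect_gte(detected, 90)
})

test_that("forward multiphase simulation is calibrated and seeded", {
  phan <- small_phantom(seed = 9)
  # noiseless: pipeline recovery is essentially exact
  sim0 <- simulate_multiphase(phan, acquisition_config(target_snr = Inf))
  res <- run_pipeline(sim0$series, sim0$m0, sim0$mask,
                      pipeline_config(delta_t = phan$bat, k_per_slice = 30))
  perf <- phan$mask & phan$f > 0
  relerr <- abs(res$cbf[perf] - phan$f[perf]) / phan$f[perf]
  expect_lt(stats::quantile(relerr, 0.99), 0.02)
  rm <- region_means(res$cbf, phan)
  expect_equal(rm$mean[1:3], c(103, 90, 77), tolerance = 0.01)
  # triggered and untriggered differ only by the fluctuation term
  st <- simulate_multiphase(phan, acquisition_config(target_snr = 15.1,
                                                     seed = 9))
  su_same <- simulate_multiphase(phan,
    acquisition_config(target_snr = 15.1, untriggered_snr = 15.1,
                       triggered = FALSE, seed = 9))
  expect_equal(st$series$signal, su_same$series$signal)
  # measured SNR close to target over seeds
  snrs_t <- snrs_u <- numeric(6)
  for (s in 1:6) {
    a <- acquisition_config(target_snr = 15.1, seed = s)
    snrs_t[s] <- series_snr(diff_series(simulate_multiphase(phan, a)),
                            phan$mask, !phan$mask)
    au <- acquisition_config(target_snr = 15.1, triggered = FALSE, seed = s)
    snrs_u[s] <- series_snr(diff_series(simulate_multiphase(phan, au)),
                            phan$mask, !phan$mask)
  }
  expect_lt(abs(mean(snrs_t) - 15.1) / 15.1, 0.15)
  expect_lt(abs(mean(snrs_u) - 6.5) / 6.5, 0.15)
  # rician magnitude option stays finite and close to gaussian at high SNR
  sr <- simulate_multiphase(phan, acquisition_config(target_snr = 15.1,
                                                     noise = "rician",
                                                     seed = 9))
  expect_true(all(is.finite(sr$series$signal)))
})

test_that("forward multi-delay simulation matches its own ground truth", {
  phan <- small_phantom(seed = 10)
  p <- kinetic_params()
  # all delays before arrival: identically zero noiseless signal
  early <- pld_schedule(c(0.001, 0.002, 0.003, 0.004))
  acq_fast <- acquisition_config(target_snr = Inf, tau = 0.01)
  mp0 <- simulate_multi_pld(phan, early, acq_fast)
  expect_identical(max(abs(mp0$series)), 0)
  # noiseless arrival recovery to 1e-3 s
  sch <- pld_schedule()
  mp <- simulate_multi_pld(phan, sch, acquisition_config(target_snr = Inf))
  m0b <- calibrate_m0(phan$m0, phan$mask, p$lam)
  fit <- fit_bat_map(mp$series, phan$mask, sch, p, m0_blood = m0b)
  perf <- phan$mask & phan$f > 0
  expect_lt(max(abs(fit$delta_t - phan$bat)[perf]), 1e-3)
  expect_lt(max(abs(fit$f - phan$f)[perf]), 0.1)
})

test_that("the forward model is the kinetic module's (single source)", {
  # the generator's amplitude equals buxton_delta_m evaluated voxelwise
  phan <- small_phantom(seed = 12, shape = c(24, 24, 2))
  acq <- acquisition_config(target_snr = Inf)
  sim <- simulate_multiphase(phan, acq)
  i <- which(phan$mask & phan$f > 0)[100]
  p <- acq$kinetic
  p$f <- phan$f[i]; p$delta_t <- phan$bat[i]
  p$t1_tissue <- phan$t1[i]; p$m0_blood <- phan$m0[i] / p$lam
  expect_equal(sim$truth$amplitude[i],
               buxton_delta_m(acq$tau + acq$pld, p))
})
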