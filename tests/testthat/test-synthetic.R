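# Phantom generator: rendering fidelity, determinism, conservation,
# wash-in kinetics, and the circumferential dataset.

test_that("background-only frame is constant and invalid specs are rejected", {
  sp <- frame_spec(fov_um = 64, grid_px = 64, background_au = 37,
                   noise_sd_au = 0, psf_sigma_um = 2)
  fr <- generate_vessel_frame(sp, list())$frame
  expect_equal(dim(fr$pixels), c(64L, 64L))
  expect_true(all(abs(fr$pixels - 37) < 1e-9))

  expect_error(frame_spec(fov_um = -1), "fov_um")
  expect_error(frame_spec(grid_px = 16), "grid_px")
  expect_error(frame_spec(noise_sd_au = -1), "noise_sd_au")
  expect_error(vessel_truth(cbind(1, 1), 2, 1), "centerline")
  expect_error(vessel_truth(cbind(c(0, 1), c(0, 1)), -2, 1), "sigma0_um")
})

test_that("vessel cross-section is Gaussian with variance sigma0^2 + psf^2", {
  sp <- frame_spec(fov_um = 423, grid_px = 512, background_au = 0,
                   noise_sd_au = 0)
  sigma0 <- fwhm_to_sigma(30)
  v <- vessel_truth(cbind(c(-50, 500), c(211.5, 211.5)), sigma0, 100)
  fr <- generate_vessel_frame(sp, list(v))$frame
  col <- fr$pixels[, 256]
  y_um <- (seq_len(512) - 1) * fr$pitch_um
  sig_eff <- sqrt(sigma0^2 + sp$psf_sigma_um^2)
  pred <- max(col) * exp(-(y_um - 211.5)^2 / (2 * sig_eff^2))
  expect_lt(max(abs(col - pred)) / max(col), 0.01)
})

test_that("rendered FWHM matches PSF-broadened truth within 5% for 10-50 um", {
  sp <- frame_spec(fov_um = 423, grid_px = 512, background_au = 0,
                   noise_sd_au = 0)
  for (fw in c(10, 20, 30, 40, 50)) {
    s0 <- fwhm_to_sigma(fw)
    v <- vessel_truth(cbind(c(-50, 500), c(211.5, 211.5)), s0, 100)
    fr <- generate_vessel_frame(sp, list(v))$frame
    y_um <- (seq_len(512) - 1) * fr$pitch_um
    measured <- profile_fwhm(y_um, fr$pixels[, 256])
    expected <- sigma_to_fwhm(sqrt(s0^2 + sp$psf_sigma_um^2))
    expect_lt(abs(measured - expected) / expected, 0.05)
  }
})

test_that("generation is deterministic in the seed and clamped at zero", {
  sp <- frame_spec(fov_um = 100, grid_px = 64, background_au = 5,
                   noise_sd_au = 20, seed = 11)
  v <- vessel_truth(cbind(c(0, 100), c(50, 50)), 5, 40)
  f1 <- generate_vessel_frame(sp, list(v))$frame
  f2 <- generate_vessel_frame(sp, list(v))$frame
  expect_identical(f1$pixels, f2$pixels)
  expect_true(all(f1$pixels >= 0))   # noise SD >> background forces clamping
  sp2 <- sp; sp2$seed <- 12
  expect_false(identical(generate_vessel_frame(sp2, list(v))$frame$pixels,
                         f1$pixels))
  # ground truth passes through unchanged
  expect_identical(generate_vessel_frame(sp, list(v))$truth[[1]], v)
})

test_that("total rendered intensity matches the analytic tube integral", {
  # zero noise, zero background: PSF convolution preserves the integral,
  # so sum = A*(sqrt(2*pi)*sigma0*L + 2 half-disc end caps of pi*sigma0^2
  # each) / pitch^2.
  sp <- frame_spec(fov_um = 200, grid_px = 256, background_au = 0,
                   noise_sd_au = 0)
  s0 <- fwhm_to_sigma(20)
  cl <- cbind(c(50, 150), c(60, 140))   # fully interior diagonal segment
  v <- vessel_truth(cl, s0, 80)
  fr <- generate_vessel_frame(sp, list(v))$frame
  L <- sqrt(sum((cl[2, ] - cl[1, ])^2))
  analytic <- 80 * (sqrt(2 * pi) * s0 * L + 2 * pi * s0^2) /
    sp$pitch_um^2
  expect_lt(abs(sum(fr$pixels) - analytic) / analytic, 0.02)
})

test_that("wash-in series has the right length, rise, and presets", {
  sp <- frame_spec(fov_um = 100, grid_px = 64, background_au = 10,
                   noise_sd_au = 0)
  v <- vessel_truth(cbind(c(-10, 110), c(50, 50)), 6, 100)
  wt <- washin_truth(tau_s = 84, t0_s = 0, duration_s = 480,
                     frame_interval_s = 10)
  ser <- generate_washin_series(sp, wt, list(v))
  expect_length(ser, floor(480 / 10) + 1)
  roi <- fov_roi(ser[[1]]$frame)
  last <- roi_total_intensity(ser[[length(ser)]]$frame, roi)
  # e^(-480/84) < 0.01: last frame within 1% of the plateau frame
  plateau <- roi_total_intensity(
    generate_vessel_frame(sp, list(v))$frame, roi)
  expect_gte(last, 0.99 * plateau)
  # background-only first frame (w(0) = 0)
  expect_equal(roi_total_intensity(ser[[1]]$frame, roi),
               10 * length(ser[[1]]$frame$pixels))

  # boundary case: interval = duration -> exactly 2 frames
  wt2 <- washin_truth(tau_s = 10, duration_s = 100, frame_interval_s = 10)
  wt2$frame_interval_s <- 100   # boundary: interval == duration
  expect_length(generate_washin_series(sp, wt2, list(v)), 2L)

  expect_error(washin_truth(tau_s = -5), "tau_s")
  # presets: time to 95% plateau is tau * ln 20
  expect_equal(washin_preset("porcine")$tau_s * log(20), 300)
  expect_equal(washin_preset("human")$tau_s * log(20), 420)
})

test_that("limbal dataset respects the grid, labels, and group means", {
  sp <- frame_spec()
  ds1 <- generate_limbal_dataset(sp, limbal_effect_spec(n_eyes = 1),
                                 seed = 3)
  expect_equal(nrow(ds1$truth), 24L)
  expect_equal(sum(ds1$truth$quadrant == "inferior"), 7L)
  expect_equal(sum(ds1$truth$quadrant == "other"), 17L)
  # stored labels agree with assign_quadrant on every angle
  expect_identical(ds1$truth$quadrant, assign_quadrant(ds1$truth$angle_deg))
  expect_error(limbal_effect_spec(angles_deg = c(0, 10)), "15")

  # inferior truth mean within 3 SEM of the configured 1742 au over the
  # 14 inferior draws (2 eyes x 7 angles)
  ds2 <- generate_limbal_dataset(sp, limbal_effect_spec(n_eyes = 2),
                                 seed = 101)
  inf <- ds2$truth$total_au[ds2$truth$quadrant == "inferior"]
  expect_length(inf, 14L)
  expect_lt(abs(mean(inf) - 1742), 3 * 271 / sqrt(14))

  # determinism
  ds3 <- generate_limbal_dataset(sp, limbal_effect_spec(n_eyes = 1),
                                 seed = 3)
  expect_identical(ds1$truth, ds3$truth)
})

test_that("rendered limbal frames carry the drawn vessel totals", {
  sp <- frame_spec(grid_px = 128, fov_um = 280, background_au = 1,
                   noise_sd_au = 0.02)
  eff <- limbal_effect_spec(angles_deg = seq(0, 345, 15), n_eyes = 1)
  ds <- generate_limbal_dataset(sp, eff, seed = 9, render = TRUE)
  expect_length(ds$frames, 24L)
  # background-corrected ROI total tracks the drawn ground truth
  k <- which(ds$truth$total_au > 500)[1:4]
  for (i in k) {
    measured <- roi_vessel_total(ds$frames[[i]], fov_roi(ds$frames[[i]]))
    expect_lt(abs(measured - ds$truth$total_au[i]) /
                ds$truth$total_au[i], 0.15)
  }
  # high-diameter vessels appear in contiguous angular runs
  tbl <- diameter_by_angle(ds$truth)
  runs <- cluster_span(tbl, 0.6 * diff(eff$diameter_range_um) +
                         eff$diameter_range_um[1])
  expect_gte(nrow(runs), 1L)
  expect_true(all(runs$span_deg >= 15))
})
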