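# Multiscale ridge detection: closed-form scale selection, point
# detection, linking, diameter estimation, and overlays.

test_that("constant image has zero ridge response at every scale", {
  fr <- frame_image(matrix(42, 100, 100), pitch_um = 1)
  st <- scale_space_response(fr, px_params(sigmas = c(2, 4, 8)))
  expect_true(all(st$response == 0))
})

test_that("frames smaller than the largest kernel are rejected", {
  fr <- frame_image(matrix(1, 64, 64), pitch_um = 1)
  expect_error(scale_space_response(fr, px_params(sigmas = c(5, 20))),
               "too small")
})

test_that("selected scale matches the analytic optimum for gamma 0.75 and 1", {
  # R(t) ~ t^gamma * sigma0 * (sigma0^2 + t)^(-3/2) is maximized at
  # t = gamma*sigma0^2/(3/2 - gamma); brute-force dense-grid scan confirms
  grid_t <- exp(seq(log(0.5), log(900), length.out = 4000))
  for (g in c(0.75, 1)) {
    s0 <- 6
    R <- grid_t^g * s0 * (s0^2 + grid_t)^(-3 / 2)
    brute <- sqrt(grid_t[which.max(R)])
    expect_equal(brute, analytic_opt_sigma(s0, g), tolerance = 1e-3)
  }
  # and the detector reproduces it on rendered ridges
  for (g in c(0.75, 1)) {
    for (s0 in c(3, 6, 9)) {
      p <- px_params(gamma = g, response_threshold = 1e-3)
      fr <- mk_ridge_frame(160, s0)
      pts <- detect_ridge_points(scale_space_response(fr, p), p)
      expect_gt(nrow(pts), 50)
      step <- exp(diff(log(range(p$sigmas_um))) / (length(p$sigmas_um) - 1))
      ratio <- median(pts$sigma_star_um) / analytic_opt_sigma(s0, g)
      expect_lt(abs(log(ratio)), log(step))
    }
  }
})

test_that("per-pixel max over scales equals a brute-force loop exactly", {
  set.seed(4)
  fr <- frame_image(matrix(runif(80 * 80, 0, 100), 80, 80), pitch_um = 1)
  p <- px_params(sigmas = c(2, 3, 5, 8))
  st <- scale_space_response(fr, p)
  am <- limbusflow:::stack_scale_argmax(st$response)
  brute_max <- matrix(0, 80, 80)
  brute_which <- matrix(1L, 80, 80)
  for (i in 1:80) for (j in 1:80) {
    v <- st$response[i, j, ]
    brute_max[i, j] <- max(v)
    brute_which[i, j] <- which.max(v)   # which.max keeps the first maximum
  }
  expect_identical(am$max, brute_max)
  expect_identical(am$which, brute_which)
})

test_that("detected midline is sub-pixel accurate on a noiseless ridge", {
  fr <- mk_ridge_frame(120, 5)
  p <- px_params(response_threshold = 1e-3)
  pts <- detect_ridge_points(scale_space_response(fr, p), p)
  # brute-force argmax per column sits on the center row
  expect_true(all(abs(pts$y_px - 59.5) <= 0.5))
  expect_gt(nrow(pts), 100)
})

test_that("a threshold above the global maximum yields no points", {
  fr <- mk_ridge_frame(100, 4)
  p <- px_params(sigmas = c(2, 4, 8), response_threshold = 1e9)
  pts <- detect_ridge_points(scale_space_response(fr, p), p)
  expect_equal(nrow(pts), 0L)
})

test_that("two parallel ridges stay separate with no points between", {
  # ridges 60 um apart, sigma0 = 6 um (pitch 1 -> px == um)
  n <- 200
  y <- matrix(rep(seq_len(n) - 1, times = n), nrow = n)
  m <- 100 * exp(-(y - 70)^2 / (2 * 36)) + 100 * exp(-(y - 130)^2 / (2 * 36))
  fr <- frame_image(m, pitch_um = 1)
  p <- px_params(response_threshold = 1e-3)
  pts <- detect_ridge_points(scale_space_response(fr, p), p)
  expect_gt(sum(abs(pts$y_px - 70) < 2), 50)
  expect_gt(sum(abs(pts$y_px - 130) < 2), 50)
  expect_equal(sum(pts$y_px > 85 & pts$y_px < 115), 0L)
})

test_that("linking joins one ridge into one segment and handles crossings", {
  fr <- mk_ridge_frame(120, 5)
  p <- px_params(response_threshold = 1e-3)
  pts <- detect_ridge_points(scale_space_response(fr, p), p)
  segs <- link_ridges(pts, p)
  expect_length(segs, 1L)
  expect_gte(nrow(segs[[1]]), 0.9 * nrow(pts))

  expect_identical(link_ridges(limbusflow:::empty_ridge_points(), p),
                   list())

  # X phantom: two crossing straight tubes
  sp <- frame_spec(fov_um = 200, grid_px = 200, background_au = 0,
                   noise_sd_au = 0, psf_sigma_um = 0)
  v1 <- vessel_truth(cbind(c(-20, 220), c(40, 160)), 4, 100)
  v2 <- vessel_truth(cbind(c(-20, 220), c(160, 40)), 4, 100)
  fr2 <- generate_vessel_frame(sp, list(v1, v2))$frame
  seg2 <- segment_vessels(fr2, px_params(response_threshold = 1e-3),
                          psf_sigma_um = 0)
  expect_equal(seg2$n_segments, 2L)
  # the crossing point belongs to exactly one segment
  ctr <- seg2$points[abs(seg2$points$x_px - 100) < 1.5 &
                       abs(seg2$points$y_px - 100) < 1.5, ]
  expect_lte(length(unique(ctr$segment_id)), 1L)
})

test_that("diameters deconvolve the PSF and flag degenerate widths", {
  psf <- fwhm_to_sigma(3.5)
  seg <- data.frame(sigma_star_um = psf, response = 1)
  out <- estimate_diameter(seg, psf_sigma_um = psf)
  expect_lt(out$diameter_um, 0.01)   # point-like
  # recovery: sigma* = sqrt(sigma0^2 + psf^2) -> diameter = FWHM of sigma0
  s0 <- fwhm_to_sigma(30)
  seg2 <- data.frame(sigma_star_um = sqrt(s0^2 + psf^2))
  expect_equal(estimate_diameter(seg2, psf_sigma_um = psf)$diameter_um, 30,
               tolerance = 1e-6)
})

test_that("diameter estimates are amplitude-invariant", {
  sp <- frame_spec(fov_um = 200, grid_px = 200, background_au = 20,
                   noise_sd_au = 0)
  v <- vessel_truth(cbind(c(-20, 220), c(100, 100)), fwhm_to_sigma(25), 50)
  f1 <- generate_vessel_frame(sp, list(v))$frame
  f2 <- frame_image(2 * f1$pixels, f1$pitch_um)
  p <- scale_space_params(response_threshold = 1e-3)
  s1 <- segment_vessels(f1, p, psf_sigma_um = sp$psf_sigma_um)
  s2 <- segment_vessels(f2, p, psf_sigma_um = sp$psf_sigma_um)
  expect_equal(s1$points$diameter_um, s2$points$diameter_um,
               tolerance = 1e-8)
})

test_that("median diameter increases strictly with true FWHM", {
  meds <- vapply(c(10, 20, 30, 40, 50), function(fw) {
    sp <- frame_spec(fov_um = 250, grid_px = 256, background_au = 50,
                     noise_sd_au = 10, seed = 100 + fw)
    v <- vessel_truth(cbind(c(-20, 300), c(125, 125)), fwhm_to_sigma(fw),
                      100)
    fr <- generate_vessel_frame(sp, list(v))$frame
    seg <- segment_vessels(fr, scale_space_params(),
                           psf_sigma_um = sp$psf_sigma_um)
    median(seg$points$diameter_um)
  }, numeric(1))
  expect_true(all(diff(meds) > 0))
})

test_that("diameter estimates are rotation-invariant within 5% relative SD", {
  meds <- vapply(seq(0, 170, by = 30), function(ang) {
    th <- ang * pi / 180
    dirv <- c(cos(th), sin(th))
    cl <- rbind(c(100, 100) - 300 * dirv, c(100, 100) + 300 * dirv)
    sp <- frame_spec(fov_um = 200, grid_px = 200, background_au = 50,
                     noise_sd_au = 10, seed = 11)
    v <- vessel_truth(cl, fwhm_to_sigma(25), 100)
    fr <- generate_vessel_frame(sp, list(v))$frame
    seg <- segment_vessels(fr, scale_space_params(),
                           psf_sigma_um = sp$psf_sigma_um)
    median(seg$points$diameter_um[!seg$points$near_edge])
  }, numeric(1))
  expect_lt(sd(meds) / mean(meds), 0.05)
})

test_that("whole-pixel shifts of the phantom shift the midline equally", {
  n <- 140; shift <- 7
  m1 <- mk_ridge_matrix(n, 5)
  m2 <- rbind(matrix(0, shift, n), m1[seq_len(n - shift), ])
  p <- px_params(response_threshold = 1e-3)
  pts1 <- detect_ridge_points(
    scale_space_response(frame_image(m1, 1), p), p)
  pts2 <- detect_ridge_points(
    scale_space_response(frame_image(m2, 1), p), p)
  y1 <- median(pts1$y_px[pts1$x_px > 30 & pts1$x_px < 110])
  y2 <- median(pts2$y_px[pts2$x_px > 30 & pts2$x_px < 110])
  expect_lt(abs((y2 - y1) - shift), 0.5)
})

test_that("overlay paints midlines red and borders blue at the radius", {
  sp <- frame_spec(fov_um = 200, grid_px = 200, background_au = 20,
                   noise_sd_au = 0)
  v <- vessel_truth(cbind(c(-20, 220), c(100, 100)), fwhm_to_sigma(30), 100)
  fr <- generate_vessel_frame(sp, list(v))$frame
  seg <- segment_vessels(fr, scale_space_params(response_threshold = 1e-3),
                         psf_sigma_um = sp$psf_sigma_um)
  rgb <- render_overlay(fr, seg)
  red <- rgb[, , 1] == 1 & rgb[, , 2] == 0 & rgb[, , 3] == 0
  blue <- rgb[, , 3] == 1 & rgb[, , 1] == 0 & rgb[, , 2] == 0
  # one red pixel per de-duplicated rounded midline position
  uniq_mid <- unique(paste(round(seg$points$x_px), round(seg$points$y_px)))
  expect_equal(sum(red), length(uniq_mid))
  # mean distance from blue to nearest red approximates the median radius
  ri <- which(red, arr.ind = TRUE); bi <- which(blue, arr.ind = TRUE)
  dmin <- vapply(seq_len(nrow(bi)), function(k)
    sqrt(min((ri[, 1] - bi[k, 1])^2 + (ri[, 2] - bi[k, 2])^2)),
    numeric(1))
  r_px <- median(seg$points$diameter_um / 2) / fr$pitch_um
  expect_lt(abs(mean(dmin) - r_px), 1)

  # no segments -> pure grayscale
  empty <- segment_vessels(frame_image(matrix(7, 100, 100), 1),
                           px_params(sigmas = c(2, 4),
                                     response_threshold = 10))
  rgb0 <- render_overlay(frame_image(matrix(7, 100, 100), 1), empty)
  expect_true(all(rgb0[, , 1] == rgb0[, , 2] & rgb0[, , 2] == rgb0[, , 3]))
})
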