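# Phantom builders and independent oracles used across the suite.

# Pure matrix Gaussian ridge (horizontal), built directly from the profile
# formula — independent of the package's renderer. Center row at
# (n-1)/2 in 0-based coordinates.
mk_ridge_matrix <- function(n, sigma0_px, A = 100, background = 0) {
  y <- matrix(rep(seq_len(n) - 1, times = n), nrow = n)
  background + A * exp(-(y - (n - 1) / 2)^2 / (2 * sigma0_px^2))
}

mk_ridge_frame <- function(n, sigma0_px, A = 100, background = 0,
                           pitch_um = 1) {
  frame_image(mk_ridge_matrix(n, sigma0_px, A, background), pitch_um)
}

# Closed-form optimal scale for a gamma-normalized ridge response on a
# Gaussian profile of SD sigma0: t* = gamma * sigma0^2 / (3/2 - gamma).
analytic_opt_sigma <- function(sigma0, gamma) {
  sigma0 * sqrt(gamma / (1.5 - gamma))
}

# Brute-force ROI total: double loop over pixel centers.
roi_sum_bruteforce <- function(frame, roi) {
  m <- frame$pixels
  tot <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      if ((j - 1 - roi$center_px[1])^2 + (i - 1 - roi$center_px[2])^2 <=
          roi$radius_px^2)
        tot <- tot + m[i, j]
    }
  }
  tot
}

# FWHM of a sampled profile by linear interpolation at half maximum,
# measured on both flanks.
profile_fwhm <- function(x, y) {
  half <- max(y) / 2
  i_pk <- which.max(y)
  left <- which(y[seq_len(i_pk)] < half)
  right <- i_pk - 1 + which(y[i_pk:length(y)] < half)
  if (length(left) == 0 || length(right) == 0) return(NA_real_)
  l <- max(left); r <- min(right)
  xl <- x[l] + (half - y[l]) / (y[l + 1] - y[l]) * (x[l + 1] - x[l])
  xr <- x[r - 1] + (half - y[r - 1]) / (y[r] - y[r - 1]) * (x[r] - x[r - 1])
  xr - xl
}

# Default small scale grid in pixel units (pitch 1) for ridge tests.
px_params <- function(..., sigmas = exp(seq(log(1.5), log(20),
                                            length.out = 14))) {
  scale_space_params(sigmas_um = sigmas, ...)
}
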