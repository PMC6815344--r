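# Synthetic CLE phantom generation: frames with Gaussian-profile tubular
# vessels, wash-in time series, and full circumferential (limbal) datasets
# with known ground truth.

#' Frame specification for the phantom generator
#'
#' Describes the simulated imaging system. Defaults emulate a fiber-bundle
#' confocal laser endomicroscope: 423 x 423 um field of view sampled on a
#' 512 px grid (pitch ~0.826 um) and an isotropic Gaussian PSF whose FWHM
#' equals the 3.5 um lateral resolution.
#'
#' @param fov_um physical field width (um).
#' @param grid_px pixels per side (>= 64).
#' @param background_au mean background intensity (au).
#' @param noise_sd_au additive Gaussian noise SD (au), >= 0.
#' @param psf_sigma_um optical blur SD (um); default \code{fwhm_to_sigma(3.5)}.
#' @param seed integer RNG seed used by the generators.
#' @return An object of class \code{frame_spec}.
#' @examples
#' frame_spec(noise_sd_au = 0)
#' @export
frame_spec <- function(fov_um = 423, grid_px = 512L, background_au = 50,
                       noise_sd_au = 10, psf_sigma_um = fwhm_to_sigma(3.5),
                       seed = 1L) {
  stopifnot_scalar_pos(fov_um, "fov_um")
  if (!is.numeric(grid_px) || length(grid_px) != 1L || grid_px < 64)
    stop("grid_px must be a single integer >= 64", call. = FALSE)
  if (!is.numeric(noise_sd_au) || noise_sd_au < 0)
    stop("noise_sd_au must be >= 0", call. = FALSE)
  if (background_au < 0) stop("background_au must be >= 0", call. = FALSE)
  if (psf_sigma_um < 0) stop("psf_sigma_um must be >= 0", call. = FALSE)
  structure(list(fov_um = fov_um, grid_px = as.integer(grid_px),
                 background_au = background_au, noise_sd_au = noise_sd_au,
                 psf_sigma_um = psf_sigma_um, seed = seed,
                 pitch_um = fov_um / grid_px),
            class = "frame_spec")
}

#' @export
print.frame_spec <- function(x, ...) {
  cat(sprintf(
    "<frame_spec> FOV %g um on %d px (pitch %.4g um), PSF sigma %.3g um,\n",
    x$fov_um, x$grid_px, x$pitch_um, x$psf_sigma_um))
  cat(sprintf("  background %g au, noise SD %g au, seed %s\n",
              x$background_au, x$noise_sd_au, format(x$seed)))
  invisible(x)
}

#' Ground-truth vessel description
#'
#' A tubular vessel with Gaussian cross-sectional intensity
#' I(d) = amplitude * exp(-d^2 / (2 sigma0^2)), where d is the distance to
#' the centerline. The ground-truth diameter is the profile FWHM,
#' 2*sqrt(2*ln 2)*sigma0.
#'
#' @param centerline numeric matrix (n x 2) of (x, y) points in um, n >= 2.
#' @param sigma0_um Gaussian cross-section SD (um), > 0.
#' @param amplitude_au peak intraluminal intensity above background (au), > 0.
#' @return An object of class \code{vessel_truth} with an added
#'   \code{truth_diameter_um} field.
#' @examples
#' v <- vessel_truth(cbind(c(0, 400), c(200, 200)), fwhm_to_sigma(30), 100)
#' v$truth_diameter_um   # 30
#' @export
vessel_truth <- function(centerline, sigma0_um, amplitude_au) {
  centerline <- as.matrix(centerline)
  if (ncol(centerline) != 2L || nrow(centerline) < 2L)
    stop("centerline must be an n x 2 matrix with n >= 2", call. = FALSE)
  stopifnot_scalar_pos(sigma0_um, "sigma0_um")
  stopifnot_scalar_pos(amplitude_au, "amplitude_au")
  structure(list(centerline = centerline, sigma0_um = sigma0_um,
                 amplitude_au = amplitude_au,
                 truth_diameter_um = sigma_to_fwhm(sigma0_um)),
            class = "vessel_truth")
}

#' Wash-in kinetics specification
#'
#' Single saturating exponential rise of intravascular fluorescence after
#' dye injection: w(t) = 1 - exp(-(t - t0)/tau) for t >= t0, else 0. Vessel
#' amplitudes are scaled by w(t); the plateau amplitude corresponds to
#' w = 1. Presets \code{washin_preset} give time constants whose noiseless
#' time to 95% of plateau (tau * ln 20) is 300 s (porcine) or 420 s (human).
#'
#' @param tau_s time constant (s), > 0.
#' @param t0_s injection time offset (s).
#' @param duration_s series length (s), >= 10 * frame_interval_s.
#' @param frame_interval_s sampling period (s), > 0.
#' @return An object of class \code{washin_truth}.
#' @examples
#' washin_preset("human")$tau_s * log(20)   # 420 s
#' @export
washin_truth <- function(tau_s, t0_s = 0, duration_s = 480,
                         frame_interval_s = 10) {
  stopifnot_scalar_pos(tau_s, "tau_s")
  stopifnot_scalar_pos(frame_interval_s, "frame_interval_s")
  if (duration_s < 10 * frame_interval_s)
    stop("duration_s must be >= 10 * frame_interval_s", call. = FALSE)
  structure(list(tau_s = tau_s, t0_s = t0_s, duration_s = duration_s,
                 frame_interval_s = frame_interval_s),
            class = "washin_truth")
}

#' @rdname washin_truth
#' @param species "porcine" (plateau reached by 5 min) or "human" (7 min).
#' @export
washin_preset <- function(species = c("porcine", "human"),
                          frame_interval_s = 10, duration_s = 600) {
  species <- match.arg(species)
  t95 <- switch(species, porcine = 300, human = 420)
  washin_truth(tau_s = t95 / log(20), t0_s = 0, duration_s = duration_s,
               frame_interval_s = frame_interval_s)
}

# --- vessel rendering -------------------------------------------------------

# Render the summed vessel contribution (no background, no noise, no PSF)
# on the pixel grid of `spec`. Cross-section Gaussians are truncated at
# 4 sigma for speed; evaluation is restricted to each vessel's bounding box.
render_vessel_field <- function(spec, vessels, washin = 1) {
  n <- spec$grid_px
  pitch <- spec$pitch_um
  V <- matrix(0, n, n)
  if (length(vessels) == 0L) return(V)
  xs <- (seq_len(n) - 1) * pitch   # column centers, um
  ys <- (seq_len(n) - 1) * pitch   # row centers, um
  for (v in vessels) {
    trunc_um <- 4 * v$sigma0_um
    xr <- range(v$centerline[, 1]) + c(-trunc_um, trunc_um)
    yr <- range(v$centerline[, 2]) + c(-trunc_um, trunc_um)
    jj <- which(xs >= xr[1] & xs <= xr[2])
    ii <- which(ys >= yr[1] & ys <= yr[2])
    if (length(ii) == 0L || length(jj) == 0L) next   # fully outside FOV
    px <- rep(xs[jj], each = length(ii))
    py <- rep(ys[ii], times = length(jj))
    d <- dist_to_polyline(px, py, v$centerline)
    prof <- ifelse(d <= trunc_um,
                   v$amplitude_au * exp(-d^2 / (2 * v$sigma0_um^2)), 0)
    V[ii, jj] <- V[ii, jj] + matrix(prof, nrow = length(ii))
  }
  V * washin
}

#' Generate one phantom CLE frame
#'
#' Renders Gaussian-profile tubes along the given centerlines, convolves
#' with the Gaussian PSF, adds the constant background and additive Gaussian
#' noise, and clamps negative intensities to zero. Identical
#' (spec, vessels, seed) reproduce the frame bit-identically.
#'
#' @param spec a \code{\link{frame_spec}}.
#' @param vessels list of \code{\link{vessel_truth}} (may be empty).
#' @return A list with \code{frame} (a \code{\link{frame_image}}) and
#'   \code{truth} (the vessel list, unchanged).
#' @examples
#' sp <- frame_spec(grid_px = 64, fov_um = 64, noise_sd_au = 0,
#'                  psf_sigma_um = 0)
#' v <- vessel_truth(cbind(c(0, 64), c(32, 32)), 3, 100)
#' fr <- generate_vessel_frame(sp, list(v))$frame
#' @export
generate_vessel_frame <- function(spec, vessels = list()) {
  stopifnot(inherits(spec, "frame_spec"))
  if (inherits(vessels, "vessel_truth")) vessels <- list(vessels)
  V <- render_vessel_field(spec, vessels)
  if (spec$psf_sigma_um > 0)
    V <- gauss_smooth(V, spec$psf_sigma_um / spec$pitch_um)
  img <- V + spec$background_au
  if (spec$noise_sd_au > 0)
    img <- with_seed(spec$seed,
                     img + matrix(stats::rnorm(length(img), 0,
                                               spec$noise_sd_au),
                                  nrow = nrow(img)))
  img <- pmax(img, 0)
  list(frame = frame_image(img, spec$pitch_um), truth = vessels)
}

#' Generate a wash-in time series of phantom frames
#'
#' Vessel amplitudes are scaled by the saturating-exponential wash-in factor
#' at each frame time; the background is constant in time. Frame times run
#' from 0 to \code{duration_s} in steps of \code{frame_interval_s}, so the
#' series has floor(duration/interval) + 1 frames.
#'
#' @param spec a \code{\link{frame_spec}}.
#' @param truth a \code{\link{washin_truth}}.
#' @param vessels list of \code{\link{vessel_truth}}.
#' @return A list of elements \code{list(time_s =, frame =)}, with the truth
#'   attached as attributes \code{washin_truth} and \code{vessel_truth}.
#' @export
generate_washin_series <- function(spec, truth, vessels) {
  stopifnot(inherits(spec, "frame_spec"), inherits(truth, "washin_truth"))
  if (inherits(vessels, "vessel_truth")) vessels <- list(vessels)
  times <- seq(0, truth$duration_s, by = truth$frame_interval_s)
  V <- render_vessel_field(spec, vessels)
  if (spec$psf_sigma_um > 0)
    V <- gauss_smooth(V, spec$psf_sigma_um / spec$pitch_um)
  out <- with_seed(spec$seed, lapply(times, function(t) {
    w <- if (t >= truth$t0_s) 1 - exp(-(t - truth$t0_s) / truth$tau_s) else 0
    img <- spec$background_au + w * V
    if (spec$noise_sd_au > 0)
      img <- img + matrix(stats::rnorm(length(img), 0, spec$noise_sd_au),
                          nrow = nrow(img))
    list(time_s = t, frame = frame_image(pmax(img, 0), spec$pitch_um))
  }))
  attr(out, "washin_truth") <- truth
  attr(out, "vessel_truth") <- vessels
  out
}

#' Limbal effect specification
#'
#' Parameters of the circumferential dataset generator: per-angle total
#' vessel fluorescence is drawn from a normal distribution whose mean
#' depends on the quadrant (inferior = 225-315 degrees inclusive vs the
#' rest), and vessel diameters are drawn so that large-calibre vessels
#' occur in contiguous angular runs of about \code{cluster_span_deg}.
#' Default group means and spreads follow the reported group summaries
#' (inferior 1742 +/- 271 au vs other 1300 +/- 316 au); the printed
#' dispersions are used as between-angle SDs.
#'
#' @param angles_deg angle grid, must lie on the 15-degree grid in [0, 360).
#' @param inferior_mean_au,other_mean_au group mean total fluorescence (au).
#' @param inferior_sd_au,other_sd_au between-angle SDs (au), >= 0.
#' @param diameter_range_um sampling interval for vessel diameters (um).
#' @param cluster_span_deg angular width of high-diameter clusters (deg).
#' @param n_eyes number of eyes (default 2).
#' @return An object of class \code{limbal_effect_spec}.
#' @export
limbal_effect_spec <- function(angles_deg = seq(0, 345, by = 15),
                               inferior_mean_au = 1742,
                               other_mean_au = 1300,
                               inferior_sd_au = 271,
                               other_sd_au = 316,
                               diameter_range_um = c(10, 50),
                               cluster_span_deg = 45,
                               n_eyes = 2L) {
  if (any(angles_deg %% 15 != 0) || any(angles_deg < 0 | angles_deg >= 360) ||
      anyDuplicated(angles_deg))
    stop("angles_deg must be distinct multiples of 15 in [0, 360)",
         call. = FALSE)
  if (inferior_sd_au < 0 || other_sd_au < 0)
    stop("group SDs must be >= 0", call. = FALSE)
  if (length(diameter_range_um) != 2L || any(diameter_range_um <= 0) ||
      diff(diameter_range_um) < 0)
    stop("diameter_range_um must be an increasing positive pair",
         call. = FALSE)
  if (n_eyes < 1) stop("n_eyes must be >= 1", call. = FALSE)
  structure(list(angles_deg = sort(angles_deg),
                 inferior_mean_au = inferior_mean_au,
                 other_mean_au = other_mean_au,
                 inferior_sd_au = inferior_sd_au, other_sd_au = other_sd_au,
                 diameter_range_um = diameter_range_um,
                 cluster_span_deg = cluster_span_deg,
                 n_eyes = as.integer(n_eyes)),
            class = "limbal_effect_spec")
}

# Random vessel centerline: a chord through the frame with a random
# orientation and offset, jittered into a gentle curve.
random_chord <- function(fov_um, n_pts = 9L) {
  theta <- stats::runif(1, 0, pi)
  cx <- stats::runif(1, 0.25, 0.75) * fov_um
  cy <- stats::runif(1, 0.25, 0.75) * fov_um
  half <- fov_um    # long enough to cross the FOV
  t <- seq(-half, half, length.out = n_pts)
  bend <- stats::runif(1, -0.2, 0.2) / fov_um
  x <- cx + t * cos(theta) - bend * t^2 * sin(theta)
  y <- cy + t * sin(theta) + bend * t^2 * cos(theta)
  cbind(x, y)
}

#' Generate a circumferential limbal dataset with ground truth
#'
#' For each eye and each angle on the grid, draws the total vessel
#' fluorescence from the quadrant-dependent normal distribution and a set
#' of vessel diameters such that large-diameter vessels fall in contiguous
#' angular runs (two runs per eye of width about \code{cluster_span_deg}).
#' With \code{render = TRUE}, a phantom frame is rendered per angle whose
#' background-subtracted vessel fluorescence equals the drawn ground-truth
#' total before noise.
#'
#' @param spec a \code{\link{frame_spec}}; its seed is ignored in favour of
#'   \code{seed}.
#' @param effect a \code{\link{limbal_effect_spec}}.
#' @param seed integer RNG seed for the whole dataset.
#' @param render render frames (slow) or return ground truth only.
#' @return An object of class \code{limbal_dataset}: list with \code{truth}
#'   (data.frame: eye_id, angle_deg, quadrant, total_au, diameters_um as a
#'   semicolon-separated string), and \code{frames} (named list of
#'   \code{frame_image}, or NULL).
#' @examples
#' eff <- limbal_effect_spec(n_eyes = 1)
#' ds <- generate_limbal_dataset(frame_spec(), eff, seed = 7)
#' table(ds$truth$quadrant)   # 7 inferior, 17 other
#' @export
generate_limbal_dataset <- function(spec, effect, seed = spec$seed,
                                    render = FALSE) {
  stopifnot(inherits(spec, "frame_spec"),
            inherits(effect, "limbal_effect_spec"))
  angles <- effect$angles_deg
  n_ang <- length(angles)
  run_len <- max(1L, round(effect$cluster_span_deg / 15))
  lo <- effect$diameter_range_um[1]; hi <- effect$diameter_range_um[2]
  cut <- lo + 0.6 * (hi - lo)
  rows <- list(); frames <- if (render) list() else NULL
  with_seed(seed, {
    for (eye in seq_len(effect$n_eyes)) {
      eye_id <- sprintf("eye%02d", eye)
      # two diametrically opposed high-diameter runs
      s1 <- sample.int(n_ang, 1L)
      starts <- c(s1, ((s1 - 1L + n_ang %/% 2L) %% n_ang) + 1L)
      in_cluster <- rep(FALSE, n_ang)
      for (s in starts)
        in_cluster[((s - 1L + seq_len(run_len) - 1L) %% n_ang) + 1L] <- TRUE
      for (k in seq_len(n_ang)) {
        ang <- angles[k]
        quad <- assign_quadrant(ang)
        mu <- if (quad == "inferior") effect$inferior_mean_au else
          effect$other_mean_au
        sd <- if (quad == "inferior") effect$inferior_sd_au else
          effect$other_sd_au
        total <- max(0, stats::rnorm(1, mu, sd))
        n_ves <- sample(2:4, 1L)
        diams <- stats::runif(n_ves, lo, cut)
        if (in_cluster[k]) diams[1] <- stats::runif(1, cut, hi)
        rows[[length(rows) + 1L]] <- data.frame(
          eye_id = eye_id, angle_deg = ang, quadrant = quad,
          total_au = total,
          diameters_um = paste(sprintf("%.4f", diams), collapse = ";"),
          stringsAsFactors = FALSE)
        if (render) {
          vs <- lapply(diams, function(d) {
            vessel_truth(random_chord(spec$fov_um), fwhm_to_sigma(d), 1)
          })
          V <- render_vessel_field(spec, vs)
          if (spec$psf_sigma_um > 0)
            V <- gauss_smooth(V, spec$psf_sigma_um / spec$pitch_um)
          sc <- if (sum(V) > 0) total / sum(V) else 0
          img <- spec$background_au + sc * V
          if (spec$noise_sd_au > 0)
            img <- img + matrix(stats::rnorm(length(img), 0,
                                             spec$noise_sd_au),
                                nrow = nrow(img))
          frames[[sprintf("%s_a%03d", eye_id, ang)]] <-
            frame_image(pmax(img, 0), spec$pitch_um)
        }
      }
    }
  })
  truth <- do.call(rbind, rows)
  structure(list(truth = truth, frames = frames, effect = effect,
                 spec = spec, seed = seed),
            class = "limbal_dataset")
}

#' @export
print.limbal_dataset <- function(x, ...) {
  cat(sprintf("<limbal_dataset> %d eyes x %d angles (%d samples)%s\n",
              x$effect$n_eyes, length(x$effect$angles_deg), nrow(x$truth),
              if (is.null(x$frames)) ", truth only" else ", with frames"))
  print(utils::head(x$truth, 4))
  invisible(x)
}
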