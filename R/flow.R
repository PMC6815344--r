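# ROI fluorescence quantification: per-frame totals, intensity-vs-time
# curves, saturating wash-in fits, and per-frame vessel summary tables.

#' Circular region of interest
#'
#' @param center_px 0-based (x, y) pixel-center coordinates of the center.
#' @param radius_px radius in pixels, > 0.
#' @param description optional label.
#' @return An object of class \code{circular_roi}.
#' @export
circular_roi <- function(center_px, radius_px, description = "") {
  if (length(center_px) != 2L || !is.numeric(center_px))
    stop("center_px must be a numeric (x, y) pair", call. = FALSE)
  stopifnot_scalar_pos(radius_px, "radius_px")
  structure(list(center_px = as.numeric(center_px),
                 radius_px = radius_px, description = description),
            class = "circular_roi")
}

#' @rdname circular_roi
#' @param frame a \code{\link{frame_image}}; returns the ROI matching the
#'   full field of view: centered, radius = half the pixel diagonal, so
#'   every pixel of the (square) synthetic field is included. Pass an
#'   explicit \code{circular_roi} to restrict to an inscribed fiber field.
#' @export
fov_roi <- function(frame) {
  d <- dim(frame$pixels)
  circular_roi(center_px = c((d[2] - 1) / 2, (d[1] - 1) / 2),
               radius_px = sqrt(sum(d^2)) / 2,
               description = "field of view")
}

#' Total fluorescence within a circular ROI
#'
#' Sums the intensities of all pixels whose centers lie within the circle
#' (strict Euclidean test; pixels at distance exactly equal to the radius
#' are included).
#'
#' @param frame a \code{\link{frame_image}}.
#' @param roi a \code{\link{circular_roi}}.
#' @return Total intensity (au).
#' @export
roi_total_intensity <- function(frame, roi) {
  stopifnot(inherits(frame, "frame_image"), inherits(roi, "circular_roi"))
  inside <- roi_mask(frame, roi)
  if (!any(inside))
    stop("ROI contains no pixel centers (entirely outside the frame?)",
         call. = FALSE)
  sum(frame$pixels[inside])
}

# Logical membership mask of pixel centers inside the circular ROI.
roi_mask <- function(frame, roi) {
  n <- nrow(frame$pixels); p <- ncol(frame$pixels)
  x <- matrix(rep(seq_len(p) - 1, each = n), nrow = n)
  y <- matrix(rep(seq_len(n) - 1, times = p), nrow = n)
  (x - roi$center_px[1])^2 + (y - roi$center_px[2])^2 <= roi$radius_px^2
}

#' @rdname roi_total_intensity
#' @details \code{roi_vessel_total} subtracts a robust background estimate
#'   (the half-sample mode of the pixel intensities — the modal background
#'   level, insensitive to the minority of vessel pixels) times the ROI
#'   pixel count from the ROI total, clamped at zero — the
#'   background-corrected total vessel fluorescence used by the limbal
#'   pipeline.
#' @export
roi_vessel_total <- function(frame, roi) {
  inside <- roi_mask(frame, roi)
  if (!any(inside))
    stop("ROI contains no pixel centers (entirely outside the frame?)",
         call. = FALSE)
  max(0, sum(frame$pixels[inside]) -
        half_sample_mode(as.vector(frame$pixels)) * sum(inside))
}

#' Build an ROI intensity time course
#'
#' One total per frame, order preserved; frame times must be strictly
#' increasing.
#'
#' @param frames list of elements \code{list(time_s =, frame =)} (as
#'   returned by \code{\link{generate_washin_series}}).
#' @param roi a \code{\link{circular_roi}}; default matches the field of
#'   view of the first frame.
#' @return An object of class \code{timecourse}: data.frame-backed list with
#'   \code{samples} (time_s, total_au), \code{roi}, and an empty \code{fit}.
#' @export
build_timecourse <- function(frames, roi = NULL) {
  if (length(frames) < 2L) stop(">= 2 frames required", call. = FALSE)
  times <- vapply(frames, function(f) f$time_s, numeric(1))
  if (any(diff(times) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (is.null(roi)) roi <- fov_roi(frames[[1]]$frame)
  totals <- vapply(frames, function(f) roi_total_intensity(f$frame, roi),
                   numeric(1))
  structure(list(samples = data.frame(time_s = times, total_au = totals),
                 roi = roi, fit = NULL),
            class = "timecourse")
}

#' @export
print.timecourse <- function(x, ...) {
  cat(sprintf("<timecourse> %d samples, t = [%g, %g] s\n",
              nrow(x$samples), min(x$samples$time_s), max(x$samples$time_s)))
  if (!is.null(x$fit)) {
    f <- x$fit
    cat(sprintf(
      "  wash-in fit: plateau %.4g au, tau %.4g s, t0 %.4g s (RMSE %.3g)\n",
      f$plateau_au, f$tau_s, f$t0_s, f$rmse_au))
    cat(sprintf("  optimal imaging time (95%% of plateau): %.4g s%s\n",
                f$optimal_time_s,
                if (f$converged) "" else "  [fit did not converge]"))
  }
  invisible(x)
}

#' Fit the saturating wash-in model to a time course
#'
#' Nonlinear least squares (Levenberg-Marquardt with bounds) of
#' total(t) = B + Iinf * (1 - exp(-(t - t0)/tau)) for t >= t0 (and B
#' before t0). The optimal imaging time is the time to reach 95% of the
#' fitted plateau, t0 + tau * ln 20. Non-convergence returns the course
#' with a \code{converged = FALSE} flag rather than an error. Start values:
#' Iinf0 = range of the totals, tau0 = one third of the time span, t00 =
#' time of the first sample exceeding min + 5% of range.
#'
#' @param tc a \code{\link{build_timecourse}} result (or a data.frame with
#'   \code{time_s} and \code{total_au}).
#' @param plateau_fraction fraction of plateau defining the optimal time
#'   (default 0.95).
#' @return The \code{timecourse} with \code{fit} filled in: plateau_au,
#'   tau_s, t0_s, baseline_au, rmse_au, optimal_time_s, converged,
#'   degenerate, plateau_fraction.
#' @export
fit_washin <- function(tc, plateau_fraction = 0.95) {
  if (is.data.frame(tc))
    tc <- structure(list(samples = tc, roi = NULL, fit = NULL),
                    class = "timecourse")
  s <- tc$samples
  if (nrow(s) < 5L)
    stop("wash-in fit needs >= 5 samples", call. = FALSE)
  t <- s$time_s; y <- s$total_au
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps * max(1, max(abs(y)))) {
    tc$fit <- list(plateau_au = 0, tau_s = NA_real_, t0_s = t[1],
                   baseline_au = y[1], rmse_au = 0, optimal_time_s = t[1],
                   converged = TRUE, degenerate = TRUE,
                   plateau_fraction = plateau_fraction)
    return(tc)
  }
  t00 <- t[which(y > min(y) + 0.05 * rng)[1]]
  span <- diff(range(t))
  start <- list(B = min(y), Iinf = rng, tau = span / 3, t0 = t00)
  lower <- c(B = 0, Iinf = 0, tau = span * 1e-4, t0 = min(t) - span)
  upper <- c(B = max(y), Iinf = 10 * rng, tau = 100 * span, t0 = max(t))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ B + Iinf * (1 - exp(-pmax(t - t0, 0) / tau)),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    tc$fit <- list(plateau_au = NA_real_, tau_s = NA_real_, t0_s = NA_real_,
                   baseline_au = NA_real_, rmse_au = NA_real_,
                   optimal_time_s = NA_real_, converged = FALSE,
                   degenerate = FALSE, plateau_fraction = plateau_fraction)
    return(tc)
  }
  cf <- stats::coef(fit)
  rmse <- sqrt(mean(stats::resid(fit)^2))
  tc$fit <- list(plateau_au = unname(cf["Iinf"]), tau_s = unname(cf["tau"]),
                 t0_s = unname(cf["t0"]), baseline_au = unname(cf["B"]),
                 rmse_au = rmse,
                 optimal_time_s = unname(cf["t0"] -
                                           cf["tau"] *
                                           log(1 - plateau_fraction)),
                 converged = TRUE, degenerate = FALSE,
                 plateau_fraction = plateau_fraction)
  tc
}

#' @export
coef.timecourse <- function(object, ...) {
  if (is.null(object$fit)) stop("time course not fitted", call. = FALSE)
  with(object$fit, c(plateau_au = plateau_au, tau_s = tau_s, t0_s = t0_s,
                     baseline_au = baseline_au,
                     optimal_time_s = optimal_time_s))
}

#' @export
predict.timecourse <- function(object, newdata = NULL, ...) {
  if (is.null(object$fit) || !isTRUE(object$fit$converged))
    stop("no converged fit to predict from", call. = FALSE)
  t <- if (is.null(newdata)) object$samples$time_s else newdata$time_s
  f <- object$fit
  if (isTRUE(f$degenerate)) return(rep(f$baseline_au, length(t)))
  f$baseline_au + f$plateau_au * (1 - exp(-pmax(t - f$t0_s, 0) / f$tau_s))
}

#' @export
plot.timecourse <- function(x, ...) {
  graphics::plot(x$samples$time_s, x$samples$total_au, pch = 16,
                 xlab = "time (s)", ylab = "ROI total intensity (au)", ...)
  if (!is.null(x$fit) && isTRUE(x$fit$converged) &&
      !isTRUE(x$fit$degenerate)) {
    tt <- seq(min(x$samples$time_s), max(x$samples$time_s), length.out = 200)
    graphics::lines(tt, predict(x, data.frame(time_s = tt)), col = 2)
    graphics::abline(v = x$fit$optimal_time_s, lty = 2, col = 4)
  }
  invisible(x)
}

#' Per-segment vessel summary table for one frame
#'
#' One row per segment: point count, diameter statistics, mean midline
#' response, and total intraluminal intensity (sum over pixels lying within
#' the vessel border, i.e. within the local radius of the midline).
#'
#' @param frame a \code{\link{frame_image}}.
#' @param segments a \code{vessel_segments} object for this frame.
#' @return data.frame with columns segment_id, n_points,
#'   median/mean/min/max_diameter_um, mean_response, total_au.
#' @export
frame_vessel_summary <- function(frame, segments) {
  empty <- data.frame(segment_id = integer(0), n_points = integer(0),
                      median_diameter_um = numeric(0),
                      mean_diameter_um = numeric(0),
                      min_diameter_um = numeric(0),
                      max_diameter_um = numeric(0),
                      mean_response = numeric(0), total_au = numeric(0))
  pts <- segments$points
  if (is.null(pts) || nrow(pts) == 0L) return(empty)
  n <- nrow(frame$pixels); p <- ncol(frame$pixels)
  gx <- rep(seq_len(p) - 1, each = n)
  gy <- rep(seq_len(n) - 1, times = p)
  rows <- lapply(unique(pts$segment_id), function(sid) {
    sp <- pts[pts$segment_id == sid, , drop = FALSE]
    r_px <- stats::median(sp$diameter_um / 2) / frame$pitch_um
    poly <- cbind(sp$x_px, sp$y_px)
    lum <- if (nrow(poly) >= 2) {
      bb_ok <- gx >= min(poly[, 1]) - r_px & gx <= max(poly[, 1]) + r_px &
        gy >= min(poly[, 2]) - r_px & gy <= max(poly[, 2]) + r_px
      d <- dist_to_polyline(gx[bb_ok], gy[bb_ok], poly)
      sum(frame$pixels[bb_ok][d <= r_px])
    } else NA_real_
    data.frame(segment_id = sid, n_points = nrow(sp),
               median_diameter_um = stats::median(sp$diameter_um),
               mean_diameter_um = mean(sp$diameter_um),
               min_diameter_um = min(sp$diameter_um),
               max_diameter_um = max(sp$diameter_um),
               mean_response = mean(sp$response), total_au = lum)
  })
  do.call(rbind, rows)
}
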