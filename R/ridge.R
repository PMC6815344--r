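# Multiscale ridge detection: gamma-normalized Hessian responses across a
# scale grid, per-pixel scale selection, non-maximum suppression with
# sub-pixel localisation, greedy orientation-gated linking, and diameter
# estimation from the selected scale.

#' Scale-space parameters for ridge detection
#'
#' Ridges are detected as the gamma-normalized magnitude of the most
#' negative Hessian eigenvalue of the Gaussian-smoothed frame, evaluated on
#' a grid of smoothing scales. With the default exponent gamma = 0.75 the
#' scale of maximal response on a Gaussian ridge profile of SD sigma0
#' equals sigma0 itself, which gives a parameter-free width calibration
#' (for gamma = 1 the optimum sits at sigma0 * sqrt(2)).
#'
#' @param sigmas_um strictly increasing smoothing scales (SD, um). Default:
#'   12 log-spaced values spanning 1.5-25 um, covering vessel FWHM 10-50 um
#'   with margin.
#' @param gamma scale-normalization exponent in (0, 1.5].
#' @param response_threshold minimum normalized ridge strength kept
#'   (absolute floor; default 0, leaving thresholding to the adaptive rule).
#' @param adaptive_k noise-adaptive threshold multiplier: points must also
#'   exceed \code{adaptive_k} times the calibrated white-noise response
#'   level at their selected scale, where the frame's noise SD is estimated
#'   robustly from pixel differences. Set to 0 to disable.
#' @param link_max_gap_px maximum pixel gap when linking ridge points.
#' @param min_segment_len_px minimum number of points per retained segment.
#' @param combine per-pixel combination rule across scales used for point
#'   detection: \code{"max"} (default; maximum response over scales) or
#'   \code{"median"} (median response over scales). The selected scale
#'   sigma* is the argmax in either case.
#' @param refine_scale refine sigma* between grid points by quadratic
#'   interpolation of log-response over log-scale (default TRUE).
#' @return An object of class \code{scale_space_params}.
#' @export
scale_space_params <- function(sigmas_um = exp(seq(log(1.5), log(25),
                                                   length.out = 12)),
                               gamma = 0.75, response_threshold = 0,
                               adaptive_k = 1.5,
                               link_max_gap_px = 3, min_segment_len_px = 10,
                               combine = c("max", "median"),
                               refine_scale = TRUE) {
  if (length(sigmas_um) < 2L || any(diff(sigmas_um) <= 0) ||
      any(sigmas_um <= 0))
    stop("sigmas_um must be >= 2 strictly increasing positive scales",
         call. = FALSE)
  if (gamma <= 0 || gamma > 1.5)
    stop("gamma must be in (0, 1.5]", call. = FALSE)
  if (response_threshold < 0 || adaptive_k < 0 || link_max_gap_px <= 0 ||
      min_segment_len_px < 1)
    stop("thresholds must be non-negative and lengths positive",
         call. = FALSE)
  structure(list(sigmas_um = sigmas_um, gamma = gamma,
                 response_threshold = response_threshold,
                 adaptive_k = adaptive_k,
                 link_max_gap_px = link_max_gap_px,
                 min_segment_len_px = min_segment_len_px,
                 combine = match.arg(combine),
                 refine_scale = isTRUE(refine_scale)),
            class = "scale_space_params")
}

#' Multiscale ridge response stack
#'
#' For each scale sigma, smooths the frame with a Gaussian of that SD
#' (reflective boundary handling), forms the Hessian from Gaussian
#' derivative kernels, and records the gamma-normalized magnitude of the
#' most negative eigenvalue, (sigma_px^2)^gamma * |lambda_min|, zeroed where
#' lambda_min >= 0. Only bright ridges on a dark background respond
#' (fluorescein is a positive contrast agent). Also records the principal
#' curvature direction (the cross-vessel direction) per pixel and scale.
#'
#' @param frame a \code{\link{frame_image}}.
#' @param params a \code{\link{scale_space_params}}.
#' @return An object of class \code{scale_space_stack}: list with 3-D arrays
#'   \code{response} and \code{theta} (rows x cols x scales), the scale
#'   grids in um and px, and the parameters.
#' @export
scale_space_response <- function(frame, params) {
  stopifnot(inherits(frame, "frame_image"),
            inherits(params, "scale_space_params"))
  m <- frame$pixels
  sig_px <- params$sigmas_um / frame$pitch_um
  need <- ceiling(6 * max(sig_px))
  if (nrow(m) < need || ncol(m) < need)
    stop(sprintf(
      "frame too small for largest scale: need >= %d px per side, have %d x %d",
      need, nrow(m), ncol(m)), call. = FALSE)
  S <- length(sig_px)
  resp <- array(0, dim = c(nrow(m), ncol(m), S))
  theta <- array(0, dim = c(nrow(m), ncol(m), S))
  for (s in seq_len(S)) {
    hr <- hessian_ridge_response(m, sig_px[s], params$gamma)
    resp[, , s] <- hr$response
    theta[, , s] <- hr$theta
  }
  structure(list(response = resp, theta = theta, sigmas_um = params$sigmas_um,
                 noise_sd_au = estimate_noise_sd(m),
                 sigmas_px = sig_px, gamma = params$gamma,
                 pitch_um = frame$pitch_um, params = params,
                 dim = dim(m)),
            class = "scale_space_stack")
}

# Gamma-normalized bright-ridge Hessian response and principal-curvature
# direction at one scale (sigma in px). The response is
# (sigma^2)^gamma * max(-lambda_min, 0) where lambda_min is the most
# negative Hessian eigenvalue of the sigma-smoothed image; theta is the
# eigenvector direction of lambda_min (the cross-vessel direction).
hessian_ridge_response <- function(m, sigma_px, gamma) {
  g0 <- gauss_kernel(sigma_px, 0L)
  g1 <- gauss_kernel(sigma_px, 1L)
  g2 <- gauss_kernel(sigma_px, 2L)
  # x runs along columns, y along rows
  by0 <- conv_cols(m, g0); by1 <- conv_cols(m, g1); by2 <- conv_cols(m, g2)
  Lxx <- conv_rows(by0, g2)
  Lyy <- conv_rows(by2, g0)
  Lxy <- conv_rows(by1, g1)
  tr <- Lxx + Lyy
  disc <- sqrt(pmax((Lxx - Lyy)^2 + 4 * Lxy^2, 0))
  lmin <- (tr - disc) / 2
  resp <- pmax(-lmin, 0)
  # curvature at the level of floating-point ripple is structureless:
  # clamp to exact zero (a constant image has exactly zero response)
  resp[resp <= 1e-12 * max(abs(m))] <- 0
  list(response = (sigma_px^2)^gamma * resp,
       theta = 0.5 * atan2(2 * Lxy, Lxx - Lyy) + pi / 2)
}

# Robust estimate of the additive noise SD of an image from horizontal
# pixel differences: sd = median(|d|) / (0.6745 * sqrt(2)). Smooth image
# structure is sparse in the difference map, so the median is driven by
# the noise; for a noiseless frame the estimate is ~0.
estimate_noise_sd <- function(m) {
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  stats::median(abs(d)) / (0.6745 * sqrt(2))
}

# Calibrated extreme response level of the ridge operator on unit-SD white
# noise, per scale: the max response over a fixed pseudo-random patch
# (deterministic internal seed), memoised on (scale grid, gamma). Used for
# the noise-adaptive detection threshold.
.noise_cal_cache <- new.env(parent = emptyenv())
noise_response_level <- function(sig_px, gamma) {
  key <- paste(c(format(sig_px, digits = 8), gamma), collapse = "|")
  if (!is.null(.noise_cal_cache[[key]])) return(.noise_cal_cache[[key]])
  side <- max(192L, as.integer(ceiling(6 * max(sig_px))) + 1L)
  patch <- with_seed(987654321L,
                     matrix(stats::rnorm(side * side), side, side))
  lev <- vapply(sig_px, function(sp)
    max(hessian_ridge_response(patch, sp, gamma)$response), numeric(1))
  .noise_cal_cache[[key]] <- lev
  lev
}

# Per-pixel argmax over scales; ties broken toward the smallest scale.
# Returns list(max = matrix, which = integer matrix).
stack_scale_argmax <- function(resp) {
  S <- dim(resp)[3]
  best <- resp[, , 1]
  which <- matrix(1L, nrow(best), ncol(best))
  if (S > 1) for (s in 2:S) {
    r <- resp[, , s]
    upd <- r > best            # strict: first (smallest) scale wins ties
    best[upd] <- r[upd]
    which[upd] <- s
  }
  list(max = best, which = which)
}

# Quadratic refinement of the selected scale: fit a parabola to
# log-response vs log-sigma through the argmax and its neighbours.
refine_sigma <- function(resp_at, s_idx, sigmas) {
  S <- length(sigmas)
  if (s_idx <= 1L || s_idx >= S) return(sigmas[s_idx])
  r0 <- resp_at[s_idx - 1L]; r1 <- resp_at[s_idx]; r2 <- resp_at[s_idx + 1L]
  if (r0 <= 0 || r1 <= 0 || r2 <= 0) return(sigmas[s_idx])
  l0 <- log(r0); l1 <- log(r1); l2 <- log(r2)
  den <- l0 - 2 * l1 + l2
  if (den >= 0) return(sigmas[s_idx])
  delta <- 0.5 * (l0 - l2) / den
  delta <- max(min(delta, 1), -1)
  step <- log(sigmas[s_idx + 1L]) - log(sigmas[s_idx])  # uniform log grid
  exp(log(sigmas[s_idx]) + delta * step)
}

#' Detect ridge points across scales
#'
#' Takes the per-pixel maximum response over scales (ties to the smallest
#' scale), keeps pixels that are local maxima of the combined response
#' along the principal-curvature (cross-vessel) direction using non-maximum
#' suppression with sub-pixel quadratic localisation, and that exceed the
#' response threshold. Each kept point records its selected scale sigma*,
#' ridge tangent orientation, and response.
#'
#' @param stack a \code{scale_space_stack} from
#'   \code{\link{scale_space_response}}.
#' @param params a \code{\link{scale_space_params}} (defaults to the one
#'   stored in the stack).
#' @return data.frame of ridge points: \code{x_px, y_px} (0-based sub-pixel),
#'   \code{orientation_rad} (tangent), \code{sigma_star_um},
#'   \code{response}, \code{scale_clipped}, \code{near_edge}.
#' @export
detect_ridge_points <- function(stack, params = stack$params) {
  stopifnot(inherits(stack, "scale_space_stack"))
  n <- stack$dim[1]; p <- stack$dim[2]
  am <- stack_scale_argmax(stack$response)
  comb <- if (params$combine == "median") {
    apply(stack$response, c(1, 2), stats::median)
  } else am$max
  # per-scale threshold: absolute floor plus the noise-adaptive level at
  # the selected scale (calibrated white-noise extreme response times the
  # frame's estimated noise SD)
  thr_scale <- rep(params$response_threshold, length(stack$sigmas_px))
  if (params$adaptive_k > 0 && stack$noise_sd_au > 0) {
    lev <- noise_response_level(stack$sigmas_px, stack$gamma)
    thr_scale <- pmax(thr_scale,
                      params$adaptive_k * stack$noise_sd_au * lev)
  }
  thr_map <- matrix(thr_scale[am$which], nrow = n)
  # relative floor: responses below 0.1% of the frame's strongest ridge are
  # boundary/truncation residue, not vessels (co-detected vessels of equal
  # amplitude differ by ~sqrt(sigma ratio), far less than 1000x)
  thr_map <- pmax(thr_map, 1e-3 * max(comb))
  cand <- which(comb > thr_map & comb > 0, arr.ind = TRUE)
  if (nrow(cand) == 0L)
    return(empty_ridge_points())
  i <- cand[, 1]; j <- cand[, 2]
  sel <- am$which[cand]
  th <- stack$theta[cbind(i, j, sel)]   # cross-vessel direction
  ux <- cos(th); uy <- sin(th)
  x0 <- j - 1; y0 <- i - 1
  r0 <- comb[cand]
  rp <- bilinear(comb, x0 + ux, y0 + uy)
  rm_ <- bilinear(comb, x0 - ux, y0 - uy)
  keep <- r0 >= rp & r0 >= rm_ & (r0 > rp | r0 > rm_)
  if (!any(keep)) return(empty_ridge_points())
  i <- i[keep]; j <- j[keep]; sel <- sel[keep]
  th <- th[keep]; ux <- ux[keep]; uy <- uy[keep]
  x0 <- x0[keep]; y0 <- y0[keep]
  r0 <- r0[keep]; rp <- rp[keep]; rm_ <- rm_[keep]
  den <- rm_ - 2 * r0 + rp
  delta <- ifelse(den < 0, 0.5 * (rm_ - rp) / den, 0)
  delta <- pmin(pmax(delta, -0.5), 0.5)
  sig <- stack$sigmas_um[sel]
  if (params$refine_scale) {
    sig <- vapply(seq_along(i), function(k) {
      refine_sigma(stack$response[i[k], j[k], ], sel[k], stack$sigmas_um)
    }, numeric(1))
  }
  S <- length(stack$sigmas_um)
  clipped <- sel == 1L | sel == S
  sig_px <- sig / stack$pitch_um
  near_edge <- (x0 < 3 * sig_px) | (x0 > p - 1 - 3 * sig_px) |
    (y0 < 3 * sig_px) | (y0 > n - 1 - 3 * sig_px)
  out <- data.frame(
    x_px = x0 + delta * ux, y_px = y0 + delta * uy,
    orientation_rad = (th + pi / 2) %% pi,   # ridge tangent
    sigma_star_um = sig, sigma_star_px = sig_px, response = r0,
    scale_clipped = clipped, near_edge = near_edge)
  # ridges running along the outermost pixels are reflective-padding
  # artifacts (the mirrored image is symmetric about the border)
  out[out$x_px >= 2 & out$x_px <= p - 3 &
        out$y_px >= 2 & out$y_px <= n - 3, , drop = FALSE]
}

empty_ridge_points <- function() {
  data.frame(x_px = numeric(0), y_px = numeric(0),
             orientation_rad = numeric(0), sigma_star_um = numeric(0),
             sigma_star_px = numeric(0), response = numeric(0),
             scale_clipped = logical(0), near_edge = logical(0))
}

#' Link ridge points into vessel segments
#'
#' Greedy linking: starting from the strongest unclaimed point, the midline
#' is extended in both tangent directions to the nearest unclaimed point
#' within \code{link_max_gap_px} whose ridge orientation differs by at most
#' 45 degrees and which lies within 45 degrees of the current heading.
#' Chains whose endpoints are collinear (within 30 degrees) across a gap of
#' up to 6 times \code{link_max_gap_px} are then merged — vessels stay
#' connected across crossings, where non-maximum suppression leaves a void.
#' Short chains that run inside the width footprint of a longer chain
#' (junction spurs) are suppressed. Segments shorter than
#' \code{min_segment_len_px} points are discarded; every input point
#' belongs to at most one segment.
#'
#' @param points data.frame from \code{\link{detect_ridge_points}}.
#' @param params a \code{\link{scale_space_params}}.
#' @return List of segments; each is a data.frame of ordered ridge points
#'   with a \code{segment_id} column.
#' @export
link_ridges <- function(points, params) {
  if (nrow(points) == 0L) return(list())
  ord <- order(-points$response)
  claimed <- rep(FALSE, nrow(points))
  px <- points$x_px; py <- points$y_px
  pth <- points$orientation_rad
  gap <- params$link_max_gap_px
  chains <- list()
  for (seed in ord) {
    if (claimed[seed]) next
    claimed[seed] <- TRUE
    chain <- seed
    for (dir in c(1, -1)) {
      cur <- if (dir == 1) chain[length(chain)] else chain[1]
      heading <- c(cos(pth[seed]), sin(pth[seed])) * dir
      repeat {
        cx <- px[cur]; cy <- py[cur]
        cand <- which(!claimed &
                        abs(px - cx) <= gap & abs(py - cy) <= gap)
        if (length(cand) == 0L) break
        dx <- px[cand] - cx; dy <- py[cand] - cy
        d <- sqrt(dx^2 + dy^2)
        ok <- d > 1e-9 & d <= gap &
          orient_diff(pth[cand], pth[cur]) <= pi / 4 &
          (dx * heading[1] + dy * heading[2]) / pmax(d, 1e-12) >= cos(pi / 4)
        if (!any(ok)) break
        cand <- cand[ok]; d <- d[ok]
        nxt <- cand[which.min(d)]
        claimed[nxt] <- TRUE
        heading <- c(px[nxt] - cx, py[nxt] - cy)
        heading <- heading / sqrt(sum(heading^2))
        if (dir == 1) chain <- c(chain, nxt) else chain <- c(nxt, chain)
        cur <- nxt
      }
    }
    chains[[length(chains) + 1L]] <- chain
  }
  chains <- merge_collinear_chains(chains, px, py, 6 * gap)
  chains <- suppress_spur_chains(chains, points)
  chains <- Filter(function(ch) length(ch) >= params$min_segment_len_px,
                   chains)
  segs <- lapply(seq_along(chains), function(k) {
    seg <- points[chains[[k]], , drop = FALSE]
    seg$segment_id <- k
    rownames(seg) <- NULL
    seg
  })
  segs
}

# Outward end tangent of a chain (unit vector), from up to 8 end points.
chain_end_tangent <- function(chain, px, py, tail_end) {
  k <- min(8L, length(chain))
  idx <- if (tail_end) chain[(length(chain) - k + 1L):length(chain)] else
    rev(chain[seq_len(k)])
  v <- c(px[idx[k]] - px[idx[1]], py[idx[k]] - py[idx[1]])
  nv <- sqrt(sum(v^2))
  if (nv < 1e-9) c(1, 0) else v / nv
}

# Merge chains whose end points face each other within merge_gap and whose
# end tangents are collinear with the connecting direction (<= 45 deg).
merge_collinear_chains <- function(chains, px, py, merge_gap) {
  # tiny chains (noise specks) do not participate in merging
  small <- chains[lengths(chains) < 3L]
  chains <- chains[lengths(chains) >= 3L]
  repeat {
    n <- length(chains)
    if (n < 2L) break
    best <- NULL; best_score <- Inf
    ends <- lapply(chains, function(ch) {
      list(head = c(px[ch[1]], py[ch[1]]),
           tail = c(px[ch[length(ch)]], py[ch[length(ch)]]),
           t_head = chain_end_tangent(ch, px, py, FALSE),
           t_tail = chain_end_tangent(ch, px, py, TRUE))
    })
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      for (ei in c("head", "tail")) for (ej in c("head", "tail")) {
        pi_ <- ends[[i]][[ei]]; pj <- ends[[j]][[ej]]
        d <- sqrt(sum((pj - pi_)^2))
        if (d > merge_gap || d < 1e-9) next
        u <- (pj - pi_) / d
        ti <- ends[[i]][[paste0("t_", ei)]]
        tj <- ends[[j]][[paste0("t_", ej)]]
        # leave end i along its outward tangent, enter end j against its
        a1 <- sum(u * ti); a2 <- sum(-u * tj)
        if (a1 < cos(pi / 6) || a2 < cos(pi / 6)) next
        score <- d + 5 * (2 - a1 - a2)
        if (score < best_score) {
          best_score <- score
          best <- list(i = i, j = j, ei = ei, ej = ej)
        }
      }
    }
    if (is.null(best)) break
    ci <- chains[[best$i]]; cj <- chains[[best$j]]
    if (best$ei == "head") ci <- rev(ci)      # merge at ci tail
    if (best$ej == "tail") cj <- rev(cj)      # ... onto cj head
    merged <- c(ci, cj)
    chains <- c(chains[-c(best$i, best$j)], list(merged))
  }
  c(chains, small)
}

# Drop chains that mostly run inside the width footprint of a longer chain
# (junction spurs from superposed crossing vessels).
suppress_spur_chains <- function(chains, points) {
  if (length(chains) < 2L) return(chains)
  ord <- order(-lengths(chains))
  kept <- list()
  for (k in ord) {
    ch <- chains[[k]]
    spur <- FALSE
    for (K in kept) {
      if (length(K) <= length(ch)) next
      poly <- cbind(points$x_px[K], points$y_px[K])
      tol <- max(2, stats::median(points$sigma_star_px[K]))
      d <- dist_to_polyline(points$x_px[ch], points$y_px[ch], poly)
      if (mean(d <= tol) >= 0.6) { spur <- TRUE; break }
    }
    if (!spur) kept[[length(kept) + 1L]] <- ch
  }
  # restore strongest-first order
  kept[order(-vapply(kept, function(ch) max(points$response[ch]),
                     numeric(1)))]
}

#' Estimate per-point vessel diameter from the selected scale
#'
#' With gamma = 0.75 the scale of maximal normalized response on a Gaussian
#' profile equals the profile SD, so sigma* estimates the (PSF-broadened)
#' cross-section SD. The diameter is the PSF-deconvolved FWHM,
#' 2*sqrt(2*ln 2) * sqrt(max(sigma*^2 - psf_sigma^2, eps)). Points whose
#' selected scale sits at the boundary of the scale grid are flagged
#' \code{scale_clipped} (kept, marked unreliable).
#'
#' @param segment data.frame of ridge points (one segment) carrying
#'   \code{sigma_star_um}.
#' @param psf_sigma_um SD of the optical PSF (um); default matches a 3.5 um
#'   lateral resolution (FWHM). Use 0 for no deconvolution.
#' @param eps_um2 variance floor (um^2) for point-like widths.
#' @return The segment with added \code{diameter_um} column and attribute
#'   \code{median_diameter_um}.
#' @export
estimate_diameter <- function(segment, psf_sigma_um = fwhm_to_sigma(3.5),
                              eps_um2 = 1e-6) {
  var_um2 <- pmax(segment$sigma_star_um^2 - psf_sigma_um^2, eps_um2)
  segment$diameter_um <- FWHM_FACTOR * sqrt(var_um2)
  attr(segment, "median_diameter_um") <- stats::median(segment$diameter_um)
  segment
}

#' Segment vessels in a frame
#'
#' End-to-end ridge segmentation: multiscale response, ridge-point
#' detection, linking, and diameter estimation.
#'
#' @param frame a \code{\link{frame_image}}.
#' @param params a \code{\link{scale_space_params}}.
#' @param psf_sigma_um PSF SD passed to \code{\link{estimate_diameter}}.
#' @return An object of class \code{vessel_segments}: list with
#'   \code{points} (data.frame over all segments, ordered within segment),
#'   \code{n_segments}, \code{frame}, \code{params}.
#' @examples
#' sp <- frame_spec(grid_px = 128, fov_um = 128, noise_sd_au = 0,
#'                  psf_sigma_um = 0, background_au = 10)
#' v <- vessel_truth(cbind(c(0, 128), c(64, 64)), 4, 100)
#' fr <- generate_vessel_frame(sp, list(v))$frame
#' seg <- segment_vessels(fr, scale_space_params(sigmas_um = 2:8),
#'                        psf_sigma_um = 0)
#' seg
#' @export
segment_vessels <- function(frame, params = scale_space_params(),
                            psf_sigma_um = fwhm_to_sigma(3.5)) {
  stack <- scale_space_response(frame, params)
  pts <- detect_ridge_points(stack, params)
  segs <- link_ridges(pts, params)
  segs <- lapply(segs, estimate_diameter, psf_sigma_um = psf_sigma_um)
  all_pts <- if (length(segs)) do.call(rbind, segs) else
    cbind(empty_ridge_points(),
          data.frame(segment_id = integer(0), diameter_um = numeric(0)))
  structure(list(points = all_pts, n_segments = length(segs),
                 frame = frame, params = params,
                 psf_sigma_um = psf_sigma_um),
            class = "vessel_segments")
}

#' @export
print.vessel_segments <- function(x, ...) {
  cat(sprintf("<vessel_segments> %d segment(s), %d ridge point(s)\n",
              x$n_segments, nrow(x$points)))
  if (x$n_segments > 0) {
    med <- tapply(x$points$diameter_um, x$points$segment_id, stats::median)
    cat("  median diameter per segment (um):",
        paste(sprintf("%.1f", med), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
summary.vessel_segments <- function(object, ...) {
  frame_vessel_summary(object$frame, object)
}

#' @export
as.data.frame.vessel_segments <- function(x, ...) x$points

# Border polylines at midline +/- radius along the local normal, per
# segment, in pixel coordinates. Radius = diameter/2 converted to px.
segment_borders <- function(seg_pts, pitch_um) {
  nrm <- (seg_pts$orientation_rad + pi / 2)
  r_px <- (seg_pts$diameter_um / 2) / pitch_um
  list(left = cbind(seg_pts$x_px + r_px * cos(nrm),
                    seg_pts$y_px + r_px * sin(nrm)),
       right = cbind(seg_pts$x_px - r_px * cos(nrm),
                     seg_pts$y_px - r_px * sin(nrm)))
}

#' Render a segmentation overlay
#'
#' 8-bit-style RGB rendering of the frame (grayscale, normalized to its own
#' maximum) with the vessel midlines marked in red and the vessel borders
#' (midline +/- radius along the local normal) outlined in blue.
#'
#' @param frame a \code{\link{frame_image}}.
#' @param segments a \code{vessel_segments} object.
#' @return numeric array (rows x cols x 3) with values in [0, 1].
#' @export
render_overlay <- function(frame, segments) {
  stopifnot(inherits(frame, "frame_image"))
  m <- frame$pixels
  g <- if (max(m) > 0) m / max(m) else m
  rgb <- array(rep(g, 3), dim = c(nrow(m), ncol(m), 3))
  pts <- segments$points
  if (!is.null(pts) && nrow(pts) > 0) {
    paint <- function(x_px, y_px, col) {
      i <- round(y_px) + 1; j <- round(x_px) + 1
      ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
      i <- i[ok]; j <- j[ok]
      for (ch in 1:3) rgb[cbind(i, j, ch)] <<- col[ch]
    }
    for (sid in unique(pts$segment_id)) {
      sp <- pts[pts$segment_id == sid, , drop = FALSE]
      b <- segment_borders(sp, frame$pitch_um)
      paint(b$left[, 1], b$left[, 2], c(0, 0, 1))
      paint(b$right[, 1], b$right[, 2], c(0, 0, 1))
      paint(sp$x_px, sp$y_px, c(1, 0, 0))
    }
  }
  rgb
}

#' @export
plot.vessel_segments <- function(x, ...) {
  rgb <- render_overlay(x$frame, x)
  op <- graphics::par(mar = c(0, 0, 0, 0)); on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::rasterImage(rgb, 0, 0, 1, 1)
  invisible(x)
}
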