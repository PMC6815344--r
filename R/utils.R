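# Internal numerical and plumbing helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the RNG seed, runs \code{expr}, and restores the caller's RNG state,
#' so seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return The value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  invisible(x)
}

# FWHM of a Gaussian = 2*sqrt(2*log(2)) * sigma
FWHM_FACTOR <- 2 * sqrt(2 * log(2))

#' Convert between Gaussian sigma and full width at half maximum
#'
#' Vessel diameter is defined throughout as the FWHM of the Gaussian
#' cross-sectional intensity profile, FWHM = 2*sqrt(2*ln 2)*sigma.
#'
#' @param sigma,fwhm numeric vectors.
#' @return numeric vector of the converted quantity.
#' @examples
#' fwhm_to_sigma(3.5)   # sigma of a PSF with 3.5 um lateral resolution
#' @export
sigma_to_fwhm <- function(sigma) FWHM_FACTOR * sigma

#' @rdname sigma_to_fwhm
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_FACTOR

# --- 1-D Gaussian (derivative) kernels --------------------------------------

# Sampled Gaussian derivative kernel of given order (0, 1, 2), truncated at
# 4 sigma. Order 0 is normalized to unit sum; derivative kernels are
# mean-corrected so they annihilate constants (order 1, 2) and, for order 2,
# reproduce d2/dx2 of smooth inputs to discretization accuracy.
gauss_kernel <- function(sigma_px, order = 0L, truncate = 4) {
  stopifnot_scalar_pos(sigma_px, "sigma_px")
  r <- max(1L, as.integer(ceiling(truncate * sigma_px)))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma_px^2))
  g <- g / sum(g)
  if (order == 0L) return(g)
  if (order == 1L) {
    k <- (-x / sigma_px^2) * g
    k <- k - mean(k)                      # exact zero response to constants
    # normalize so response to a unit ramp is exactly 1
    k / sum(k * x)
  } else if (order == 2L) {
    k <- ((x^2 - sigma_px^2) / sigma_px^4) * g
    k <- k - mean(k)
    # normalize so response to x^2/2 is exactly 1
    k / sum(k * x^2 / 2)
  } else stop("order must be 0, 1 or 2", call. = FALSE)
}

# Indices implementing symmetric (reflective) padding of length r on both
# sides of 1..n: ... 2 1 | 1 2 ... n | n n-1 ...
reflect_idx <- function(n, r) {
  if (r == 0L) return(seq_len(n))
  idx <- seq.int(1L - r, n + r)
  # fold repeatedly for pads wider than the signal
  period <- 2L * n
  idx <- ((idx - 1L) %% period + period) %% period + 1L
  idx[idx > n] <- period - idx[idx > n] + 1L
  idx
}

# Convolve each column of m with kernel k (reflective boundaries). Kernel is
# applied in correlation orientation; all kernels used here are symmetric or
# antisymmetric, and antisymmetric sign conventions cancel in the Hessian
# products we form, so orientation is documented rather than flipped.
conv_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  mp <- m[reflect_idx(n, r), , drop = FALSE]
  K <- matrix(0, nrow = n, ncol = n + 2L * r)
  off <- seq_len(length(k)) - 1L
  i <- rep(seq_len(n), each = length(k))
  j <- rep(seq_len(n), each = length(k)) + off
  K[cbind(i, j)] <- rep(rev(k), times = n)
  K %*% mp
}

conv_rows <- function(m, k) t(conv_cols(t(m), k))

# Separable Gaussian smoothing (reflective boundaries), sigma in pixels.
gauss_smooth <- function(m, sigma_px, truncate = 4) {
  if (sigma_px <= 0) return(m)
  k <- gauss_kernel(sigma_px, 0L, truncate)
  conv_rows(conv_cols(m, k), k)
}

# Bilinear interpolation of matrix m at 0-based pixel-center coordinates
# (x = column - 1, y = row - 1). Out-of-range queries are clamped to the
# frame border. Returns a vector.
bilinear <- function(m, x, y) {
  n <- nrow(m); p <- ncol(m)
  x <- pmin(pmax(x, 0), p - 1)
  y <- pmin(pmax(y, 0), n - 1)
  x0 <- pmin(floor(x), p - 2); y0 <- pmin(floor(y), n - 2)
  fx <- x - x0; fy <- y - y0
  i0 <- y0 + 1; j0 <- x0 + 1
  m[cbind(i0, j0)] * (1 - fx) * (1 - fy) +
    m[cbind(i0, j0 + 1)] * fx * (1 - fy) +
    m[cbind(i0 + 1, j0)] * (1 - fx) * fy +
    m[cbind(i0 + 1, j0 + 1)] * fx * fy
}

# Distance from points (x, y) to a polyline given as a 2-column matrix,
# plus arc-length position of the foot point. Vectorized over points.
dist_to_polyline <- function(x, y, poly) {
  stopifnot(ncol(poly) == 2, nrow(poly) >= 2)
  best <- rep(Inf, length(x))
  for (s in seq_len(nrow(poly) - 1L)) {
    ax <- poly[s, 1]; ay <- poly[s, 2]
    bx <- poly[s + 1L, 1]; by <- poly[s + 1L, 2]
    dx <- bx - ax; dy <- by - ay
    len2 <- dx * dx + dy * dy
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(pmax(((x - ax) * dx + (y - ay) * dy) / len2, 0), 1)
    d2 <- (x - (ax + t * dx))^2 + (y - (ay + t * dy))^2
    best <- pmin(best, d2)
  }
  sqrt(best)
}

# Total polyline length.
polyline_length <- function(poly) {
  d <- diff(poly)
  sum(sqrt(rowSums(d^2)))
}

# Half-sample mode: recursively take the shortest half of the sorted
# sample. Robust estimator of the modal (background) intensity of a frame
# whose signal occupies a minority of pixels.
half_sample_mode <- function(x) {
  x <- sort(x)
  while (length(x) > 3L) {
    n <- length(x)
    h <- ceiling(n / 2)
    w <- x[h:n] - x[1:(n - h + 1L)]
    i <- which.min(w)
    x <- x[i:(i + h - 1L)]
  }
  mean(x)
}

# Normalize an angular difference of ridge orientations (mod 180 deg -> pi)
# to [0, pi/2].
orient_diff <- function(a, b) {
  d <- abs(a - b) %% pi
  pmin(d, pi - d)
}
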