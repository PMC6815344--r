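# Circumferential limbal mapping: quadrant assignment on the 15-degree
# grid, inferior-vs-rest two-sample comparison, per-angle diameter tables,
# and angular cluster spans of large-calibre vessels.

#' Assign a limbal angle to a quadrant
#'
#' Angles increase counter-clockwise with 270 degrees at the inferior pole.
#' The inferior quadrant is the arc from 225 to 315 degrees with both
#' endpoints inclusive; every other angle is labelled "other". Angles
#' outside [0, 360) are normalized modulo 360 first.
#'
#' @param angle_deg numeric vector of limbal angles (degrees).
#' @return character vector of labels, "inferior" or "other".
#' @examples
#' assign_quadrant(c(225, 270, 315))   # all inferior
#' assign_quadrant(c(210, 330, 630))   # other, other, inferior (630 -> 270)
#' @export
assign_quadrant <- function(angle_deg) {
  a <- angle_deg %% 360
  ifelse(a >= 225 & a <= 315, "inferior", "other")
}

#' Compare inferior vs all other quadrants
#'
#' Two-tailed two-sample t-test on per-angle total fluorescence, inferior
#' (225-315 degrees inclusive) vs all other angles, pooling eyes. Groups are
#' assigned from \code{angle_deg} via \code{\link{assign_quadrant}}. The
#' default variant is the unequal-variance (Welch) test; a pooled-variance
#' test is available. Group summaries are reported as mean +/- SEM
#' (SD/sqrt(n)). A per-eye stratified table is included when \code{eye_id}
#' is present.
#'
#' @param samples data.frame with columns \code{angle_deg} and
#'   \code{total_au} (and optionally \code{eye_id}).
#' @param variant "welch" (default) or "pooled".
#' @param alpha significance level recorded in the result (default 0.05).
#' @return An object of class \code{quadrant_comparison}: group means, SDs,
#'   SEMs and sizes, t statistic, df, two-sided p-value, variant, alpha,
#'   the quadrant convention string, and a per-eye summary table (or NULL).
#' @examples
#' s <- data.frame(angle_deg = c(225, 270, 315, 0, 45, 90),
#'                 total_au = c(3, 4, 5, 1, 2, 3))
#' compare_inferior_vs_rest(s, variant = "pooled")
#' @export
compare_inferior_vs_rest <- function(samples,
                                     variant = c("welch", "pooled"),
                                     alpha = 0.05) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(samples),
            all(c("angle_deg", "total_au") %in% names(samples)))
  quad <- assign_quadrant(samples$angle_deg)
  inf <- samples$total_au[quad == "inferior"]
  oth <- samples$total_au[quad == "other"]
  if (length(inf) < 2L || length(oth) < 2L)
    stop("each group needs >= 2 samples (have ", length(inf),
         " inferior, ", length(oth), " other)", call. = FALSE)
  if (stats::sd(inf) == 0 && stats::sd(oth) == 0 &&
      mean(inf) == mean(oth)) {
    # degenerate but well-defined: no variability, no difference
    tt <- list(statistic = c(t = 0),
               parameter = c(df = length(inf) + length(oth) - 2),
               p.value = 1)
  } else {
    tt <- stats::t.test(inf, oth, alternative = "two.sided",
                        var.equal = (variant == "pooled"))
  }
  per_eye <- NULL
  if ("eye_id" %in% names(samples)) {
    per_eye <- do.call(rbind, lapply(split(samples, samples$eye_id),
      function(d) {
        q <- assign_quadrant(d$angle_deg)
        data.frame(eye_id = d$eye_id[1],
                   inferior_mean_au = mean(d$total_au[q == "inferior"]),
                   other_mean_au = mean(d$total_au[q == "other"]),
                   n_inferior = sum(q == "inferior"),
                   n_other = sum(q == "other"))
      }))
    rownames(per_eye) <- NULL
  }
  structure(list(
    group_means_au = c(inferior = mean(inf), other = mean(oth)),
    group_sds_au = c(inferior = stats::sd(inf), other = stats::sd(oth)),
    group_sems_au = c(inferior = stats::sd(inf) / sqrt(length(inf)),
                      other = stats::sd(oth) / sqrt(length(oth))),
    n_per_group = c(inferior = length(inf), other = length(oth)),
    t_stat = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, test_variant = variant, alpha = alpha,
    quadrant_convention = "inferior = 225-315 deg, endpoints inclusive",
    per_eye = per_eye),
    class = "quadrant_comparison")
}

#' @export
print.quadrant_comparison <- function(x, ...) {
  cat("<quadrant_comparison> inferior vs all other quadrants\n")
  cat(sprintf("  inferior: %.4g +/- %.3g au (SEM), n = %d\n",
              x$group_means_au["inferior"], x$group_sems_au["inferior"],
              x$n_per_group["inferior"]))
  cat(sprintf("  other:    %.4g +/- %.3g au (SEM), n = %d\n",
              x$group_means_au["other"], x$group_sems_au["other"],
              x$n_per_group["other"]))
  cat(sprintf("  %s t-test: t = %.4g, df = %.4g, two-sided p = %.4g%s\n",
              x$test_variant, x$t_stat, x$df, x$p_value,
              if (x$p_value < x$alpha) " (significant)" else ""))
  cat("  convention:", x$quadrant_convention, "\n")
  invisible(x)
}

#' Permutation test of a difference in group means
#'
#' Monte-Carlo permutation p-value for the two-sided test of equal means:
#' group labels are reshuffled \code{n_perm} times and the absolute
#' difference in means compared with the observed one. Serves as a
#' distribution-free cross-check of the t-test.
#'
#' @param x,y numeric vectors (the two groups).
#' @param n_perm number of label permutations.
#' @param seed RNG seed.
#' @return two-sided permutation p-value (with add-one correction).
#' @export
perm_test_means <- function(x, y, n_perm = 20000L, seed = 1L) {
  obs <- abs(mean(x) - mean(y))
  pooled <- c(x, y)
  nx <- length(x)
  with_seed(seed, {
    hits <- sum(vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(length(pooled), nx)
      abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12
    }, logical(1)))
    (hits + 1) / (n_perm + 1)
  })
}

# Parse semicolon-separated diameter strings into numeric vectors.
parse_diameters <- function(s) {
  lapply(s, function(v) {
    if (is.na(v) || !nzchar(v)) return(numeric(0))
    as.numeric(strsplit(v, ";", fixed = TRUE)[[1]])
  })
}

#' Per-angle vessel diameter summary
#'
#' Collapses per-sample diameter lists to one row per angle of the
#' 15-degree grid, reporting the maximum and median segment diameter.
#' Angles of the grid that have no sample (e.g. a failed frame) are kept as
#' rows with NA diameters and \code{missing = TRUE}.
#'
#' @param samples data.frame with \code{angle_deg} and \code{diameters_um}
#'   (semicolon-separated string per row, as written by the generator and
#'   the pipeline).
#' @param grid_deg the angle grid to report on (default 0, 15, ..., 345).
#' @return data.frame ordered by angle: angle_deg, n_vessels,
#'   max_diameter_um, median_diameter_um, missing.
#' @export
diameter_by_angle <- function(samples, grid_deg = seq(0, 345, by = 15)) {
  stopifnot(is.data.frame(samples))
  out <- lapply(grid_deg, function(a) {
    d <- samples[samples$angle_deg == a, , drop = FALSE]
    di <- unlist(parse_diameters(d$diameters_um))
    if (nrow(d) == 0L || length(di) == 0L) {
      data.frame(angle_deg = a, n_vessels = 0L,
                 max_diameter_um = NA_real_, median_diameter_um = NA_real_,
                 missing = TRUE)
    } else {
      data.frame(angle_deg = a, n_vessels = length(di),
                 max_diameter_um = max(di),
                 median_diameter_um = stats::median(di), missing = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Angular spans of large-diameter vessel clusters
#'
#' Finds maximal circular runs of consecutive grid angles whose maximum
#' vessel diameter reaches \code{high_threshold_um}. Runs wrap across the
#' 345-to-0 boundary; the span is 15 degrees times the run length. If all
#' angles qualify, a single full-circle run of span 360 is returned.
#'
#' @param per_angle table from \code{\link{diameter_by_angle}} covering the
#'   full grid.
#' @param high_threshold_um diameter threshold (um).
#' @return data.frame with start_deg, end_deg, span_deg (zero rows if no
#'   angle qualifies).
#' @examples
#' tbl <- data.frame(angle_deg = seq(0, 345, 15), max_diameter_um = 10)
#' tbl$max_diameter_um[tbl$angle_deg %in% c(45, 60, 75)] <- 40
#' cluster_span(tbl, 35)   # one run spanning 45 degrees
#' @export
cluster_span <- function(per_angle, high_threshold_um) {
  stopifnot(is.data.frame(per_angle),
            all(c("angle_deg", "max_diameter_um") %in% names(per_angle)))
  tbl <- per_angle[order(per_angle$angle_deg), ]
  ang <- tbl$angle_deg
  if (length(ang) < 2L || any(diff(ang) != 15) || ang[1] %% 15 != 0)
    stop("per_angle must cover a full 15-degree grid", call. = FALSE)
  hi <- !is.na(tbl$max_diameter_um) &
    tbl$max_diameter_um >= high_threshold_um
  n <- length(hi)
  if (!any(hi))
    return(data.frame(start_deg = numeric(0), end_deg = numeric(0),
                      span_deg = numeric(0)))
  if (all(hi))
    return(data.frame(start_deg = ang[1], end_deg = ang[n], span_deg = 360))
  # run starts: hi[i] & !hi[i-1], circularly
  prev <- c(hi[n], hi[-n])
  starts <- which(hi & !prev)
  runs <- lapply(starts, function(s) {
    len <- 1L
    while (hi[(s - 1L + len) %% n + 1L]) len <- len + 1L
    data.frame(start_deg = ang[s],
               end_deg = ang[(s - 1L + len - 1L) %% n + 1L],
               span_deg = 15 * len)
  })
  do.call(rbind, runs)
}
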