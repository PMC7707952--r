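#' Polygon area
#'
#' Area enclosed by the nucleus boundary, computed exactly from the vertex
#' list as the sum of the signed triangles spanned by consecutive vertices
#' (shoelace formula). Invariant to vertex order reversal, rotation of the
#' starting vertex, and translation.
#'
#' @param boundary A [nucleus_boundary()] (or n x 2 vertex matrix).
#' @return Area in px^2 (always positive).
#' @export
polygon_area <- function(boundary) {
  b <- as_boundary(boundary)
  abs(signed_area(b$vertices))
}

#' Polygon perimeter
#'
#' Sum of the Euclidean edge lengths of the closed boundary, including the
#' implicit closing edge.
#'
#' @inheritParams polygon_area
#' @return Length in px.
#' @export
polygon_perimeter <- function(boundary) {
  v <- as_boundary(boundary)$vertices
  j <- c(2:nrow(v), 1L)
  sum(sqrt(rowSums((v[j, , drop = FALSE] - v)^2)))
}

# Area centroid from the standard signed-triangle decomposition.
polygon_centroid <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  cr <- v[, 1] * v[j, 2] - v[j, 1] * v[, 2]
  a <- sum(cr) / 2
  c(sum((v[, 1] + v[j, 1]) * cr) / (6 * a),
    sum((v[, 2] + v[j, 2]) * cr) / (6 * a))
}

#' Caliper (Feret) diameters
#'
#' Width of the projection of the boundary onto a uniform grid of
#' directions over half a turn. Returns the maximum, minimum and mean
#' projection width; the maximum is additionally lower-bounded by the
#' exact largest inter-vertex distance, so `max_caliper` is the true Feret
#' diameter regardless of grid resolution.
#'
#' @inheritParams polygon_area
#' @param n_angles Number of equally spaced directions over \[0, pi)
#'   (default 180, i.e. 1 degree resolution; minimum 2).
#' @return Named vector `max_caliper`, `min_caliper`, `mean_caliper` (px).
#' @export
caliper_diameters <- function(boundary, n_angles = 180) {
  v <- as_boundary(boundary)$vertices
  if (n_angles < 2) stop("n_angles must be >= 2")
  th <- (seq_len(n_angles) - 1) * pi / n_angles
  proj <- v %*% rbind(cos(th), sin(th))       # n_vertices x n_angles
  widths <- apply(proj, 2, max) - apply(proj, 2, min)
  dmax <- max(stats::dist(v))
  c(max_caliper = max(max(widths), dmax),
    min_caliper = min(widths),
    mean_caliper = mean(widths))
}

# Resample the closed boundary at m points equally spaced in arc length.
resample_boundary <- function(v, m) {
  n <- nrow(v)
  vc <- rbind(v, v[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  s <- c(0, cumsum(seg))
  total <- s[n + 1]
  t_new <- seq(0, total, length.out = m + 1)[-(m + 1)]
  xi <- stats::approx(s, vc[, 1], xout = t_new)$y
  yi <- stats::approx(s, vc[, 2], xout = t_new)$y
  cbind(xi, yi)
}

#' Radial statistics of the boundary
#'
#' Distances from the polygon's area centroid to the boundary, evaluated
#' on the outline resampled at equally spaced arc-length points. For a
#' strongly non-convex outline whose centroid falls outside the polygon
#' the values are still computed and the condition is flagged.
#'
#' @inheritParams polygon_area
#' @param n_samples Number of equal arc-length sample points (>= 256).
#' @return Named vector `max_radius`, `min_radius`, `radius_ratio`, with
#'   attribute `centroid_outside` (logical).
#' @export
radial_stats <- function(boundary, n_samples = 256) {
  b <- as_boundary(boundary)
  v <- b$vertices
  n_samples <- max(256L, as.integer(n_samples))
  ctr <- polygon_centroid(v)
  pts <- resample_boundary(v, n_samples)
  r <- sqrt((pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2)
  out <- c(max_radius = max(r), min_radius = min(r),
           radius_ratio = max(r) / min(r))
  inside <- points_in_polygon(matrix(ctr, 1), v)
  attr(out, "centroid_outside") <- unname(!inside)
  out
}

#' Moments-equivalent ellipse axes
#'
#' Axes of the ellipse having the same area and second-order central area
#' moments as the polygon interior. Moments are computed exactly from the
#' vertex list (Green's-theorem polygon moment formulas), so no
#' rasterization is involved.
#'
#' @inheritParams polygon_area
#' @return Named vector `major_axis`, `minor_axis` (full lengths, px) and
#'   `aspect_ratio` = major/minor (>= 1).
#' @export
ellipse_axes <- function(boundary) {
  v <- as_boundary(boundary)$vertices
  n <- nrow(v)
  j <- c(2:n, 1L)
  x0 <- v[, 1]; y0 <- v[, 2]; x1 <- v[j, 1]; y1 <- v[j, 2]
  cr <- x0 * y1 - x1 * y0
  a <- sum(cr) / 2
  cx <- sum((x0 + x1) * cr) / (6 * a)
  cy <- sum((y0 + y1) * cr) / (6 * a)
  # second moments about the origin, then centered and normalized by area
  ixx <- sum((x0^2 + x0 * x1 + x1^2) * cr) / 12          # integral x^2 dA
  iyy <- sum((y0^2 + y0 * y1 + y1^2) * cr) / 12          # integral y^2 dA
  ixy <- sum((x0 * y1 + 2 * x0 * y0 + 2 * x1 * y1 + x1 * y0) * cr) / 24
  mxx <- ixx / a - cx^2
  myy <- iyy / a - cy^2
  mxy <- ixy / a - cx * cy
  ev <- eigen(matrix(c(mxx, mxy, mxy, myy), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  # an ellipse with semi-axes (p, q) has normalized central moments
  # p^2/4 and q^2/4 along its principal axes
  major <- 4 * sqrt(ev[1])
  minor <- 4 * sqrt(ev[2])
  if (minor <= 0) stop("degenerate polygon: zero minor moment")
  c(major_axis = major, minor_axis = minor, aspect_ratio = major / minor)
}

#' Roundness (isoperimetric shape factor)
#'
#' `4 * pi * area / perimeter^2`: 1 for a perfect circle, smaller for any
#' irregular outline.
#'
#' @param area Area in px^2 (> 0).
#' @param perimeter Perimeter in px (> 0).
#' @return Unitless roundness in (0, 1] up to floating error.
#' @export
roundness <- function(area, perimeter) {
  if (!is.finite(area) || area <= 0) stop("area must be > 0")
  if (!is.finite(perimeter) || perimeter <= 0) stop("perimeter must be > 0")
  4 * pi * area / perimeter^2
}

#' Box-counting fractal dimension of the boundary curve
#'
#' The outline is rasterized onto a fine grid (`supersample` subpixels per
#' image pixel), occupied boxes are counted at dyadic box sizes
#' 1, 2, 4, ..., 64, and the dimension is the negated least-squares slope
#' of log N(s) versus log s, clamped to \[1, 2\]. Smooth outlines give
#' values near 1; space-filling irregularity pushes the value up.
#'
#' @inheritParams polygon_area
#' @param supersample Subpixel resolution of the rasterization (default 4).
#' @return Unitless dimension in \[1, 2\].
#' @export
fractal_dimension <- function(boundary, supersample = 4) {
  v <- as_boundary(boundary)$vertices
  g <- v * supersample
  g[, 1] <- g[, 1] - min(g[, 1])
  g[, 2] <- g[, 2] - min(g[, 2])
  # dense sampling along each edge at half-cell steps
  vc <- rbind(g, g[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(vc)^2))
  pts <- lapply(seq_len(nrow(g)), function(i) {
    k <- max(2L, ceiling(seg[i] / 0.5) + 1L)
    t <- seq(0, 1, length.out = k)
    cbind(vc[i, 1] + t * (vc[i + 1, 1] - vc[i, 1]),
          vc[i, 2] + t * (vc[i + 1, 2] - vc[i, 2]))
  })
  p <- do.call(rbind, pts)
  cellx <- floor(p[, 1]); celly <- floor(p[, 2])
  sizes <- 2^(0:6)
  counts <- vapply(sizes, function(s) {
    length(unique(floor(cellx / s) + 1i * floor(celly / s)))
  }, numeric(1))
  keep <- counts > 0
  fit <- stats::lm.fit(cbind(1, log(sizes[keep])), log(counts[keep]))
  min(2, max(1, -fit$coefficients[2]))
}
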