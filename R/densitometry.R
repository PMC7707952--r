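#' Image patch container
#'
#' An RGB cytology image region with 8-bit channel intensities, optionally
#' paired with a blank-field image of the same size for flat-field
#' correction.
#'
#' @param pixels H x W x 3 numeric array of intensities in \[0, 255\].
#' @param blank_field Optional H x W x 3 array of identical dimensions.
#' @return An `image_patch` object.
#' @export
image_patch <- function(pixels, blank_field = NULL) {
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    stop("pixels must be an H x W x 3 array")
  }
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("intensities must lie in [0, 255]")
  }
  if (!is.null(blank_field) && !identical(dim(blank_field), dim(pixels))) {
    stop("blank_field dimensions must match pixels")
  }
  structure(list(pixels = pixels, blank_field = blank_field),
            class = "image_patch")
}

#' @export
print.image_patch <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_patch: %d x %d RGB%s>\n", d[2], d[1],
              if (is.null(x$blank_field)) "" else ", with blank field"))
  invisible(x)
}

#' Read an RGB image (PNG or TIFF) as an image patch
#'
#' @param path Image file; format chosen by extension.
#' @param blank_field_path Optional blank-field image of the same size.
#' @return An [image_patch()] with intensities on the 0-255 scale.
#' @export
read_image_patch <- function(path, blank_field_path = NULL) {
  read1 <- function(p) {
    ext <- tolower(tools::file_ext(p))
    a <- switch(ext,
                png = png::readPNG(p),
                tif = , tiff = tiff::readTIFF(p),
                stop("unsupported image format: ", ext))
    if (length(dim(a)) == 2) a <- array(rep(a, 3), c(dim(a), 3))
    if (dim(a)[3] > 3) a <- a[, , 1:3, drop = FALSE]
    round(a * 255)
  }
  blank <- if (!is.null(blank_field_path)) read1(blank_field_path)
  image_patch(read1(path), blank)
}

#' Write an image patch to PNG
#'
#' @param patch An [image_patch()].
#' @param path Output PNG path.
#' @export
write_image_patch <- function(patch, path) {
  png::writePNG(patch$pixels / 255, path)
  invisible(path)
}

# Boundary-inclusive point-in-polygon (crossing number, vectorized over
# points). Points within `edge_tol` of an edge count as inside, which
# fixes the ray-casting ambiguity for pixel centers lying exactly on the
# outline.
points_in_polygon <- function(pts, v, edge_tol = 1e-9) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    x0 <- v[i, 1]; y0 <- v[i, 2]; x1 <- v[j[i], 1]; y1 <- v[j[i], 2]
    crosses <- ((y0 > py) != (y1 > py)) &
      (px < (x1 - x0) * (py - y0) / (y1 - y0) + x0)
    inside <- xor(inside, crosses)
  }
  inside | (point_polygon_distance(pts, v) <= edge_tol)
}

# Minimum distance from each point to the polygon outline (edges).
point_polygon_distance <- function(pts, v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(n)) {
    ax <- v[i, 1]; ay <- v[i, 2]
    bx <- v[j[i], 1] - ax; by <- v[j[i], 2] - ay
    len2 <- bx^2 + by^2
    t <- if (len2 == 0) 0 else
      pmin(1, pmax(0, ((pts[, 1] - ax) * bx + (pts[, 2] - ay) * by) / len2))
    d2 <- pmin(d2, (pts[, 1] - (ax + t * bx))^2 +
                   (pts[, 2] - (ay + t * by))^2)
  }
  sqrt(d2)
}

# Pixel-center mask of a polygon within an image of given dimensions.
# Returns an index matrix (x, y) of 0-based pixel centers inside the
# boundary (boundary-inclusive).
polygon_pixel_mask <- function(v, dim_hw) {
  xr <- floor(min(v[, 1])):ceiling(max(v[, 1]))
  yr <- floor(min(v[, 2])):ceiling(max(v[, 2]))
  xr <- xr[xr >= 0 & xr <= dim_hw[2] - 1]
  yr <- yr[yr >= 0 & yr <= dim_hw[1] - 1]
  if (!length(xr) || !length(yr)) return(matrix(numeric(0), 0, 2))
  grid <- cbind(rep(xr, times = length(yr)), rep(yr, each = length(xr)))
  grid[points_in_polygon(grid, v), , drop = FALSE]
}

#' Flat-field (background) correction
#'
#' Divides out the illumination pattern captured in a blank-field image:
#' per channel, `corrected = raw * mean(blank) / blank`, clipped to
#' \[0, 255\] and rounded. A uniform blank field leaves the image
#' unchanged; blank pixels of 0 are treated as 1 to avoid division by
#' zero. Without a blank field the patch is returned unchanged with a
#' warning.
#'
#' @param patch An [image_patch()] with `blank_field` set.
#' @return A corrected [image_patch()] (blank field dropped).
#' @export
background_correct <- function(patch) {
  if (is.null(patch$blank_field)) {
    warning("no blank field supplied; returning patch unchanged")
    return(patch)
  }
  px <- patch$pixels
  bl <- pmax(patch$blank_field, 1)
  out <- px
  for (ch in 1:3) {
    out[, , ch] <- round(pmin(255, pmax(0,
      px[, , ch] * mean(bl[, , ch]) / bl[, , ch])))
  }
  image_patch(out)
}

# Per-pixel BT.601 luminance of an H x W x 3 intensity array.
luminance <- function(pixels) {
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Optical density over the nucleus mask
#'
#' The mask is the set of pixels whose centers fall inside the boundary
#' polygon (boundary-inclusive). For each masked pixel the luminance
#' L = 0.299 R + 0.587 G + 0.114 B is converted to optical density
#' `OD = -log10((L + 1) / (I0 + 1))`, clipped at 0 from below. The
#' incident intensity I0 defaults to 255 (white background) or, when the
#' patch carries a blank field, to its mean luminance.
#'
#' @param patch An [image_patch()].
#' @param boundary A [nucleus_boundary()] lying within the patch.
#' @param i0 Incident intensity; `NULL` picks the default above.
#' @return A list: `od` (vector over mask pixels), `mask` (m x 2 matrix
#'   of 0-based x, y pixel centers), `i0`.
#' @export
optical_density_map <- function(patch, boundary, i0 = NULL) {
  b <- as_boundary(boundary)
  v <- b$vertices
  dims <- dim(patch$pixels)
  if (min(v[, 1]) < -0.5 || min(v[, 2]) < -0.5 ||
      max(v[, 1]) > dims[2] - 0.5 || max(v[, 2]) > dims[1] - 0.5) {
    stop("boundary extends outside the image patch")
  }
  mask <- polygon_pixel_mask(v, dims)
  if (nrow(mask) == 0) stop("empty mask: polygon smaller than one pixel")
  if (is.null(i0)) {
    i0 <- if (is.null(patch$blank_field)) 255 else
      mean(luminance(patch$blank_field))
  }
  lum <- luminance(patch$pixels)
  l <- lum[cbind(mask[, 2] + 1L, mask[, 1] + 1L)]
  od <- pmax(0, -log10((l + 1) / (i0 + 1)))
  list(od = od, mask = mask, i0 = i0)
}

#' Densitometric nuclear features
#'
#' Stain-uptake descriptors over the nucleus mask: integrated optical
#' density (IOD), per-channel mean intensities, OD summary statistics
#' (population SD), margination (fraction of IOD concentrated in the
#' peripheral band of pixels within 10% of the equivalent-circle radius
#' of the boundary) and heterogeneity (fraction of pixels whose OD
#' deviates from the mean by more than one SD).
#'
#' @inheritParams optical_density_map
#' @return Named vector: `iod`, `mean_red`, `mean_green`, `mean_blue`,
#'   `mean_od`, `max_od`, `min_od`, `sd_od`, `margination`,
#'   `heterogeneity`.
#' @export
densitometric_features <- function(patch, boundary, i0 = NULL) {
  b <- as_boundary(boundary)
  v <- b$vertices
  odm <- optical_density_map(patch, b, i0 = i0)
  od <- odm$od
  mask <- odm$mask
  idx <- cbind(mask[, 2] + 1L, mask[, 1] + 1L)
  mean_rgb <- vapply(1:3, function(ch) {
    mean(patch$pixels[, , ch][idx])
  }, numeric(1))
  n <- length(od)
  m_od <- mean(od)
  sd_od <- sqrt(sum((od - m_od)^2) / n)          # population denominator
  iod <- sum(od)
  r_eq <- sqrt(polygon_area(b) / pi)
  band <- point_polygon_distance(mask, v) <= 0.1 * r_eq
  margination <- if (iod > 0) sum(od[band]) / iod else 0
  heterogeneity <- if (sd_od > 0) mean(abs(od - m_od) > sd_od) else 0
  c(iod = iod, mean_red = mean_rgb[1], mean_green = mean_rgb[2],
    mean_blue = mean_rgb[3], mean_od = m_od, max_od = max(od),
    min_od = min(od), sd_od = sd_od, margination = margination,
    heterogeneity = heterogeneity)
}
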