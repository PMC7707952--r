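# geometric fixtures built in code

regular_polygon <- function(n, r = 1, cx = 0, cy = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  nucleus_boundary(cx + r * cos(t), cy + r * sin(t))
}

ellipse_polygon <- function(a, b, n = 256, cx = 0, cy = 0, rot = 0) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(t); y <- b * sin(t)
  nucleus_boundary(cx + x * cos(rot) - y * sin(rot),
                   cy + x * sin(rot) + y * cos(rot))
}

# simple (star-shaped) polygon: sorted angles, random radii
random_star_polygon <- function(n, rmin = 0.5, rmax = 2) {
  th <- sort(stats::runif(n, 0, 2 * pi))
  r <- stats::runif(n, rmin, rmax)
  nucleus_boundary(r * cos(th), r * sin(th))
}

# convex polygon: hull of random points
random_convex_polygon <- function(n_points = 20) {
  x <- stats::runif(n_points); y <- stats::runif(n_points)
  h <- grDevices::chull(x, y)
  nucleus_boundary(x[h], y[h])
}

# Koch snowflake boundary at a given iteration depth
koch_snowflake <- function(iter = 4, scale = 300) {
  p <- scale * rbind(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  pts <- rbind(p, p[1, ])
  for (i in seq_len(iter)) {
    out <- NULL
    for (e in seq_len(nrow(pts) - 1)) {
      a <- pts[e, ]; b <- pts[e + 1, ]
      d <- (b - a) / 3
      m1 <- a + d
      m2 <- a + 2 * d
      # outward apex: rotate the middle third by -60 degrees (outline
      # wound counterclockwise in standard axes)
      apex <- m1 + c(d[1] * cos(-pi / 3) - d[2] * sin(-pi / 3),
                     d[1] * sin(-pi / 3) + d[2] * cos(-pi / 3))
      out <- rbind(out, a, m1, apex, m2)
    }
    pts <- rbind(out, pts[nrow(pts), ])
  }
  nucleus_boundary(pts[-nrow(pts), 1], pts[-nrow(pts), 2], check = FALSE)
}

# uniform gray patch helper: all channels at the given level
gray_patch <- function(h, w, level, blank = NULL) {
  image_patch(array(level, c(h, w, 3)), blank)
}
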