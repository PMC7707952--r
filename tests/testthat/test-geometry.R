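test_that("polygon area matches closed forms and is orientation/rigid invariant", {
  sq <- nucleus_boundary(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_area(sq), 1.0)
  rev_sq <- nucleus_boundary(c(0, 1, 1, 0)[4:1], c(0, 0, 1, 1)[4:1])
  expect_equal(polygon_area(rev_sq), 1.0)

  set.seed(7)
  for (i in 1:20) {
    p <- random_star_polygon(12)
    v <- p$vertices
    a0 <- polygon_area(p)
    # translation, starting-vertex rotation, uniform scaling
    shift <- nucleus_boundary(v[, 1] + 13.7, v[, 2] - 2.4)
    cyc <- nucleus_boundary(v[c(5:12, 1:4), 1], v[c(5:12, 1:4), 2])
    s <- 3.25
    scaled <- nucleus_boundary(s * v[, 1], s * v[, 2])
    expect_equal(polygon_area(shift), a0, tolerance = 1e-9)
    expect_equal(polygon_area(cyc), a0, tolerance = 1e-9)
    expect_equal(polygon_area(scaled), s^2 * a0, tolerance = 1e-9)
    cal0 <- caliper_diameters(p, 36)
    expect_equal(unname(caliper_diameters(scaled, 36)), s * unname(cal0),
                 tolerance = 1e-9)
  }
})

test_that("polygon area agrees with an independent fine-grid rasterization", {
  set.seed(11)
  p <- random_star_polygon(12, rmin = 0.8, rmax = 2)
  v <- p$vertices
  # pixel-count oracle at 100x supersampling, point-in-polygon from mgcv
  step <- 0.01
  gx <- seq(min(v[, 1]) - step, max(v[, 1]) + step, by = step)
  gy <- seq(min(v[, 2]) - step, max(v[, 2]) + step, by = step)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  inside <- mgcv::in.out(rbind(v, v[1, ]), grid)
  expect_equal(polygon_area(p), sum(inside) * step^2, tolerance = 0.005)
})

test_that("degenerate polygons are rejected", {
  expect_error(nucleus_boundary(c(0, 1), c(0, 1)), "3 vertices")
  expect_error(nucleus_boundary(c(0, 1, 2), c(0, 1, 2)), "zero area")
  th <- pi / 2 + 2 * pi * c(0, 2, 4, 1, 3) / 5   # pentagram
  expect_error(nucleus_boundary(cos(th), sin(th)), "self-intersect")
})

test_that("perimeter matches closed forms and an explicit edge-sum oracle", {
  sq <- nucleus_boundary(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(polygon_perimeter(sq), 4.0)
  expect_equal(polygon_perimeter(regular_polygon(256, r = 1)), 2 * pi,
               tolerance = 1e-3)
  set.seed(3)
  p <- random_star_polygon(12)
  v <- rbind(p$vertices, p$vertices[1, ])
  oracle <- sum(vapply(seq_len(nrow(v) - 1), function(i) {
    sqrt(sum((v[i + 1, ] - v[i, ])^2))
  }, numeric(1)))
  expect_equal(polygon_perimeter(p), oracle, tolerance = 1e-12)
})

test_that("caliper diameters match known shapes and the pairwise bound", {
  sq <- nucleus_boundary(c(0, 1, 1, 0), c(0, 0, 1, 1))
  # at angles {0, 90} both projection widths are 1, but the maximum
  # caliper is bounded below by the exact diagonal
  cal2 <- caliper_diameters(sq, n_angles = 2)
  expect_equal(unname(cal2), c(sqrt(2), 1, 1))

  rect <- nucleus_boundary(c(0, 4, 4, 0), c(0, 0, 2, 2))
  cal <- caliper_diameters(rect, 180)
  expect_equal(unname(cal["max_caliper"]), sqrt(20), tolerance = 1e-3)
  expect_equal(unname(cal["min_caliper"]), 2, tolerance = 1e-3)

  set.seed(5)
  for (i in 1:25) {
    p <- random_convex_polygon(10)
    brute <- max(dist(p$vertices))
    expect_equal(unname(caliper_diameters(p)["max_caliper"]), brute,
                 tolerance = 1e-9)
  }
})

test_that("radial statistics match circle, rectangle and a dense oracle", {
  circ <- regular_polygon(256, r = 10)
  rs <- radial_stats(circ)
  expect_equal(unname(rs), c(10, 10, 1), tolerance = 0.005,
               ignore_attr = TRUE)
  expect_false(attr(rs, "centroid_outside"))

  rect <- nucleus_boundary(c(0, 4, 4, 0), c(0, 0, 2, 2))
  rr <- radial_stats(rect)
  expect_equal(unname(rr["max_radius"]), sqrt(5), tolerance = 0.02)
  expect_equal(unname(rr["min_radius"]), 1, tolerance = 0.02)

  set.seed(9)
  p <- random_star_polygon(16, rmin = 1, rmax = 3)
  # dense 10,000-point oracle: interpolate each edge directly
  v <- rbind(p$vertices, p$vertices[1, ])
  seg <- sqrt(rowSums(diff(v)^2))
  tpts <- do.call(rbind, lapply(seq_len(nrow(v) - 1), function(i) {
    k <- max(2, ceiling(10000 * seg[i] / sum(seg)))
    tt <- seq(0, 1, length.out = k)
    cbind(v[i, 1] + tt * (v[i + 1, 1] - v[i, 1]),
          v[i, 2] + tt * (v[i + 1, 2] - v[i, 2]))
  }))
  ctr <- cytodx:::polygon_centroid(p$vertices)
  rad <- sqrt((tpts[, 1] - ctr[1])^2 + (tpts[, 2] - ctr[2])^2)
  rp <- radial_stats(p, n_samples = 4096)
  expect_equal(unname(rp["max_radius"]), max(rad), tolerance = 0.01)
  expect_equal(unname(rp["min_radius"]), min(rad), tolerance = 0.01)
})

test_that("moment-ellipse axes recover true ellipses and match a raster oracle", {
  el <- ellipse_polygon(20, 10, rot = 0.4)
  ax <- ellipse_axes(el)
  expect_equal(unname(ax), c(40, 20, 2), tolerance = 0.01)
  sq <- nucleus_boundary(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(unname(ellipse_axes(sq)["aspect_ratio"]), 1, tolerance = 1e-9)

  set.seed(13)
  p <- random_star_polygon(12, rmin = 1, rmax = 2.5)
  v <- p$vertices
  step <- 0.02
  gx <- seq(min(v[, 1]), max(v[, 1]), by = step)
  gy <- seq(min(v[, 2]), max(v[, 2]), by = step)
  grid <- cbind(rep(gx, times = length(gy)), rep(gy, each = length(gx)))
  pts <- grid[mgcv::in.out(rbind(v, v[1, ]), grid), ]
  cov_px <- stats::cov(pts) * (nrow(pts) - 1) / nrow(pts)
  ev <- eigen(cov_px, symmetric = TRUE)$values
  expect_equal(unname(ellipse_axes(p)[c("major_axis", "minor_axis")]),
               4 * sqrt(ev), tolerance = 0.01)
})

test_that("roundness follows the isoperimetric closed forms", {
  expect_equal(roundness(pi, 2 * pi), 1.0)
  sq <- nucleus_boundary(c(0, 1, 1, 0), c(0, 0, 1, 1))
  expect_equal(roundness(polygon_area(sq), polygon_perimeter(sq)), pi / 4)
  expect_equal(roundness(8, 12), 4 * pi * 8 / 144)
  expect_error(roundness(0, 1), "area")
  expect_error(roundness(1, -1), "perimeter")

  set.seed(17)
  for (i in 1:50) {
    p <- random_convex_polygon(15)
    expect_lte(roundness(polygon_area(p), polygon_perimeter(p)), 1 + 1e-9)
  }
})

test_that("box-counting dimension is ~1 for smooth outlines and ~log4/log3 for the Koch curve", {
  # fixture sizes keep the dyadic box range inside each curve's scaling
  # regime: smaller than the rectangle separation, larger than the Koch
  # generator segment
  rect <- nucleus_boundary(c(0, 200, 200, 0), c(0, 0, 30, 30))
  expect_equal(fractal_dimension(rect), 1, tolerance = 0.1)
  expect_equal(fractal_dimension(regular_polygon(256, r = 50)), 1,
               tolerance = 0.1)
  koch <- koch_snowflake(iter = 4, scale = 40)
  expect_equal(fractal_dimension(koch), log(4) / log(3), tolerance = 0.1)
})
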