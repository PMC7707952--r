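#' Nucleus boundary polygon
#'
#' A nucleus outline delineated on a digitized cytology image, stored as a
#' closed polygon in continuous pixel coordinates (0-based, x rightward,
#' y downward; the last vertex connects implicitly back to the first).
#'
#' @param x,y Numeric vectors of vertex coordinates (equal length, >= 3).
#' @param check Validate the polygon (default `TRUE`). Validation rejects
#'   fewer than three vertices, zero signed area (collinear vertices) and
#'   self-intersecting outlines.
#' @return An object of class `nucleus_boundary`: a list with a `vertices`
#'   matrix (n x 2, columns `x`, `y`).
#' @export
nucleus_boundary <- function(x, y, check = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  v <- cbind(x = as.numeric(x), y = as.numeric(y))
  # drop a duplicated closing vertex so the closure stays implicit
  n <- nrow(v)
  if (n >= 2 && all(v[1, ] == v[n, ])) v <- v[-n, , drop = FALSE]
  b <- structure(list(vertices = v), class = "nucleus_boundary")
  if (check) validate_boundary(b)
  b
}

#' @export
print.nucleus_boundary <- function(x, ...) {
  cat(sprintf("<nucleus_boundary: %d vertices, area %.2f px^2>\n",
              nrow(x$vertices), polygon_area(x)))
  invisible(x)
}

as_boundary <- function(boundary) {
  if (inherits(boundary, "nucleus_boundary")) return(boundary)
  if (is.matrix(boundary) && ncol(boundary) == 2) {
    return(nucleus_boundary(boundary[, 1], boundary[, 2]))
  }
  stop("boundary must be a nucleus_boundary or an n x 2 matrix")
}

signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1] * v[j, 2] - v[j, 1] * v[, 2]) / 2
}

validate_boundary <- function(b) {
  v <- b$vertices
  if (nrow(v) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (any(!is.finite(v))) stop("boundary vertices must be finite")
  a <- signed_area(v)
  scale2 <- max(1, max(abs(v))^2)
  if (abs(a) < 1e-12 * scale2) {
    stop("degenerate polygon: zero area (collinear vertices)")
  }
  if (polygon_self_intersects(v)) stop("boundary polygon self-intersects")
  invisible(b)
}

# Proper-crossing test between all non-adjacent edge pairs (O(n^2),
# vectorized). Shared endpoints between adjacent edges are not crossings.
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  p1 <- v
  p2 <- v[j, , drop = FALSE]
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  a <- idx[, 1]; b <- idx[, 2]
  adjacent <- (b - a == 1L) | (a == 1L & b == n)
  a <- a[!adjacent]; b <- b[!adjacent]
  if (!length(a)) return(FALSE)
  d1 <- cross2(p2[a, ] - p1[a, ], p1[b, ] - p1[a, ])
  d2 <- cross2(p2[a, ] - p1[a, ], p2[b, ] - p1[a, ])
  d3 <- cross2(p2[b, ] - p1[b, ], p1[a, ] - p1[b, ])
  d4 <- cross2(p2[b, ] - p1[b, ], p2[a, ] - p1[b, ])
  any(d1 * d2 < 0 & d3 * d4 < 0)
}

cross2 <- function(u, w) u[, 1] * w[, 2] - u[, 2] * w[, 1]

#' Read nucleus boundaries from a vertex CSV
#'
#' The file holds one row per vertex with columns `structure_id`,
#' `case_id`, `vertex_index`, `x`, `y`; one file may hold many structures.
#'
#' @param path CSV file path.
#' @return A named list of `nucleus_boundary` objects (names are structure
#'   ids) with a `case_id` attribute vector alongside each boundary.
#' @export
read_boundaries <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("structure_id", "case_id", "vertex_index", "x", "y")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("boundary CSV missing columns: ",
                         paste(miss, collapse = ", "))
  out <- lapply(split(d, d$structure_id), function(s) {
    s <- s[order(s$vertex_index), ]
    b <- nucleus_boundary(s$x, s$y)
    attr(b, "case_id") <- s$case_id[1]
    b
  })
  out[unique(as.character(d$structure_id))]
}

#' Write nucleus boundaries to a vertex CSV
#'
#' @param boundaries Named list of `nucleus_boundary` objects.
#' @param path Output CSV path.
#' @param case_ids Optional case id per boundary; defaults to the
#'   `case_id` attribute or `NA`.
#' @export
write_boundaries <- function(boundaries, path, case_ids = NULL) {
  if (is.null(names(boundaries))) {
    names(boundaries) <- seq_along(boundaries)
  }
  rows <- lapply(seq_along(boundaries), function(i) {
    b <- boundaries[[i]]
    cid <- if (!is.null(case_ids)) case_ids[[i]] else {
      ca <- attr(b, "case_id"); if (is.null(ca)) NA else ca
    }
    v <- b$vertices
    data.frame(structure_id = names(boundaries)[i], case_id = cid,
               vertex_index = seq_len(nrow(v)) - 1L,
               x = v[, 1], y = v[, 2])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
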