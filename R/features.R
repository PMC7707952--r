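#' Names of the 23 nuclear morphometry features, in canonical order
#'
#' Thirteen geometric descriptors followed by ten densitometric ones.
#' This ordering is used for every feature table the package reads or
#' writes.
#' @export
cytodx_features <- c(
  "area", "major_axis", "minor_axis", "aspect_ratio",
  "max_caliper", "min_caliper", "mean_caliper",
  "max_radius", "min_radius", "radius_ratio",
  "perimeter", "roundness", "fractal_dimension",
  "iod", "mean_red", "mean_green", "mean_blue",
  "mean_od", "max_od", "min_od", "sd_od",
  "margination", "heterogeneity")

#' Extract the full nuclear feature vector
#'
#' Computes all 23 geometric and densitometric measurements for one
#' delineated structure: area, moments-ellipse axes and aspect ratio,
#' caliper (Feret) diameters, centroid-to-boundary radii, perimeter,
#' roundness, box-counting fractal dimension, then the optical-density
#' panel of [densitometric_features()]. Deterministic for fixed input.
#'
#' @param patch An [image_patch()].
#' @param boundary A [nucleus_boundary()] within the patch.
#' @param n_angles Caliper direction count (default 180).
#' @param i0 Incident intensity override for optical density.
#' @return Named numeric vector of length 23 in [cytodx_features] order,
#'   with attribute `centroid_outside`.
#' @export
extract_features <- function(patch, boundary, n_angles = 180, i0 = NULL) {
  b <- as_boundary(boundary)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("feature '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  area <- step("area", polygon_area(b))
  perim <- step("perimeter", polygon_perimeter(b))
  ax <- step("ellipse_axes", ellipse_axes(b))
  cal <- step("caliper", caliper_diameters(b, n_angles))
  rad <- step("radial", radial_stats(b))
  rnd <- step("roundness", roundness(area, perim))
  fd <- step("fractal_dimension", fractal_dimension(b))
  dens <- step("densitometry", densitometric_features(patch, b, i0 = i0))
  out <- c(area = area, ax[c("major_axis", "minor_axis", "aspect_ratio")],
           cal, rad[c("max_radius", "min_radius", "radius_ratio")],
           perimeter = perim, roundness = rnd, fractal_dimension = fd,
           dens)
  out <- out[cytodx_features]
  attr(out, "centroid_outside") <- attr(rad, "centroid_outside")
  out
}

#' Extract a feature table from boundary files and images
#'
#' Batch version of [extract_features()]: every structure in the boundary
#' CSV is measured on its image, and structures that fail validation are
#' skipped with a logged message rather than aborting the run.
#'
#' @param boundaries Named list from [read_boundaries()] (or a CSV path).
#' @param patches A single [image_patch()] shared by all structures, or a
#'   named list of patches keyed by structure id.
#' @param labels Optional named vector of class labels per structure id.
#' @return A data.frame with `case_id`, `structure_id`, `label`, then the
#'   23 feature columns; attribute `n_skipped` records failures.
#' @export
extract_feature_table <- function(boundaries, patches, labels = NULL) {
  if (is.character(boundaries)) boundaries <- read_boundaries(boundaries)
  ids <- names(boundaries)
  rows <- vector("list", length(ids))
  skipped <- 0L
  for (i in seq_along(ids)) {
    id <- ids[i]
    patch <- if (inherits(patches, "image_patch")) patches else
      patches[[id]]
    fv <- tryCatch(extract_features(patch, boundaries[[id]]),
                   error = function(e) {
                     message(sprintf("skipping structure %s: %s", id,
                                     conditionMessage(e)))
                     NULL
                   })
    if (is.null(fv)) { skipped <- skipped + 1L; next }
    cid <- attr(boundaries[[id]], "case_id")
    lab <- if (!is.null(labels) && id %in% names(labels)) labels[[id]]
           else NA_character_
    rows[[i]] <- data.frame(case_id = if (is.null(cid)) NA else cid,
                            structure_id = id, label = lab,
                            as.list(fv), check.names = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no structure produced a valid feature vector")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

#' Write / read a feature table CSV
#'
#' Columns: `case_id`, `structure_id`, `label`, then the 23 features in
#' [cytodx_features] order.
#' @param table Feature data.frame.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(cytodx_features, names(d))
  if (length(miss)) stop("feature table missing columns: ",
                         paste(miss, collapse = ", "))
  d
}
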