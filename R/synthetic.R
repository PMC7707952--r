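#' Cohort generator configuration
#'
#' Defaults describe a thyroid FNA morphometry cohort of the size and
#' composition typical of a single-center study: 447 patients, 64.4%
#' histologically benign, about 92 measured structures per slide
#' (negative-binomially dispersed), and class mixing within cases —
#' benign slides contain the occasional malignant-looking structure and
#' malignant slides a substantial benign-looking fraction (follicular
#' cells, histiocytes and colloid accompany tumor cells on real slides).
#'
#' @param n_cases Number of patients (default 447).
#' @param benign_case_fraction Fraction of histologically benign cases
#'   (default 0.644).
#' @param nuclei_mean Mean structures per case (default 92).
#' @param nuclei_dispersion Negative-binomial size parameter (default 8).
#' @param contamination_benign Fraction of malignant-distributed
#'   structures inside benign cases (default 0.01).
#' @param contamination_malignant Fraction of benign-distributed
#'   structures inside malignant cases (default 0.20).
#' @param feature_effect Named per-feature benign-to-malignant mean shift
#'   in SD units; default 1.5 on `area`, `iod`, `sd_od` and 0.5 on every
#'   other feature. A scalar is recycled over all 23 features.
#' @param seed Integer seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_cases = 447, benign_case_fraction = 0.644,
                          nuclei_mean = 92, nuclei_dispersion = 8,
                          contamination_benign = 0.01,
                          contamination_malignant = 0.20,
                          feature_effect = NULL, seed = 1) {
  if (is.null(feature_effect)) {
    feature_effect <- stats::setNames(rep(0.5, length(cytodx_features)),
                                      cytodx_features)
    feature_effect[c("area", "iod", "sd_od")] <- 1.5
  } else if (length(feature_effect) == 1 && is.null(names(feature_effect))) {
    feature_effect <- stats::setNames(rep(feature_effect,
                                          length(cytodx_features)),
                                      cytodx_features)
  }
  cfg <- list(n_cases = as.integer(n_cases),
              benign_case_fraction = benign_case_fraction,
              nuclei_mean = nuclei_mean,
              nuclei_dispersion = nuclei_dispersion,
              contamination_benign = contamination_benign,
              contamination_malignant = contamination_malignant,
              feature_effect = feature_effect, seed = as.integer(seed))
  bad <- character(0)
  if (cfg$n_cases < 2) bad <- c(bad, "n_cases")
  fr <- c("benign_case_fraction", "contamination_benign",
          "contamination_malignant")
  for (f in fr) if (cfg[[f]] < 0 || cfg[[f]] > 1) bad <- c(bad, f)
  if (cfg$nuclei_mean < 1) bad <- c(bad, "nuclei_mean")
  if (cfg$nuclei_dispersion <= 0) bad <- c(bad, "nuclei_dispersion")
  if (!all(cytodx_features %in% names(cfg$feature_effect))) {
    bad <- c(bad, "feature_effect")
  }
  if (length(bad)) stop("invalid cohort config field(s): ",
                        paste(bad, collapse = ", "))
  structure(cfg, class = "cohort_config")
}

# features whose latent draws share a mild positive correlation (size)
size_features <- c("area", "major_axis", "minor_axis", "max_caliper",
                   "min_caliper", "mean_caliper", "max_radius",
                   "min_radius", "perimeter")

benign_subtypes <- c("goiter", "nodular hyperplasia-hyperplastic nodule",
                     "adenomatous nodule", "Hashimoto thyroiditis",
                     "follicular adenoma", "thyroiditis-nonspecific",
                     "oxyphilic adenoma", "nodular hyperplasia")
benign_subtype_w <- c(186, 37, 24, 24, 5, 5, 4, 3)
malignant_subtypes <- c("papillary Ca", "medullary Ca", "follicular Ca",
                        "anaplastic Ca")
malignant_subtype_w <- c(126, 20, 10, 3)

# map latent standard-normal draws to plausible feature scales; every
# map is monotone so class separation in the latents survives
latent_to_features <- function(z) {
  f <- data.frame(
    area = pmax(1, 400 + 100 * z[, "area"]),
    major_axis = pmax(0.5, 26 + 4 * z[, "major_axis"]),
    minor_axis = pmax(0.5, 20 + 3 * z[, "minor_axis"]),
    aspect_ratio = 1 + 0.25 * exp(0.25 * z[, "aspect_ratio"]),
    max_caliper = pmax(0.5, 28 + 4 * z[, "max_caliper"]),
    min_caliper = pmax(0.5, 19 + 3 * z[, "min_caliper"]),
    mean_caliper = pmax(0.5, 23 + 3.5 * z[, "mean_caliper"]),
    max_radius = pmax(0.25, 14 + 2 * z[, "max_radius"]),
    min_radius = pmax(0.25, 10 + 1.5 * z[, "min_radius"]),
    radius_ratio = NA_real_,
    perimeter = pmax(1, 75 + 12 * z[, "perimeter"]),
    roundness = stats::plogis(1.5 - 0.5 * z[, "roundness"]),
    fractal_dimension = 1 + 0.3 * stats::plogis(z[, "fractal_dimension"]),
    iod = pmax(0.1, 120 + 40 * z[, "iod"]),
    mean_red = pmin(255, pmax(0, 150 - 15 * z[, "mean_red"])),
    mean_green = pmin(255, pmax(0, 120 - 15 * z[, "mean_green"])),
    mean_blue = pmin(255, pmax(0, 160 - 12 * z[, "mean_blue"])),
    mean_od = pmax(0.005, 0.30 + 0.06 * z[, "mean_od"]),
    max_od = pmax(0.01, 0.60 + 0.08 * z[, "max_od"]),
    min_od = pmax(0, 0.05 + 0.02 * z[, "min_od"]),
    sd_od = pmax(0.001, 0.10 + 0.03 * z[, "sd_od"]),
    margination = stats::plogis(-1 + 0.4 * z[, "margination"]),
    heterogeneity = stats::plogis(-0.8 + 0.4 * z[, "heterogeneity"]))
  # enforce the ordering contracts by sorting the relevant tuples
  cal <- t(apply(f[, c("min_caliper", "mean_caliper", "max_caliper")],
                 1, sort))
  f$min_caliper <- cal[, 1]; f$mean_caliper <- cal[, 2]
  f$max_caliper <- cal[, 3]
  rad <- t(apply(f[, c("min_radius", "max_radius")], 1, sort))
  f$min_radius <- rad[, 1]; f$max_radius <- rad[, 2]
  f$radius_ratio <- f$max_radius / f$min_radius
  ax <- t(apply(f[, c("minor_axis", "major_axis")], 1, sort))
  f$minor_axis <- ax[, 1]; f$major_axis <- ax[, 2]
  f$aspect_ratio <- f$major_axis / f$minor_axis
  od <- t(apply(f[, c("min_od", "mean_od", "max_od")], 1, sort))
  f$min_od <- od[, 1]; f$mean_od <- od[, 2]; f$max_od <- od[, 3]
  f[, cytodx_features]
}

#' Simulate a thyroid cytology cohort
#'
#' Draws case labels, per-case structure counts and per-structure
#' morphometric features from the generative model of [cohort_config()].
#' Each structure has a latent class (its own benign/malignant feature
#' distribution, possibly differing from the case histology through
#' contamination); features are class-conditional multivariate normal
#' latents (unit SD, mild 0.3 correlation among size features, configured
#' mean shifts) mapped monotonically onto valid feature ranges. The
#' `label` column used for classifier training is the case histology, as
#' only the histological diagnosis is observable for real slides; the
#' latent class is retained for oracle evaluation.
#'
#' @param config A [cohort_config()].
#' @return A `cohort`: list with `cases` (case_id, histology, subtype)
#'   and `structures` (case_id, structure_id, label, latent_class, 23
#'   feature columns). Pure function of the config (and its seed).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config,
                                                            config)
  set.seed(config$seed)
  n <- config$n_cases
  histology <- ifelse(stats::runif(n) < config$benign_case_fraction,
                      "benign", "malignant")
  subtype <- character(n)
  nb <- sum(histology == "benign")
  subtype[histology == "benign"] <-
    sample(benign_subtypes, nb, TRUE, benign_subtype_w)
  subtype[histology == "malignant"] <-
    sample(malignant_subtypes, n - nb, TRUE, malignant_subtype_w)
  case_id <- sprintf("case_%04d", seq_len(n))
  counts <- pmax(1L, stats::rnbinom(n, size = config$nuclei_dispersion,
                                    mu = config$nuclei_mean))

  total <- sum(counts)
  case_of <- rep(seq_len(n), counts)
  contam <- ifelse(histology[case_of] == "benign",
                   config$contamination_benign,
                   config$contamination_malignant)
  flip <- stats::runif(total) < contam
  latent <- ifelse(xor(histology[case_of] == "malignant", flip),
                   "malignant", "benign")

  d <- length(cytodx_features)
  sigma <- diag(d)
  dimnames(sigma) <- list(cytodx_features, cytodx_features)
  sigma[size_features, size_features] <- 0.3
  diag(sigma) <- 1
  z <- MASS::mvrnorm(total, mu = rep(0, d), Sigma = sigma)
  colnames(z) <- cytodx_features
  shift <- config$feature_effect[cytodx_features]
  z[latent == "malignant", ] <- sweep(
    z[latent == "malignant", , drop = FALSE], 2, shift, "+")
  feats <- latent_to_features(z)

  structures <- data.frame(
    case_id = case_id[case_of],
    structure_id = sprintf("%s_s%03d", case_id[case_of],
                           unlist(lapply(counts, seq_len))),
    label = histology[case_of], latent_class = latent, feats,
    check.names = FALSE)
  structure(list(cases = data.frame(case_id = case_id,
                                    histology = histology,
                                    subtype = subtype),
                 structures = structures, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort: %d cases (%.1f%% benign), %d structures>\n",
              nrow(x$cases),
              100 * mean(x$cases$histology == "benign"),
              nrow(x$structures)))
  invisible(x)
}

#' Case-level stratified train/test split
#'
#' Splits patients (never individual nuclei) into training and test
#' sets. Stratification keeps each class's training count within one
#' case of the target fraction, mirroring the importance of respecting
#' the class distribution during network training.
#'
#' @param cases data.frame with `case_id` and `histology` (or a `cohort`).
#' @param train_fraction Fraction of cases used for training (default
#'   0.5; must leave both splits non-empty).
#' @param stratified Stratify by histology (default `TRUE`).
#' @param seed Integer seed.
#' @return List with `train` and `test` character vectors of case ids
#'   (disjoint, exhaustive).
#' @export
split_train_test <- function(cases, train_fraction = 0.5,
                             stratified = TRUE, seed = 1) {
  if (inherits(cases, "cohort")) cases <- cases$cases
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must leave both splits non-empty")
  }
  tab <- table(cases$histology)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < 2)) stop("each class needs at least 2 cases to split")
  set.seed(seed)
  if (stratified) {
    train <- unlist(lapply(split(cases$case_id, cases$histology),
                           function(ids) {
                             sample(ids, round(train_fraction * length(ids)))
                           }), use.names = FALSE)
  } else {
    train <- sample(cases$case_id, round(train_fraction * nrow(cases)))
  }
  list(train = sort(train),
       test = sort(setdiff(cases$case_id, train)))
}

#' Render a synthetic nucleus image with analytic ground truth
#'
#' Rasterizes an elliptical nucleus against a white background: every
#' pixel whose center falls inside the ellipse is given the gray level
#' whose optical density (I0 = 255) equals the requested level. The
#' boundary is returned as a 256-gon on the true ellipse together with
#' the analytic truth record (area pi*a*b, Ramanujan perimeter, axes
#' 2a/2b, OD level), giving morphometry an exact oracle.
#'
#' @param a,b Ellipse semi-axes in px (a >= b after sorting).
#' @param rotation Rotation in radians (default 0).
#' @param center Ellipse center (x, y); default centers it in the image.
#' @param od_level Target optical density of the interior (default 0.3).
#' @param texture `"none"` (uniform), `"two_tone"` (halves at
#'   `od_levels`), or `"noise"` (seeded Gaussian OD jitter, SD
#'   `noise_sd`).
#' @param od_levels Length-2 OD pair for `"two_tone"`.
#' @param noise_sd OD jitter SD for `"noise"` (default 0.05).
#' @param image_size `c(height, width)`; default fits the shape with an
#'   8 px margin.
#' @param seed Seed for the noise texture.
#' @return List: `patch` ([image_patch()]), `boundary`
#'   ([nucleus_boundary()]), `truth` (analytic record).
#' @export
render_nucleus <- function(a, b, rotation = 0, center = NULL,
                           od_level = 0.3,
                           texture = c("none", "two_tone", "noise"),
                           od_levels = c(0.2, 0.4), noise_sd = 0.05,
                           image_size = NULL, seed = 1) {
  texture <- match.arg(texture)
  if (b > a) { tmp <- a; a <- b; b <- tmp }
  if (is.null(image_size)) {
    # odd extent puts the default center on an integer pixel coordinate
    ext <- 2 * ceiling(a) + 17
    image_size <- c(ext, ext)
  }
  h <- image_size[1]; w <- image_size[2]
  if (is.null(center)) center <- c((w - 1) / 2, (h - 1) / 2)
  # extreme extents of the rotated ellipse
  ex <- sqrt((a * cos(rotation))^2 + (b * sin(rotation))^2)
  ey <- sqrt((a * sin(rotation))^2 + (b * cos(rotation))^2)
  if (center[1] - ex < 0 || center[1] + ex > w - 1 ||
      center[2] - ey < 0 || center[2] + ey > h - 1) {
    stop("shape exceeds image bounds")
  }
  xs <- matrix(rep(0:(w - 1), each = h), h, w)
  ys <- matrix(rep(0:(h - 1), w), h, w)
  dx <- xs - center[1]; dy <- ys - center[2]
  u <- dx * cos(rotation) + dy * sin(rotation)
  vv <- -dx * sin(rotation) + dy * cos(rotation)
  inside <- (u / a)^2 + (vv / b)^2 <= 1

  od <- matrix(0, h, w)
  if (texture == "none") {
    od[inside] <- od_level
  } else if (texture == "two_tone") {
    od[inside & u <= 0] <- od_levels[1]
    od[inside & u > 0] <- od_levels[2]
  } else {
    set.seed(seed)
    od[inside] <- pmax(0, od_level +
                         stats::rnorm(sum(inside), 0, noise_sd))
  }
  gray <- matrix(255, h, w)
  gray[inside] <- pmin(255, pmax(0, round(256 * 10^(-od[inside]) - 1)))
  patch <- image_patch(array(rep(gray, 3), c(h, w, 3)))

  t <- seq(0, 2 * pi, length.out = 257)[-257]
  px <- center[1] + a * cos(t) * cos(rotation) - b * sin(t) * sin(rotation)
  py <- center[2] + a * cos(t) * sin(rotation) + b * sin(t) * cos(rotation)
  boundary <- nucleus_boundary(px, py)

  hh <- (a - b)^2 / (a + b)^2
  perim <- pi * (a + b) * (1 + 3 * hh / (10 + sqrt(4 - 3 * hh)))
  list(patch = patch, boundary = boundary,
       truth = list(area = pi * a * b, perimeter = perim,
                    major_axis = 2 * a, minor_axis = 2 * b,
                    od_level = od_level, texture = texture))
}
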