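#' Fit a feature standardizer
#'
#' Column means and standard deviations estimated on training data, used
#' as the input-layer weighting of the network. The SD uses the
#' population denominator n (the training table is treated as the
#' described set, matching the optical-density SD convention), so
#' standardizing the training table gives population SDs of exactly 1.
#' Constant columns carry no information at unit scale and are dropped
#' with a warning.
#'
#' @param features Numeric matrix or data.frame (n x d, n >= 2).
#' @return A `standardizer` object: `mean`, `sd`, `features` (kept
#'   column names), `dropped`.
#' @export
fit_standardizer <- function(features) {
  x <- as.matrix(features)
  if (nrow(x) < 2) stop("need at least 2 rows to estimate a standardizer")
  mu <- colMeans(x)
  sd <- sqrt(colMeans(sweep(x, 2, mu)^2))
  dropped <- colnames(x)[sd == 0 | !is.finite(sd)]
  if (length(dropped)) {
    warning("dropping constant feature(s): ",
            paste(dropped, collapse = ", "))
  }
  keep <- setdiff(colnames(x), dropped)
  structure(list(mean = mu[keep], sd = sd[keep], features = keep,
                 dropped = dropped), class = "standardizer")
}

#' Apply / invert a standardizer
#'
#' @param std A `standardizer`.
#' @param features Matrix or data.frame holding at least the kept columns.
#' @return Standardized (or de-standardized) matrix over the kept columns.
#' @export
standardize <- function(std, features) {
  x <- as.matrix(as.data.frame(features)[, std$features, drop = FALSE])
  sweep(sweep(x, 2, std$mean), 2, std$sd, "/")
}

#' @rdname standardize
#' @export
unstandardize <- function(std, features) {
  x <- as.matrix(features)[, std$features, drop = FALSE]
  sweep(sweep(x, 2, std$sd, "*"), 2, std$mean, "+")
}

#' Hidden-layer radial basis activations
#'
#' Gaussian response of each hidden node to a standardized input:
#' `phi_j(x) = exp(-||x - c_j||^2 / (2 sigma_j^2))`, each in (0, 1\].
#'
#' @param x Standardized feature vector, or an n x d matrix of rows.
#' @param centers k x d matrix of node centers.
#' @param widths Vector of k positive node widths.
#' @return n x k activation matrix (a 1 x k matrix for a single vector).
#' @export
rbf_activations <- function(x, centers, widths) {
  x <- rbind(x)
  if (ncol(x) != ncol(centers)) stop("dimension mismatch with centers")
  # squared distances via the expansion ||x||^2 + ||c||^2 - 2 x.c
  d2 <- outer(rowSums(x^2), rowSums(centers^2), "+") -
    2 * tcrossprod(x, centers)
  d2 <- pmax(d2, 0)
  exp(sweep(d2, 2, 2 * widths^2, "/") * -1)
}

# widths from the nearest-center heuristic
rbf_widths <- function(centers, z, width_neighbors) {
  k <- nrow(centers)
  if (k == 1) {
    s <- mean(sqrt(rowSums(sweep(z, 2, centers[1, ])^2)))
  } else {
    dc <- as.matrix(stats::dist(centers))
    diag(dc) <- Inf
    m <- min(width_neighbors, k - 1)
    s <- apply(dc, 1, function(r) mean(sort(r)[seq_len(m)]))
  }
  s[s <= 0 | !is.finite(s)] <- max(mean(s[s > 0 & is.finite(s)]), 1e-6)
  s
}

# ridge least-squares output layer; escalates lambda on singularity
rbf_output_weights <- function(design, y, lambda) {
  for (attempt in 0:3) {
    w <- tryCatch(
      solve(crossprod(design) + lambda * diag(ncol(design)),
            crossprod(design, y)),
      error = function(e) NULL)
    if (!is.null(w)) return(list(weights = drop(w), lambda = lambda))
    lambda <- lambda * 10
  }
  stop("output-layer normal equations singular even after ridge escalation")
}

rbf_fit_at_k <- function(z, y, k, width_neighbors, width_scale,
                         ridge_lambda, seed) {
  set.seed((seed + 1009L * k) %% .Machine$integer.max)
  if (k >= nrow(z)) {
    # one node per training point: the exact-interpolation construction
    centers <- z
  } else {
    km <- suppressWarnings(
      stats::kmeans(z, centers = k, nstart = 10, iter.max = 100))
    centers <- km$centers
  }
  rownames(centers) <- NULL
  widths <- unname(rbf_widths(centers, z, width_neighbors)) * width_scale
  phi <- rbf_activations(z, centers, widths)
  sol <- rbf_output_weights(cbind(1, phi), y, ridge_lambda)
  list(centers = centers, widths = widths,
       weights = unname(sol$weights), lambda = sol$lambda)
}

normalize_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.numeric(labels) || is.logical(labels)) {
    return(as.integer(labels != 0))
  }
  ok <- labels %in% c("benign", "malignant")
  if (!all(ok)) stop("labels must be 'benign' or 'malignant'")
  as.integer(labels == "malignant")
}

#' Train the radial basis function nucleus classifier
#'
#' Fits the three-layer network: inputs are standardized, hidden-node
#' centers are placed by seeded k-means on the standardized training
#' features (10 restarts), node widths come from the mean distance to the
#' nearest other centers, and the linear output layer is solved by
#' ridge-regularized least squares against targets benign = 0,
#' malignant = 1. The hidden-node count is adjusted from the data: each
#' candidate in `k_grid` is scored by balanced accuracy on an internal
#' stratified 80/20 holdout of the training rows, and the winner is refit
#' on all rows. Training is deterministic for fixed data and seed, and
#' invariant to the ordering of the training rows (rows are put in a
#' canonical sort order before any seeded step).
#'
#' @param features n x d numeric matrix or data.frame of nucleus features.
#' @param labels Per-row class: `"benign"`/`"malignant"` (or 0/1 with 1 =
#'   malignant).
#' @param k_grid Candidate hidden-node counts (default `c(10, 20, 40, 80)`).
#' @param width_neighbors Nearest centers averaged for each width
#'   (default 2).
#' @param width_scale Multiplier on the heuristic widths (default 1).
#' @param ridge_lambda Output-layer ridge penalty (default 1e-6).
#' @param seed Integer seed controlling k-means restarts and the holdout.
#' @param decision_cut Score threshold for calling malignant (default
#'   0.5; ties at the cut are called malignant).
#' @param holdout_fraction Internal validation fraction (default 0.2).
#' @return An `rbf_model`: standardizer, `centers`, `widths`, `weights`
#'   (bias first), `decision_cut`, `k`, `selection` (per-k holdout
#'   record), `seed`, `feature_names`.
#' @export
fit_rbf <- function(features, labels, k_grid = c(10, 20, 40, 80),
                    width_neighbors = 2, width_scale = 1,
                    ridge_lambda = 1e-6, seed = 1, decision_cut = 0.5,
                    holdout_fraction = 0.2) {
  x <- as.matrix(as.data.frame(features))
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- normalize_labels(labels)
  if (length(unique(y)) < 2) stop("both classes must be present")
  k_grid <- k_grid[k_grid <= nrow(x)]
  if (!length(k_grid)) stop("k_grid exceeds the number of training rows")
  # canonical content order: lexicographic over features then label
  ord <- do.call(order, c(as.data.frame(x), list(y)))
  x <- x[ord, , drop = FALSE]
  y <- y[ord]

  std <- fit_standardizer(x)
  z <- standardize(std, x)

  # stratified internal holdout, seeded on content-ordered rows
  set.seed(seed %% .Machine$integer.max)
  hold <- if (holdout_fraction > 0) {
    unlist(lapply(split(seq_along(y), y), function(idx) {
      sample(idx, round(holdout_fraction * length(idx)))
    }), use.names = FALSE)
  } else integer(0)
  fit_idx <- setdiff(seq_along(y), hold)

  selection <- data.frame(k = integer(0), holdout_balanced_acc = numeric(0))
  if (!length(hold)) {
    if (length(k_grid) > 1) {
      stop("holdout_fraction = 0 requires a single k in k_grid")
    }
    best <- list(k = k_grid, bal = NA_real_)
  } else {
    best <- NULL
    for (k in sort(k_grid)) {
      if (k > length(fit_idx)) next
      f <- rbf_fit_at_k(z[fit_idx, , drop = FALSE], y[fit_idx], k,
                        width_neighbors, width_scale, ridge_lambda, seed)
      sc <- drop(cbind(1, rbf_activations(z[hold, , drop = FALSE],
                                          f$centers, f$widths)) %*% f$weights)
      pred <- as.integer(sc >= decision_cut)
      sens <- mean(pred[y[hold] == 1] == 1)
      spec <- mean(pred[y[hold] == 0] == 0)
      bal <- (sens + spec) / 2
      selection <- rbind(selection,
                         data.frame(k = k, holdout_balanced_acc = bal))
      if (is.null(best) || bal > best$bal + 1e-12) {
        best <- list(k = k, bal = bal)
      }
    }
    if (is.null(best)) stop("no k in k_grid is feasible for this data size")
  }

  final <- rbf_fit_at_k(z, y, best$k, width_neighbors, width_scale,
                        ridge_lambda, seed)
  structure(list(standardizer = std, centers = final$centers,
                 widths = final$widths, weights = final$weights,
                 ridge_lambda = final$lambda, decision_cut = decision_cut,
                 k = as.integer(best$k), selection = selection,
                 seed = seed,
                 width_neighbors = width_neighbors,
                 width_scale = width_scale,
                 feature_names = std$features,
                 holdout = list(n_holdout = length(hold),
                                n_fit = length(fit_idx),
                                n_holdout_malignant = sum(y[hold] == 1),
                                n_malignant = sum(y == 1),
                                n_total = length(y))),
            class = "rbf_model")
}

#' @export
print.rbf_model <- function(x, ...) {
  cat(sprintf("<rbf_model: %d hidden nodes, %d features, cut %.2f>\n",
              x$k, length(x$feature_names), x$decision_cut))
  invisible(x)
}

#' Score nuclei with a fitted RBF model
#'
#' Standardizes the input, evaluates the hidden-layer activations and the
#' linear output, and labels each nucleus malignant when the score
#' reaches the decision cut (ties go to malignant).
#'
#' @param model A fitted `rbf_model`.
#' @param features One feature vector (named) or an n x d table.
#' @return A data.frame with `score` and `label`.
#' @export
predict_rbf <- function(model, features) {
  if (is.null(dim(features))) features <- t(as.matrix(features))
  features <- as.data.frame(features)
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  z <- standardize(model$standardizer, features)
  sc <- drop(cbind(1, rbf_activations(z, model$centers, model$widths)) %*%
               model$weights)
  data.frame(score = sc,
             label = ifelse(sc >= model$decision_cut,
                            "malignant", "benign"))
}

#' @rdname predict_rbf
#' @export
predict_nucleus <- function(model, features) {
  p <- predict_rbf(model, features)
  list(score = p$score[1], label = p$label[1])
}

#' Serialize / restore an RBF model as JSON
#'
#' The JSON document carries the standardizer, centers, widths, output
#' weights, configuration and seed at full numeric precision, so a
#' restored model reproduces scores bit-exactly.
#'
#' @param model A fitted `rbf_model`.
#' @param path JSON file path.
#' @export
write_rbf_model <- function(model, path) {
  doc <- list(
    feature_names = model$feature_names,
    standardizer = list(mean = unname(model$standardizer$mean),
                        sd = unname(model$standardizer$sd),
                        features = model$standardizer$features,
                        dropped = model$standardizer$dropped),
    centers = model$centers, widths = model$widths,
    weights = unname(model$weights), ridge_lambda = model$ridge_lambda,
    decision_cut = model$decision_cut, k = model$k, seed = model$seed,
    width_neighbors = model$width_neighbors,
    width_scale = model$width_scale,
    selection = model$selection, holdout = model$holdout)
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_rbf_model
#' @export
read_rbf_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  std <- structure(list(
    mean = stats::setNames(doc$standardizer$mean, doc$standardizer$features),
    sd = stats::setNames(doc$standardizer$sd, doc$standardizer$features),
    features = doc$standardizer$features,
    dropped = as.character(doc$standardizer$dropped %||% character(0))),
    class = "standardizer")
  centers <- matrix(unlist(doc$centers), nrow = doc$k, byrow = FALSE)
  if (is.matrix(doc$centers)) centers <- doc$centers
  colnames(centers) <- doc$feature_names
  rownames(centers) <- NULL
  structure(list(standardizer = std, centers = centers,
                 widths = doc$widths, weights = doc$weights,
                 ridge_lambda = doc$ridge_lambda,
                 decision_cut = doc$decision_cut, k = as.integer(doc$k),
                 selection = as.data.frame(doc$selection),
                 seed = doc$seed, width_neighbors = doc$width_neighbors,
                 width_scale = doc$width_scale,
                 feature_names = doc$feature_names,
                 holdout = doc$holdout),
            class = "rbf_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
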