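test_that("standardizer uses population SDs and round-trips", {
  s <- fit_standardizer(matrix(c(0, 2), ncol = 1,
                               dimnames = list(NULL, "f")))
  expect_equal(unname(s$mean), 1)
  expect_equal(unname(s$sd), 1)
  expect_equal(drop(standardize(s, matrix(c(0, 2), ncol = 1,
                                          dimnames = list(NULL, "f")))),
               c(-1, 1))

  set.seed(41)
  x <- matrix(rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  s2 <- fit_standardizer(x)
  z <- standardize(s2, x)
  expect_equal(unname(colMeans(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(sqrt(colMeans(z^2))), rep(1, 4), tolerance = 1e-12)
  expect_equal(unstandardize(s2, z), x, tolerance = 1e-12)

  # a pre-standardized table maps to itself
  z2 <- standardize(fit_standardizer(z), z)
  expect_equal(z2, z, tolerance = 1e-12)

  x_const <- cbind(x, fc = 5)
  expect_warning(s3 <- fit_standardizer(x_const), "constant")
  expect_false("fc" %in% s3$features)
})

test_that("radial activations follow the Gaussian closed form", {
  centers <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE)
  w <- c(1, 2)
  expect_equal(drop(rbf_activations(c(0, 0), centers, w))[1], 1.0)
  # a point at distance sigma from its center activates at exp(-1/2)
  expect_equal(drop(rbf_activations(c(1, 0), centers, w))[1],
               exp(-0.5))
  set.seed(42)
  x <- matrix(rnorm(10), 5, 2)
  phi <- rbf_activations(x, centers, w)
  for (i in 1:5) for (j in 1:2) {
    expect_equal(phi[i, j],
                 exp(-sum((x[i, ] - centers[j, ])^2) / (2 * w[j]^2)))
  }
  expect_true(all(phi > 0 & phi <= 1))
  expect_error(rbf_activations(c(1, 2, 3), centers, w), "dimension")
})

test_that("well-separated classes are learned perfectly", {
  set.seed(43)
  x <- rbind(matrix(rnorm(160), ncol = 2),
             matrix(rnorm(160) + 10, ncol = 2))
  y <- rep(c("benign", "malignant"), each = 80)
  m <- fit_rbf(x, y, k_grid = 2, seed = 1)
  expect_equal(mean(predict_rbf(m, x)$label == y), 1.0)
  expect_error(fit_rbf(x, rep("benign", 160), k_grid = 2), "both classes")
})

test_that("the interpolation limit reproduces the training targets", {
  set.seed(44)
  x <- matrix(rnorm(24), 12, 2, dimnames = list(NULL, c("f1", "f2")))
  y <- rep(c("benign", "malignant"), 6)
  m <- fit_rbf(x, y, k_grid = 12, width_scale = 0.05,
               ridge_lambda = 1e-12, holdout_fraction = 0, seed = 1)
  sc <- predict_rbf(m, x)$score
  expect_equal(sc, as.numeric(y == "malignant"), tolerance = 1e-6)
})

test_that("accuracy approaches the Bayes rule on overlapping Gaussians", {
  # classes N(0, I) and N((2,0), I), equal priors: the Bayes rule is
  # x1 > 1 with accuracy pnorm(1)
  set.seed(45)
  n <- 1000
  xtr <- rbind(matrix(rnorm(2 * n), ncol = 2),
               sweep(matrix(rnorm(2 * n), ncol = 2), 2, c(2, 0), "+"))
  ytr <- rep(c("benign", "malignant"), each = n)
  m <- fit_rbf(xtr, ytr, k_grid = c(5, 10, 20), seed = 2)
  nte <- 5000
  xte <- rbind(matrix(rnorm(2 * nte), ncol = 2),
               sweep(matrix(rnorm(2 * nte), ncol = 2), 2, c(2, 0), "+"))
  yte <- rep(c("benign", "malignant"), each = nte)
  acc <- mean(predict_rbf(m, xte)$label == yte)
  expect_equal(acc, pnorm(1), tolerance = 0.03)
})

test_that("training is deterministic and invariant to row order", {
  set.seed(46)
  x <- rbind(matrix(rnorm(60), ncol = 2),
             matrix(rnorm(60) + 2.5, ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("benign", "malignant"), each = 30)
  m1 <- fit_rbf(x, y, k_grid = c(2, 4), seed = 7)
  m2 <- fit_rbf(x, y, k_grid = c(2, 4), seed = 7)
  expect_identical(m1$centers, m2$centers)
  expect_identical(m1$weights, m2$weights)

  perm <- sample(length(y))
  m3 <- fit_rbf(x[perm, ], y[perm], k_grid = c(2, 4), seed = 7)
  expect_equal(m3$k, m1$k)
  expect_equal(m3$selection, m1$selection)
  expect_equal(m3$centers, m1$centers)
  expect_equal(m3$weights, m1$weights)

  # stratified holdout preserves the class ratio within one sample
  hr <- m1$holdout
  expect_lte(abs(hr$n_holdout_malignant -
                   hr$n_holdout * hr$n_malignant / hr$n_total), 1)
})

test_that("prediction applies the >= tie rule and is continuous and vectorized", {
  flat <- structure(list(
    standardizer = structure(list(mean = c(f1 = 0, f2 = 0),
                                  sd = c(f1 = 1, f2 = 1),
                                  features = c("f1", "f2"),
                                  dropped = character(0)),
                             class = "standardizer"),
    centers = matrix(0, 1, 2, dimnames = list(NULL, c("f1", "f2"))),
    widths = 1, weights = c(0.5, 0), decision_cut = 0.5, k = 1,
    feature_names = c("f1", "f2")), class = "rbf_model")
  # score is exactly at the cut everywhere -> malignant by convention
  expect_equal(predict_nucleus(flat, c(f1 = 3, f2 = -1))$label,
               "malignant")

  set.seed(47)
  x <- rbind(matrix(rnorm(40), ncol = 2),
             matrix(rnorm(40) + 3, ncol = 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("benign", "malignant"), each = 20)
  m <- fit_rbf(x, y, k_grid = 3, seed = 1)
  batch <- predict_rbf(m, x)
  single <- vapply(seq_len(nrow(x)), function(i) {
    predict_nucleus(m, x[i, ])$score
  }, numeric(1))
  expect_equal(batch$score, single, tolerance = 1e-12)

  x0 <- x[1, ]
  s0 <- predict_nucleus(m, x0)$score
  s1 <- predict_nucleus(m, x0 + 1e-9)$score
  expect_lt(abs(s1 - s0), 1e-6)

  expect_error(predict_rbf(m, matrix(1, 1, 1,
                                     dimnames = list(NULL, "f1"))),
               "f2")
})

test_that("model JSON serialization round-trips scores bit-exactly", {
  set.seed(48)
  x <- rbind(matrix(rnorm(60), ncol = 3),
             matrix(rnorm(60) + 2, ncol = 3))
  colnames(x) <- c("f1", "f2", "f3")
  y <- rep(c("benign", "malignant"), each = 20)
  m <- fit_rbf(x, y, k_grid = c(2, 4), seed = 5)
  f <- tempfile(fileext = ".json")
  write_rbf_model(m, f)
  m2 <- read_rbf_model(f)
  expect_identical(predict_rbf(m2, x)$score, predict_rbf(m, x)$score)
  expect_identical(m2$k, m$k)
  expect_identical(m2$widths, m$widths)
})
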