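test_that("case tallies count benign calls and their percentage", {
  t <- tally_case(c(rep("benign", 7), rep("malignant", 3)), "c1")
  expect_equal(t$n_benign_pred, 7)
  expect_equal(t$pct_benign_pred, 70)
  expect_equal(tally_case(rep("malignant", 4))$n_benign_pred, 0)
  expect_error(tally_case(character(0)), "inadequate")

  set.seed(51)
  labs <- sample(c("benign", "malignant"), 57, TRUE)
  t2 <- tally_case(labs)
  expect_equal(t2$n_benign_pred, sum(labs == "benign"))
  expect_equal(t2$pct_benign_pred, 100 * sum(labs == "benign") / 57)
})

test_that("the case rule is a strict threshold on counts or percentages", {
  thr37 <- list(mode = "numeric", value = 37)
  t38 <- tally_case(c(rep("benign", 38), rep("malignant", 50)))
  t37 <- tally_case(c(rep("benign", 37), rep("malignant", 51)))
  expect_equal(classify_case(t38, thr37), "benign")
  expect_equal(classify_case(t37, thr37), "malignant")

  thr51 <- list(mode = "percent", value = 51)
  t510 <- tally_case(c(rep("benign", 510), rep("malignant", 490)))
  t511 <- tally_case(c(rep("benign", 511), rep("malignant", 489)))
  expect_equal(t510$pct_benign_pred, 51.0)
  expect_equal(classify_case(t510, thr51), "malignant")
  expect_equal(classify_case(t511, thr51), "benign")
})

make_tallies <- function(benign_counts, malignant_counts, n = 100) {
  data.frame(
    case_id = sprintf("c%03d", seq_along(c(benign_counts,
                                           malignant_counts))),
    n_structures = n,
    n_benign_pred = c(benign_counts, malignant_counts),
    pct_benign_pred = 100 * c(benign_counts, malignant_counts) / n)
}

test_that("threshold optimization balances sensitivity and specificity", {
  # perfectly separable: any threshold in [5, 89] is perfect; the tie
  # rule picks the smallest
  tl <- make_tallies(rep(90, 12), rep(5, 8))
  truth <- rep(c("benign", "malignant"), c(12, 8))
  thr <- optimize_threshold(tl, truth, "numeric")
  expect_equal(thr$value, 5)
  i <- match(5, thr$sweep_record$threshold)
  expect_equal(thr$sweep_record$sensitivity[i], 1)
  expect_equal(thr$sweep_record$specificity[i], 1)
  expect_error(optimize_threshold(tl, rep("benign", 20), "numeric"),
               "both classes")

  # flipped truth: the chosen gap still equals the exhaustive minimum
  flipped <- rep(c("malignant", "benign"), c(12, 8))
  thr_f <- optimize_threshold(tl, flipped, "numeric")
  rescan <- vapply(1:100, function(t) {
    pred <- ifelse(tl$n_benign_pred > t, "benign", "malignant")
    abs(mean(pred[flipped == "malignant"] == "malignant") -
          mean(pred[flipped == "benign"] == "benign"))
  }, numeric(1))
  i <- match(thr_f$value, thr_f$sweep_record$threshold)
  expect_equal(abs(thr_f$sweep_record$sensitivity[i] -
                     thr_f$sweep_record$specificity[i]),
               min(rescan))
})

test_that("percent-mode selection matches an independent from-scratch sweep", {
  set.seed(52)
  nb <- 30; nm <- 20
  tl <- make_tallies(rbinom(nb, 100, 0.9), rbinom(nm, 100, 0.3))
  truth <- rep(c("benign", "malignant"), c(nb, nm))
  thr <- optimize_threshold(tl, truth, "percent")

  grid <- round(seq(1, 100, by = 0.1), 1)
  oracle <- do.call(rbind, lapply(grid, function(t) {
    pred <- ifelse(tl$pct_benign_pred > t, "benign", "malignant")
    sens <- mean(pred[truth == "malignant"] == "malignant")
    spec <- mean(pred[truth == "benign"] == "benign")
    data.frame(t = t, gap = abs(sens - spec), acc = mean(pred == ifelse(
      truth == "malignant", "malignant", "benign")))
  }))
  best <- oracle[order(oracle$gap, -oracle$acc, oracle$t), ][1, ]
  expect_equal(thr$value, best$t)
})

test_that("the sweep is monotone and self-consistent at the chosen threshold", {
  set.seed(53)
  tl <- make_tallies(rbinom(25, 100, 0.85), rbinom(15, 100, 0.35))
  truth <- rep(c("benign", "malignant"), c(25, 15))
  for (mode in c("numeric", "percent")) {
    thr <- optimize_threshold(tl, truth, mode)
    rec <- thr$sweep_record
    expect_true(all(diff(rec$sensitivity) >= 0))
    expect_true(all(diff(rec$specificity) <= 0))
    # reclassifying the training tallies reproduces the recorded pair
    pred <- classify_case(tl, thr)
    i <- match(thr$value, rec$threshold)
    expect_equal(mean(pred[truth == "malignant"] == "malignant"),
                 rec$sensitivity[i])
    expect_equal(mean(pred[truth == "benign"] == "benign"),
                 rec$specificity[i])
  }

  # case order must not matter
  perm <- sample(nrow(tl))
  thr1 <- optimize_threshold(tl, truth, "numeric")
  thr2 <- optimize_threshold(tl[perm, ], truth[perm], "numeric")
  expect_equal(thr1$value, thr2$value)
})

test_that("case scores rank cases from malignant to benign", {
  tl <- make_tallies(c(90, 70), c(10, 30), n = 100)
  expect_equal(case_score(tally_case(c(rep("benign", 7),
                                       rep("malignant", 3))), "percent"),
               -70)
  expect_equal(case_score(tally_case(rep("malignant", 5)), "numeric"), 0)
  sc <- case_score(tl, "numeric")
  expect_equal(order(sc), rev(order(tl$n_benign_pred)))
})

test_that("threshold artifacts round-trip through JSON", {
  set.seed(54)
  tl <- make_tallies(rbinom(20, 100, 0.9), rbinom(10, 100, 0.3))
  truth <- rep(c("benign", "malignant"), c(20, 10))
  thr <- optimize_threshold(tl, truth, "percent")
  f <- tempfile(fileext = ".json")
  write_case_threshold(thr, f)
  back <- read_case_threshold(f)
  expect_equal(back$mode, thr$mode)
  expect_equal(back$value, thr$value)
  expect_equal(back$sweep_record, thr$sweep_record, tolerance = 1e-12)
})
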