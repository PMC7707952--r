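#' Build a 2x2 confusion matrix
#'
#' Counts truth-versus-prediction agreement with malignant as the
#' positive class.
#'
#' @param truth,predicted Equal-length label vectors
#'   (`"benign"`/`"malignant"`, or 0/1 with 1 = malignant).
#' @return A `confusion_matrix`: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (!length(truth) || length(truth) != length(predicted)) {
    stop("truth and predicted must be non-empty and of equal length")
  }
  y <- normalize_labels(truth)
  p <- normalize_labels(predicted)
  confusion_matrix(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
                   tn = sum(y == 0 & p == 0), fn = sum(y == 1 & p == 0))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total")
  }
  structure(as.list(counts), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tn, x$fp, x$fn, x$tp), 2, byrow = TRUE,
              dimnames = list(truth = c("benign", "malignant"),
                              predicted = c("benign", "malignant")))
  print(m)
  invisible(x)
}

#' @export
`+.confusion_matrix` <- function(e1, e2) {
  confusion_matrix(e1$tp + e2$tp, e1$fp + e2$fp,
                   e1$tn + e2$tn, e1$fn + e2$fn)
}

#' Diagnostic performance indices
#'
#' The full panel for a 2x2 diagnostic table (malignant positive):
#' sensitivity, specificity, positive and negative predictive values,
#' false-positive and false-negative rates, overall accuracy (all in
#' percent), plus the positive and negative likelihood ratios and the
#' diagnostic odds ratio. Ratio indices are always computed from the raw
#' counts, never from rounded percentages (rounding first visibly
#' corrupts the likelihood ratios at this cohort size). A zero
#' denominator yields `NA` for a proportion and `Inf` for a ratio, with a
#' warning.
#'
#' @param cm A `confusion_matrix`.
#' @return Named list: `sensitivity`, `specificity`, `ppv`, `npv`, `fpr`,
#'   `fnr`, `oa` (percent), `plr`, `nlr`, `odds_ratio`.
#' @export
performance_indices <- function(cm) {
  frac <- function(num, den, what) {
    if (den == 0) {
      warning("undefined ", what, ": zero denominator")
      return(NA_real_)
    }
    num / den
  }
  sens <- frac(cm$tp, cm$tp + cm$fn, "sensitivity")
  spec <- frac(cm$tn, cm$tn + cm$fp, "specificity")
  ppv <- frac(cm$tp, cm$tp + cm$fp, "PPV")
  npv <- frac(cm$tn, cm$tn + cm$fn, "NPV")
  total <- cm$tp + cm$fp + cm$tn + cm$fn
  oa <- (cm$tp + cm$tn) / total
  plr <- if (is.na(spec)) NA_real_ else if (spec == 1) {
    warning("PLR infinite: zero false-positive rate"); Inf
  } else sens / (1 - spec)
  nlr <- if (is.na(spec) || spec == 0) NA_real_ else (1 - sens) / spec
  odds <- if (cm$fp * cm$fn == 0) {
    warning("odds ratio infinite: empty off-diagonal"); Inf
  } else (cm$tp * cm$tn) / (cm$fp * cm$fn)
  list(sensitivity = 100 * sens, specificity = 100 * spec,
       ppv = 100 * ppv, npv = 100 * npv,
       fpr = 100 * (1 - spec), fnr = 100 * (1 - sens), oa = 100 * oa,
       plr = plr, nlr = nlr, odds_ratio = odds)
}

#' Two-proportion z-test
#'
#' Compares two independent proportions `x1/n1` and `x2/n2`. The 95%
#' confidence interval for the difference uses the unpooled standard
#' error; the z statistic and two-sided p-value use the pooled standard
#' error by default (`variance = "unpooled"` switches both to the
#' unpooled form). `se_n` overrides the denominators used inside the
#' standard errors only, which supports reporting conventions that quote
#' a class-conditional rate but scale its uncertainty by the whole-set
#' size.
#'
#' @param x1,n1,x2,n2 Successes and sizes of the two groups.
#' @param conf_level Confidence level (default 0.95).
#' @param variance `"pooled"` (default) or `"unpooled"` for the z/p.
#' @param se_n Optional length-2 vector of standard-error denominators.
#' @return List: `difference` (percentage points), `ci_low`, `ci_high`,
#'   `z`, `p_value`.
#' @export
two_proportion_test <- function(x1, n1, x2, n2, conf_level = 0.95,
                                variance = c("pooled", "unpooled"),
                                se_n = NULL) {
  variance <- match.arg(variance)
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) {
    stop("successes must lie in [0, n]")
  }
  if (is.null(se_n)) se_n <- c(n1, n2)
  p1 <- x1 / n1
  p2 <- x2 / n2
  diff <- p1 - p2
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_unpooled <- sqrt(p1 * (1 - p1) / se_n[1] + p2 * (1 - p2) / se_n[2])
  if (variance == "pooled") {
    pp <- (x1 + x2) / (n1 + n2)
    se_z <- sqrt(pp * (1 - pp) * (1 / se_n[1] + 1 / se_n[2]))
  } else {
    se_z <- se_unpooled
  }
  z <- if (se_z == 0) 0 else diff / se_z
  list(difference = 100 * diff,
       ci_low = 100 * (diff - zq * se_unpooled),
       ci_high = 100 * (diff + zq * se_unpooled),
       z = z,
       p_value = 2 * stats::pnorm(-abs(z)))
}

#' ROC curve and trapezoidal AUC
#'
#' Sweeps every distinct score as a threshold (equal scores grouped into
#' one step) and returns the operating points with the trapezoidal area
#' under the curve. Larger scores must indicate more malignant-looking
#' cases. The AUC equals the Mann-Whitney concordance probability with
#' ties counted one half.
#'
#' @param scores Per-case numeric scores.
#' @param truth Per-case labels (`"benign"`/`"malignant"` or 0/1).
#' @return A `roc_curve` object: `points` data.frame (`threshold`,
#'   `fpr`, `tpr` on \[0, 1\]) and `auc` in percent.
#' @export
roc_curve <- function(scores, truth) {
  y <- normalize_labels(truth)
  if (length(unique(y)) < 2) stop("both classes must be present")
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  pts <- data.frame(threshold = r$thresholds,
                    fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  structure(list(points = pts, auc = 100 * as.numeric(pROC::auc(r)),
                 roc = r),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve: AUC %.2f%%, %d operating points>\n",
              x$auc, nrow(x$points)))
  invisible(x)
}

#' AUC confidence intervals and paired curve comparison
#'
#' DeLong 95% confidence intervals for the AUC of two score sets measured
#' on the same cases, and the paired DeLong test for the difference. A
#' degenerate comparison (identical scores, zero variance of the
#' difference) is reported as difference 0 with p = 1.
#'
#' @param scores_a,scores_b Two per-case score vectors (same cases).
#' @param truth Per-case labels.
#' @param conf_level Confidence level (default 0.95).
#' @return List: `auc_a`, `auc_b` (percent), `ci_a`, `ci_b` (length-2,
#'   percent, clipped to \[0, 100\]), `difference` (percent),
#'   `p_value`.
#' @export
auc_ci_and_compare <- function(scores_a, scores_b, truth,
                               conf_level = 0.95) {
  y <- normalize_labels(truth)
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (length(scores_a) != length(scores_b)) {
    stop("score vectors must cover the same cases")
  }
  ra <- pROC::roc(y, scores_a, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  rb <- pROC::roc(y, scores_b, levels = c(0, 1), direction = "<",
                  quiet = TRUE)
  ci <- function(r) {
    v <- suppressWarnings(
      as.numeric(pROC::ci.auc(r, conf.level = conf_level,
                              method = "delong")))
    pmin(100, pmax(0, 100 * v[c(1, 3)]))
  }
  auc_a <- 100 * as.numeric(pROC::auc(ra))
  auc_b <- 100 * as.numeric(pROC::auc(rb))
  p <- if (isTRUE(all.equal(scores_a, scores_b))) 1 else {
    tst <- tryCatch(
      pROC::roc.test(ra, rb, paired = TRUE, method = "delong"),
      error = function(e) NULL)
    if (is.null(tst) || !is.finite(tst$p.value)) {
      if (abs(auc_a - auc_b) < 1e-12) 1 else NA_real_
    } else tst$p.value
  }
  list(auc_a = auc_a, auc_b = auc_b, ci_a = ci(ra), ci_b = ci(rb),
       difference = auc_a - auc_b, p_value = p)
}

#' Assemble a performance report table across data splits
#'
#' Mirrors the standard index-by-split layout: one row per index, one
#' column per split, values in display units.
#'
#' @param cms Named list of `confusion_matrix` objects (e.g. train, test,
#'   combined).
#' @return data.frame with an `index` column and one column per split.
#' @export
performance_report <- function(cms) {
  cols <- lapply(cms, function(cm) unlist(performance_indices(cm)))
  out <- data.frame(index = names(cols[[1]]), do.call(cbind, cols),
                    check.names = FALSE)
  rownames(out) <- NULL
  out
}
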