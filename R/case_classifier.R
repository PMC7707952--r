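#' Tally nucleus predictions for one case
#'
#' Counts the structures the nucleus classifier labeled benign for one
#' patient and expresses the count as a percentage of the structures
#' measured on that slide.
#'
#' @param labels Character vector of per-structure predictions
#'   (`"benign"`/`"malignant"`), at least one.
#' @param case_id Optional identifier carried through.
#' @return A `case_tally`: `case_id`, `n_structures`, `n_benign_pred`,
#'   `pct_benign_pred`.
#' @export
tally_case <- function(labels, case_id = NA) {
  if (!length(labels)) stop("inadequate specimen: no structures for case")
  if (!all(labels %in% c("benign", "malignant"))) {
    stop("labels must be 'benign' or 'malignant'")
  }
  nb <- sum(labels == "benign")
  structure(list(case_id = case_id, n_structures = length(labels),
                 n_benign_pred = nb,
                 pct_benign_pred = 100 * nb / length(labels)),
            class = "case_tally")
}

#' Tally every case in a prediction table
#'
#' @param predictions data.frame with `case_id` and predicted `label`.
#' @return data.frame of one row per case: `case_id`, `n_structures`,
#'   `n_benign_pred`, `pct_benign_pred`.
#' @export
tally_cases <- function(predictions) {
  sp <- split(predictions$label, predictions$case_id)
  out <- do.call(rbind, lapply(names(sp), function(cid) {
    t <- tally_case(sp[[cid]], cid)
    data.frame(case_id = cid, n_structures = t$n_structures,
               n_benign_pred = t$n_benign_pred,
               pct_benign_pred = t$pct_benign_pred)
  }))
  rownames(out) <- NULL
  out
}

tally_value <- function(tally, mode) {
  if (mode == "numeric") tally$n_benign_pred else tally$pct_benign_pred
}

#' Classify a case from its tally
#'
#' The numeric classifier calls a patient benign when strictly more than
#' `value` structures were labeled benign; the percentages classifier
#' applies the same strict rule to the benign percentage. Anything at or
#' below the threshold is called malignant.
#'
#' @param tally A `case_tally` (or data.frame of tallies).
#' @param threshold A `case_threshold` from [optimize_threshold()], or a
#'   list with `mode` (`"numeric"`/`"percent"`) and `value`.
#' @return `"benign"` or `"malignant"` (vector for a tally table).
#' @export
classify_case <- function(tally, threshold) {
  vals <- if (is.data.frame(tally)) {
    if (threshold$mode == "numeric") tally$n_benign_pred
    else tally$pct_benign_pred
  } else tally_value(tally, threshold$mode)
  ifelse(vals > threshold$value, "benign", "malignant")
}

#' Case score for ROC construction
#'
#' Larger score means more malignant-looking: the negated benign count
#' (numeric mode) or negated benign percentage (percent mode).
#'
#' @inheritParams classify_case
#' @param mode `"numeric"` or `"percent"`.
#' @return Numeric score (vector for a tally table).
#' @export
case_score <- function(tally, mode = c("numeric", "percent")) {
  mode <- match.arg(mode)
  if (is.data.frame(tally)) {
    if (mode == "numeric") -tally$n_benign_pred else -tally$pct_benign_pred
  } else -tally_value(tally, mode)
}

threshold_grid <- function(mode) {
  if (mode == "numeric") seq(1, 100, by = 1)
  else round(seq(1, 100, by = 0.1), 1)
}

sweep_thresholds <- function(tallies, truth, mode) {
  vals <- if (mode == "numeric") tallies$n_benign_pred
          else tallies$pct_benign_pred
  is_mal <- normalize_labels(truth) == 1
  grid <- threshold_grid(mode)
  rec <- lapply(grid, function(thr) {
    pred_benign <- vals > thr
    sens <- mean(!pred_benign[is_mal])   # malignant called malignant
    spec <- mean(pred_benign[!is_mal])   # benign called benign
    acc <- mean(ifelse(is_mal, !pred_benign, pred_benign))
    data.frame(threshold = thr, sensitivity = sens, specificity = spec,
               accuracy = acc)
  })
  do.call(rbind, rec)
}

#' Optimize the case-classifier threshold on training cases
#'
#' Sweeps every candidate threshold (counts 1..100 step 1 for the numeric
#' classifier; 1%..100% step 0.1 for the percentages classifier),
#' computes case-level sensitivity and specificity at each (malignant is
#' the positive class), and returns the threshold that balances them,
#' i.e. minimizes |sensitivity - specificity|. Ties are broken by higher
#' overall accuracy, then by the smaller threshold. Only training cases
#' should be supplied, so the selection cannot leak test information.
#'
#' @param tallies data.frame from [tally_cases()].
#' @param truth Per-case histology labels aligned with `tallies`.
#' @param mode `"numeric"` or `"percent"`.
#' @return A `case_threshold`: `mode`, `value`, and the full
#'   `sweep_record` data.frame.
#' @export
optimize_threshold <- function(tallies, truth, mode = c("numeric", "percent")) {
  mode <- match.arg(mode)
  y <- normalize_labels(truth)
  if (length(unique(y)) < 2) stop("both classes must be present in truth")
  if (nrow(tallies) != length(y)) stop("tallies and truth must align")
  rec <- sweep_thresholds(tallies, truth, mode)
  gap <- abs(rec$sensitivity - rec$specificity)
  best <- order(gap, -rec$accuracy, rec$threshold)[1]
  structure(list(mode = mode, value = rec$threshold[best],
                 sweep_record = rec),
            class = "case_threshold")
}

#' @export
print.case_threshold <- function(x, ...) {
  i <- match(x$value, x$sweep_record$threshold)
  cat(sprintf(
    "<case_threshold: %s mode, value %s (sens %.1f%%, spec %.1f%%)>\n",
    x$mode, format(x$value),
    100 * x$sweep_record$sensitivity[i],
    100 * x$sweep_record$specificity[i]))
  invisible(x)
}

#' Serialize / restore a case threshold as JSON
#'
#' @param threshold A `case_threshold`.
#' @param path JSON file path.
#' @export
write_case_threshold <- function(threshold, path) {
  jsonlite::write_json(list(mode = threshold$mode, value = threshold$value,
                            sweep_record = threshold$sweep_record),
                       path, digits = I(17), auto_unbox = TRUE,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_case_threshold
#' @export
read_case_threshold <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mode = doc$mode, value = doc$value,
                 sweep_record = as.data.frame(doc$sweep_record)),
            class = "case_threshold")
}
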