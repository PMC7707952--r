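#' Published reference confusion matrices for thyroid FNA morphometry
#'
#' Cross-tabulated classification counts from a published 447-patient
#' thyroid fine-needle aspiration study whose design this package
#' follows: 41,324 measured structures classified per nucleus by an RBF
#' network, then per patient by the numeric (count > 37 benign nuclei)
#' and percentages (> 51% benign nuclei) case classifiers, each reported
#' for the training set, the test set and both combined. These counts
#' serve as fixed inputs for recomputing the study's performance-index
#' panel and its train-versus-test proportion comparisons; malignant is
#' the positive class throughout.
#'
#' @return A nested list with elements `nuclei`, `cases_numeric`,
#'   `cases_percent` — each holding `train`, `test` and `combined`
#'   [confusion_matrix()] objects — plus `thresholds` (numeric 37,
#'   percent 51) and `cohort` (case and structure totals).
#' @export
reference_study_tables <- function() {
  cm3 <- function(train, test) {
    list(train = train, test = test, combined = train + test)
  }
  nuclei <- cm3(confusion_matrix(tp = 6090, fp = 716,
                                 tn = 12517, fn = 1291),
                confusion_matrix(tp = 5978, fp = 1335,
                                 tn = 12028, fn = 1369))
  cases_numeric <- cm3(confusion_matrix(tp = 73, fp = 8,
                                        tn = 137, fn = 6),
                       confusion_matrix(tp = 73, fp = 9,
                                        tn = 134, fn = 7))
  cases_percent <- cm3(confusion_matrix(tp = 75, fp = 6,
                                        tn = 139, fn = 4),
                       confusion_matrix(tp = 76, fp = 7,
                                        tn = 136, fn = 4))
  list(nuclei = nuclei, cases_numeric = cases_numeric,
       cases_percent = cases_percent,
       thresholds = list(numeric = 37, percent = 51),
       cohort = list(n_cases = 447, n_benign = 288, n_malignant = 159,
                     n_structures = 41324,
                     train_cases = 224, train_benign = 145,
                     train_malignant = 79))
}
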