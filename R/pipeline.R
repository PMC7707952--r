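#' Run the complete synthetic-cohort pipeline in memory
#'
#' One call exercising the whole architecture on generated data:
#' simulate a cohort, split cases (never nuclei) into training and test
#' sets, train the RBF nucleus classifier on training-set structures
#' labeled by case histology, tally its per-case predictions, optimize
#' the numeric and percentages case thresholds on training cases only,
#' and classify every case.
#'
#' @param config A [cohort_config()].
#' @param train_fraction Case-level training fraction (default 0.5).
#' @param k_grid,ridge_lambda Passed to [fit_rbf()].
#' @return List: `cohort`, `split`, `model`, `thresholds` (numeric and
#'   percent), `predictions` (per-structure), `tallies` (per-case with
#'   split and truth), `case_calls`, `nucleus_cm` and `case_cm`
#'   (train/test/combined confusion matrices), `nucleus_accuracy`.
#' @export
run_synthetic_pipeline <- function(config = cohort_config(),
                                   train_fraction = 0.5,
                                   k_grid = c(10, 20, 40, 80),
                                   ridge_lambda = 1e-6) {
  cohort <- simulate_cohort(config)
  split <- split_train_test(cohort$cases, train_fraction,
                            stratified = TRUE,
                            seed = (config$seed + 1L) %% 2147483647L)
  st <- cohort$structures
  st$split <- ifelse(st$case_id %in% split$train, "train", "test")
  tr <- st[st$split == "train", ]

  model <- fit_rbf(tr[, cytodx_features], tr$label, k_grid = k_grid,
                   ridge_lambda = ridge_lambda, seed = config$seed)
  pred <- predict_rbf(model, st[, cytodx_features])
  st$predicted <- pred$label
  st$score <- pred$score

  tallies <- tally_cases(data.frame(case_id = st$case_id,
                                    label = st$predicted))
  tallies <- merge(tallies, cohort$cases[, c("case_id", "histology")],
                   by = "case_id")
  tallies$split <- ifelse(tallies$case_id %in% split$train,
                          "train", "test")
  ttr <- tallies[tallies$split == "train", ]

  thr <- list(
    numeric = optimize_threshold(ttr, ttr$histology, "numeric"),
    percent = optimize_threshold(ttr, ttr$histology, "percent"))

  calls <- data.frame(
    case_id = tallies$case_id, split = tallies$split,
    truth = tallies$histology,
    numeric = classify_case(tallies, thr$numeric),
    percent = classify_case(tallies, thr$percent))

  split_cm <- function(truth, predicted, which) {
    keep <- if (which == "combined") rep(TRUE, length(truth))
            else calls$split == which
    confusion(truth[keep], predicted[keep])
  }
  nucleus_cm <- lapply(stats::setNames(nm = c("train", "test", "combined")),
                       function(w) {
                         keep <- if (w == "combined") TRUE
                                 else st$split == w
                         confusion(st$label[keep], st$predicted[keep])
                       })
  case_cm <- lapply(stats::setNames(nm = c("numeric", "percent")),
                    function(mode) {
                      lapply(stats::setNames(nm = c("train", "test",
                                                    "combined")),
                             function(w) split_cm(calls$truth,
                                                  calls[[mode]], w))
                    })
  nucleus_accuracy <- vapply(
    stats::setNames(nm = c("train", "test")), function(w) {
      mean((st$predicted == st$label)[st$split == w])
    }, numeric(1))

  list(cohort = cohort, split = split, model = model, thresholds = thr,
       predictions = st[, c("case_id", "structure_id", "label",
                            "latent_class", "split", "predicted",
                            "score")],
       tallies = tallies, case_calls = calls, nucleus_cm = nucleus_cm,
       case_cm = case_cm, nucleus_accuracy = nucleus_accuracy)
}

write_manifest <- function(out_dir, stage, config, seed, files) {
  files <- files[file.exists(files)]
  man <- list(stage = stage,
              version = as.character(utils::packageVersion("cytodx")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              seed = seed, config = config,
              files = lapply(stats::setNames(nm = files), function(f) {
                list(path = f, md5 = unname(tools::md5sum(f)))
              }))
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Validate a run manifest
#'
#' Recomputes the digest of every file listed in a stage manifest and
#' checks it against the recorded value.
#'
#' @param path Manifest JSON path.
#' @return `TRUE` invisibly; stops on a missing or modified file.
#' @export
validate_manifest <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in man$files) {
    if (!file.exists(f$path)) stop("manifest file missing: ", f$path)
    if (unname(tools::md5sum(f$path)) != f$md5) {
      stop("digest mismatch for ", f$path)
    }
  }
  invisible(TRUE)
}

#' Pipeline stage: simulate a cohort to disk
#'
#' Wraps [simulate_cohort()] and [split_train_test()]; writes
#' `features.csv` (feature-table format plus the latent class),
#' `cases.csv` (case_id, histology, subtype, split) and a digest
#' manifest. Deterministic per config seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [cohort_config()].
#' @param train_fraction Case-level training fraction (default 0.5).
#' @return Invisibly, the written file paths.
#' @export
cmd_simulate <- function(out_dir, config = cohort_config(),
                         train_fraction = 0.5) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- simulate_cohort(config)
  split <- split_train_test(cohort$cases, train_fraction,
                            stratified = TRUE,
                            seed = (config$seed + 1L) %% 2147483647L)
  cases <- cohort$cases
  cases$split <- ifelse(cases$case_id %in% split$train, "train", "test")
  f_feat <- file.path(out_dir, "features.csv")
  f_cases <- file.path(out_dir, "cases.csv")
  utils::write.csv(cohort$structures, f_feat, row.names = FALSE)
  utils::write.csv(cases, f_cases, row.names = FALSE)
  cfg <- unclass(config)
  cfg$feature_effect <- as.list(cfg$feature_effect)
  write_manifest(out_dir, "simulate", cfg, config$seed,
                 c(f_feat, f_cases))
  message(sprintf("simulate: %d cases, %d structures -> %s",
                  nrow(cases), nrow(cohort$structures), out_dir))
  invisible(c(features = f_feat, cases = f_cases))
}

#' Pipeline stage: extract features from images and boundary files
#'
#' Measures every structure delineated in the boundary CSV on its image
#' (`<structure_id>.png` or `.tif` inside `images_dir`). Structures that
#' fail validation are skipped and logged; the run fails only when no
#' structure yields a valid feature vector.
#'
#' @param images_dir Directory of image files named by structure id.
#' @param boundaries_csv Vertex CSV (see [read_boundaries()]).
#' @param out_csv Output feature-table path.
#' @return Invisibly, the feature table.
#' @export
cmd_extract <- function(images_dir, boundaries_csv, out_csv) {
  boundaries <- read_boundaries(boundaries_csv)
  patches <- lapply(stats::setNames(nm = names(boundaries)), function(id) {
    for (ext in c("png", "tif", "tiff")) {
      p <- file.path(images_dir, paste0(id, ".", ext))
      if (file.exists(p)) return(read_image_patch(p))
    }
    NULL
  })
  have <- !vapply(patches, is.null, logical(1))
  for (id in names(boundaries)[!have]) {
    message("skipping structure ", id, ": no image found")
  }
  if (!any(have)) stop("no boundary references an existing image")
  tab <- extract_feature_table(boundaries[have], patches[have])
  write_feature_table(tab, out_csv)
  message(sprintf("extract: %d measured, %d skipped -> %s",
                  nrow(tab),
                  attr(tab, "n_skipped") + sum(!have), out_csv))
  invisible(tab)
}

#' Pipeline stage: train the nucleus and case classifiers
#'
#' Fits the RBF network on training-split structures, tallies training
#' cases, optimizes both case thresholds, and writes `model.json`,
#' `threshold_numeric.json`, `threshold_percent.json` and a training
#' report of performance indices.
#'
#' @param features_csv Feature table (must include `case_id`, `label`).
#' @param cases_csv Cases CSV with a `split` column.
#' @param out_dir Output directory.
#' @param k_grid,ridge_lambda,seed Passed to [fit_rbf()].
#' @return Invisibly: list with `model`, `thresholds`, `report`.
#' @export
cmd_train <- function(features_csv, cases_csv, out_dir,
                      k_grid = c(10, 20, 40, 80), ridge_lambda = 1e-6,
                      seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feats <- read_feature_table(features_csv)
  cases <- utils::read.csv(cases_csv, stringsAsFactors = FALSE)
  if (!"split" %in% names(cases)) {
    stop("cases CSV has no 'split' column; run cmd_simulate ",
         "(or add the split) first")
  }
  feats$split <- cases$split[match(feats$case_id, cases$case_id)]
  tr <- feats[feats$split == "train", ]
  model <- fit_rbf(tr[, cytodx_features], tr$label, k_grid = k_grid,
                   ridge_lambda = ridge_lambda, seed = seed)
  pred <- predict_rbf(model, tr[, cytodx_features])
  tallies <- tally_cases(data.frame(case_id = tr$case_id,
                                    label = pred$label))
  truth <- cases$histology[match(tallies$case_id, cases$case_id)]
  thr <- list(numeric = optimize_threshold(tallies, truth, "numeric"),
              percent = optimize_threshold(tallies, truth, "percent"))
  cms <- list(
    nuclei_train = confusion(tr$label, pred$label),
    cases_numeric_train = confusion(truth,
                                    classify_case(tallies, thr$numeric)),
    cases_percent_train = confusion(truth,
                                    classify_case(tallies, thr$percent)))
  report <- performance_report(cms)

  f_model <- file.path(out_dir, "model.json")
  f_num <- file.path(out_dir, "threshold_numeric.json")
  f_pct <- file.path(out_dir, "threshold_percent.json")
  f_rep <- file.path(out_dir, "report_train.csv")
  write_rbf_model(model, f_model)
  write_case_threshold(thr$numeric, f_num)
  write_case_threshold(thr$percent, f_pct)
  utils::write.csv(report, f_rep, row.names = FALSE)
  jsonlite::write_json(
    list(confusion = lapply(cms, unclass), report = report),
    file.path(out_dir, "report_train.json"),
    digits = NA, auto_unbox = TRUE, dataframe = "columns")
  write_manifest(out_dir, "train",
                 list(k_grid = k_grid, ridge_lambda = ridge_lambda),
                 seed, c(f_model, f_num, f_pct, f_rep))
  message(sprintf(
    "train: %d nuclei, k = %d, thresholds %d / %.1f%% -> %s",
    nrow(tr), model$k, thr$numeric$value, thr$percent$value, out_dir))
  invisible(list(model = model, thresholds = thr, report = report))
}

#' Pipeline stage: evaluate fitted artifacts on every split
#'
#' Scores all structures with the stored model, derives nucleus- and
#' case-level confusion matrices for train, test and combined,
#' recomputes the full performance-index panel, runs train-versus-test
#' two-proportion z-tests on nucleus sensitivity/specificity/accuracy,
#' and builds case-level ROC curves with DeLong AUC confidence intervals
#' plus the paired numeric-versus-percentages AUC comparison.
#'
#' @param model_path `model.json` from [cmd_train()].
#' @param threshold_paths Named list/vector with `numeric` and `percent`
#'   JSON paths.
#' @param features_csv,cases_csv Data files as in [cmd_train()].
#' @param out_dir Output directory.
#' @return Invisibly: list with `nucleus_report`, `case_reports`,
#'   `z_tests`, `roc`, `auc_comparison`.
#' @export
cmd_evaluate <- function(model_path, threshold_paths, features_csv,
                         cases_csv, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- read_rbf_model(model_path)
  thr <- list(numeric = read_case_threshold(threshold_paths[["numeric"]]),
              percent = read_case_threshold(threshold_paths[["percent"]]))
  feats <- read_feature_table(features_csv)
  cases <- utils::read.csv(cases_csv, stringsAsFactors = FALSE)
  feats$split <- cases$split[match(feats$case_id, cases$case_id)]
  pred <- predict_rbf(model, feats[, cytodx_features])
  feats$predicted <- pred$label

  splits <- stats::setNames(nm = c("train", "test", "combined"))
  nucleus_cm <- lapply(splits, function(w) {
    keep <- if (w == "combined") TRUE else feats$split == w
    confusion(feats$label[keep], feats$predicted[keep])
  })
  nucleus_report <- performance_report(nucleus_cm)

  tallies <- tally_cases(data.frame(case_id = feats$case_id,
                                    label = feats$predicted))
  tallies$truth <- cases$histology[match(tallies$case_id, cases$case_id)]
  tallies$split <- cases$split[match(tallies$case_id, cases$case_id)]
  case_reports <- list()
  roc <- list()
  auc_comparison <- list()
  for (mode in c("numeric", "percent")) {
    calls <- classify_case(tallies, thr[[mode]])
    cms <- lapply(splits, function(w) {
      keep <- if (w == "combined") TRUE else tallies$split == w
      confusion(tallies$truth[keep], calls[keep])
    })
    case_reports[[mode]] <- performance_report(cms)
    roc[[mode]] <- lapply(stats::setNames(nm = c("train", "test")),
                          function(w) {
      keep <- tallies$split == w
      roc_curve(case_score(tallies[keep, ], mode), tallies$truth[keep])
    })
  }
  for (w in c("train", "test")) {
    keep <- tallies$split == w
    auc_comparison[[w]] <- auc_ci_and_compare(
      case_score(tallies[keep, ], "numeric"),
      case_score(tallies[keep, ], "percent"), tallies$truth[keep])
  }

  ztest_of <- function(stat) {
    a <- nucleus_cm$train; b <- nucleus_cm$test
    n1 <- switch(stat, sensitivity = c(a$tp, a$tp + a$fn),
                 specificity = c(a$tn, a$tn + a$fp),
                 oa = c(a$tp + a$tn, a$tp + a$tn + a$fp + a$fn))
    n2 <- switch(stat, sensitivity = c(b$tp, b$tp + b$fn),
                 specificity = c(b$tn, b$tn + b$fp),
                 oa = c(b$tp + b$tn, b$tp + b$tn + b$fp + b$fn))
    two_proportion_test(n1[1], n1[2], n2[1], n2[2])
  }
  z_tests <- lapply(stats::setNames(nm = c("sensitivity", "specificity",
                                           "oa")), ztest_of)

  utils::write.csv(nucleus_report,
                   file.path(out_dir, "report_nuclei.csv"),
                   row.names = FALSE)
  for (mode in c("numeric", "percent")) {
    utils::write.csv(case_reports[[mode]],
                     file.path(out_dir,
                               paste0("report_cases_", mode, ".csv")),
                     row.names = FALSE)
    for (w in c("train", "test")) {
      utils::write.csv(roc[[mode]][[w]]$points,
                       file.path(out_dir,
                                 sprintf("roc_%s_%s.csv", mode, w)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(z_tests = z_tests,
         auc = lapply(roc, function(m) lapply(m, function(r) r$auc)),
         auc_comparison = auc_comparison),
    file.path(out_dir, "evaluation.json"),
    digits = NA, auto_unbox = TRUE)
  message(sprintf(
    "evaluate: nucleus OA train %.2f%%, test %.2f%% -> %s",
    performance_indices(nucleus_cm$train)$oa,
    performance_indices(nucleus_cm$test)$oa, out_dir))
  invisible(list(nucleus_report = nucleus_report,
                 case_reports = case_reports, z_tests = z_tests,
                 roc = roc, auc_comparison = auc_comparison,
                 nucleus_cm = nucleus_cm, tallies = tallies))
}
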