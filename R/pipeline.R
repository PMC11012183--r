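#' Load a cohort from CSV files
#'
#' Reads and validates the three-file cohort interface written by
#' [write_cohort()]: a feature table (`subject_id` plus one numeric column
#' per feature), a subject table (`subject_id`, `label`, `sex`, covariate
#' columns) and a feature metadata table (`feature_id`, `category`,
#' `role`). Missing values, duplicate subject ids, unmatched subject sets
#' and non-binary label/sex codings are rejected.
#'
#' @param features_csv,subjects_csv,feature_meta_csv File paths.
#' @return A validated `cad_cohort`.
#' @export
load_feature_table <- function(features_csv, subjects_csv, feature_meta_csv) {
  feat <- utils::read.csv(features_csv, check.names = FALSE, fileEncoding = "UTF-8")
  subj <- utils::read.csv(subjects_csv, check.names = FALSE, fileEncoding = "UTF-8")
  meta <- utils::read.csv(feature_meta_csv, check.names = FALSE, fileEncoding = "UTF-8")

  for (tab in list(feat, subj)) {
    if (!"subject_id" %in% names(tab)) stop("missing subject_id column", call. = FALSE)
  }
  if (anyDuplicated(feat$subject_id) || anyDuplicated(subj$subject_id)) {
    stop("duplicate subject ids", call. = FALSE)
  }
  if (!identical(sort(feat$subject_id), sort(subj$subject_id))) {
    stop("feature and subject tables cover different subjects", call. = FALSE)
  }
  feat <- feat[match(subj$subject_id, feat$subject_id), ]

  na_counts <- vapply(feat, function(col) sum(is.na(col)), integer(1))
  na_counts <- na_counts[na_counts > 0]
  if (length(na_counts)) {
    stop(sprintf(
      "missing values: %s",
      paste(sprintf("%s (%d)", names(na_counts), na_counts), collapse = ", ")
    ), call. = FALSE)
  }
  if (!all(c("label", "sex") %in% names(subj))) {
    stop("subject table needs label and sex columns", call. = FALSE)
  }
  if (!all(subj$label %in% c(0, 1))) stop("label must be coded 0/1", call. = FALSE)
  if (!all(subj$sex %in% c(0, 1))) stop("sex must be coded 0/1", call. = FALSE)
  na_cov <- vapply(subj, function(col) sum(is.na(col)), integer(1))
  na_cov <- na_cov[na_cov > 0]
  if (length(na_cov)) {
    stop(sprintf(
      "missing values: %s",
      paste(sprintf("%s (%d)", names(na_cov), na_cov), collapse = ", ")
    ), call. = FALSE)
  }

  feature_ids <- setdiff(names(feat), "subject_id")
  if (!all(c("feature_id", "category", "role") %in% names(meta))) {
    stop("feature_meta needs feature_id, category, role", call. = FALSE)
  }
  if (!setequal(meta$feature_id, feature_ids)) {
    stop("feature_meta does not match feature columns", call. = FALSE)
  }
  meta <- meta[match(feature_ids, meta$feature_id), ]

  x <- as.matrix(feat[, feature_ids, drop = FALSE])
  rownames(x) <- NULL
  if (!is.numeric(x)) stop("non-numeric feature values", call. = FALSE)
  covs <- subj[, setdiff(names(subj), c("subject_id", "label", "sex")), drop = FALSE]
  structure(
    list(
      features = x,
      subject_id = as.character(subj$subject_id),
      label = as.integer(subj$label), sex = as.integer(subj$sex),
      covariates = covs, feature_meta = meta, spec = NULL
    ),
    class = "cad_cohort"
  )
}

#' Pipeline configuration
#'
#' Bundles every stage's settings for [run_pipeline()]. The default
#' training profile is reduced-scale (`n_iterations = 10`, a 50-model
#' bank); pass `train = train_config()` for the full 100-iteration,
#' 500-model development run.
#'
#' @param cohort A [cohort_spec()] to simulate from, or a named list of
#'   CSV paths (`features`, `subjects`, `feature_meta`) to load.
#' @param screen A [screen_config()].
#' @param train A [train_config()].
#' @param target_sensitivity Per-sex calibration target.
#' @param npv_prevalences Prevalences at which to tabulate NPV. The
#'   default leads with the implied intended-use prevalence
#'   ([implied_prevalence()]) followed by hypothetical higher ones.
#' @param selection_n_neg Size of the auxiliary disease-negative block
#'   generated for feature selection only (sex-balanced; never trained
#'   on). Used when `cohort` is a spec; loaded cohorts instead carve the
#'   screening negatives out of the cohort and exclude them from
#'   training.
#' @param use_all_if_empty If screening selects nothing, proceed with all
#'   features instead of stopping.
#' @param importance_n_perm,importance_max_models,importance_max_subjects
#'   Scale of the permutation-importance computation.
#' @param out_dir Directory for stage artifacts and the run manifest;
#'   `NULL` skips writing.
#' @param seed Global seed; every stage derives its streams from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            screen = screen_config(),
                            train = train_config(n_iterations = 10),
                            target_sensitivity = 0.9,
                            npv_prevalences = c(implied_prevalence(), 0.10, 0.20, 0.30),
                            selection_n_neg = 2L * screen$per_cell,
                            use_all_if_empty = FALSE,
                            importance_n_perm = 3,
                            importance_max_models = 25,
                            importance_max_subjects = 400,
                            out_dir = NULL,
                            seed = 1L) {
  stopifnot(inherits(screen, "screen_config"), inherits(train, "train_config"))
  if (target_sensitivity <= 0 || target_sensitivity > 1) {
    stop("target_sensitivity must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(
      cohort = cohort, screen = screen, train = train,
      target_sensitivity = target_sensitivity,
      npv_prevalences = npv_prevalences,
      selection_n_neg = as.integer(selection_n_neg),
      use_all_if_empty = use_all_if_empty,
      importance_n_perm = as.integer(importance_n_perm),
      importance_max_models = as.integer(importance_max_models),
      importance_max_subjects = as.integer(importance_max_subjects),
      out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Auxiliary sex-balanced disease-negative block used for feature selection
# only. Sex is assigned exactly half female so the balanced subset is
# always satisfiable; sex has no effect on feature or covariate draws
# given class, so the overwrite changes no distribution.
make_selection_block <- function(spec, n_neg, seed) {
  block_spec <- spec
  block_spec$n_pos <- 0L
  block_spec$n_neg <- as.integer(n_neg)
  block_spec$seed <- seed
  block <- generate_cohort(block_spec)
  block$sex <- rep_len(c(1L, 0L), n_neg)
  block$subject_id <- sprintf("FS%05d", seq_len(n_neg))
  block
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full development pipeline
#'
#' Executes the development sequence end to end: obtain the cohort
#' (simulate or load), draw the sex-balanced screening subset, run the
#' triple-test feature screen, train the out-of-fold stacked ensemble on
#' the intended-use cohort, calibrate per-sex cut points at the target
#' sensitivity, and compute the full performance report. Subjects used for
#' feature selection only never enter any training split; the disease-
#' positive screening subjects are also trained on (tagged `both`), and
#' their sensitivity is reported as a multiple-use bias check.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `pipeline_result`: list with `cohort`,
#'   `roles` (per-subject data frame), `screen` (`screen_result`), `bank`,
#'   `oof`, `cut_points`, `zeroed`, `test_positive`, and `report`
#'   (class `performance_report`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- stage("load", {
    if (inherits(config$cohort, "cohort_spec")) {
      spec <- config$cohort
      spec$seed <- derive_seed(seed, 1L)
      generate_cohort(spec)
    } else if (is.list(config$cohort)) {
      load_feature_table(
        config$cohort$features, config$cohort$subjects, config$cohort$feature_meta
      )
    } else {
      stop("config$cohort must be a cohort_spec or a list of CSV paths")
    }
  })
  if (anyNA(cohort$features)) {
    stop("stage 'load' failed: cohort contains missing feature values", call. = FALSE)
  }

  # Screening cohort: auxiliary never-trained negatives plus the cohort's
  # positives (when simulated); for loaded cohorts, negatives are drawn
  # from the cohort and then withheld from training.
  scr <- stage("screen_subset", {
    pos_idx <- which(cohort$label == 1)
    if (inherits(config$cohort, "cohort_spec")) {
      block <- make_selection_block(
        config$cohort, config$selection_n_neg, derive_seed(seed, 2L)
      )
      screen_cohort <- bind_cohorts(block, subset_cohort(cohort, pos_idx))
      map <- c(rep(NA_integer_, n_subjects(block)), pos_idx)
      subset <- build_balanced_subset(
        screen_cohort, config$screen$per_cell, derive_seed(seed, 3L)
      )
      list(
        cohort = screen_cohort, subset = subset,
        selection_only_ids = block$subject_id,
        both_idx = stats::na.omit(map[subset]),
        train_idx = seq_len(n_subjects(cohort))
      )
    } else {
      subset <- build_balanced_subset(
        cohort, config$screen$per_cell, derive_seed(seed, 3L)
      )
      neg_screen <- subset[cohort$label[subset] == 0]
      list(
        cohort = cohort, subset = subset,
        selection_only_ids = cohort$subject_id[neg_screen],
        both_idx = subset[cohort$label[subset] == 1],
        train_idx = setdiff(seq_len(n_subjects(cohort)), neg_screen)
      )
    }
  })

  screen_cfg <- config$screen
  screen_cfg$seed <- derive_seed(seed, 4L)
  screen <- stage("feature_screen", {
    select_features(scr$cohort, scr$subset, screen_cfg)
  })
  selected <- screen$selected
  if (length(selected) == 0) {
    if (!config$use_all_if_empty) {
      stop("stage 'feature_screen' failed: no features selected", call. = FALSE)
    }
    selected <- colnames(cohort$features)
  }

  train_cohort <- subset_cohort(cohort, scr$train_idx)
  train_cfg <- config$train
  train_cfg$seed <- derive_seed(seed, 5L)
  fit <- stage("oof_train", run_oof(train_cohort, selected, train_cfg))

  cp <- stage("calibrate", {
    calibrate_cut_points(
      fit$oof$scores$oof_score, train_cohort$label, train_cohort$sex,
      config$target_sensitivity
    )
  })
  applied <- apply_cut_points(fit$oof$scores$oof_score, train_cohort$sex, cp)

  report <- stage("evaluate", {
    build_report(
      train_cohort, fit, cp, applied, config,
      both_ids = cohort$subject_id[scr$both_idx]
    )
  })

  roles <- data.frame(
    subject_id = c(scr$selection_only_ids, cohort$subject_id),
    role = c(
      rep("feature_selection_only", length(scr$selection_only_ids)),
      ifelse(cohort$subject_id %in% cohort$subject_id[scr$both_idx],
        "both", "train_validate"
      )
    ),
    stringsAsFactors = FALSE
  )
  roles <- roles[!duplicated(roles$subject_id), ]

  result <- structure(
    list(
      cohort = cohort, roles = roles, screen = screen,
      bank = fit$bank, oof = fit$oof, cut_points = cp,
      zeroed = applied$zeroed, test_positive = applied$test_positive,
      report = report, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_artifacts(result, config$out_dir)
  result
}

build_report <- function(cohort, fit, cp, applied, config, both_ids) {
  label <- cohort$label
  sex <- cohort$sex
  cr <- confusion_and_rates(applied$test_positive, label)
  or_raw <- odds_ratio(cr, continuity = any(cr$confusion == 0))

  auc <- c(
    combined = roc_auc(applied$zeroed, label),
    female = roc_auc(applied$zeroed[sex == 1], label[sex == 1]),
    male = roc_auc(applied$zeroed[sex == 0], label[sex == 0])
  )

  npv <- data.frame(
    prevalence = config$npv_prevalences,
    npv = npv_at_prevalence(cr$sensitivity, cr$specificity, config$npv_prevalences)
  )

  covs <- cohort$covariates
  subgroups <- list(female = sex == 1, male = sex == 0)
  for (nm in intersect(
    c("age_ge_65", "diabetes", "hypertension", "hyperlipidemia", "bmi_ge_30"),
    names(covs)
  )) {
    subgroups[[nm]] <- covs[[nm]] == 1
  }
  if (length(both_ids)) {
    subgroups[["screened_cad_pos"]] <- cohort$subject_id %in% both_ids
  }
  sub_tab <- subgroup_report(applied$test_positive, label, subgroups)

  adj_covs <- data.frame(male = 1L - sex)
  for (nm in intersect(
    c("age_ge_65", "diabetes", "hyperlipidemia", "hypertension"),
    names(covs)
  )) {
    adj_covs[[nm]] <- covs[[nm]]
  }
  adj <- adjusted_odds_ratios(applied$test_positive, label, adj_covs)

  en_rf_r <- model_correlation(
    fit$oof$scores$en_oof_score, fit$oof$scores$rf_oof_score
  )

  n_train <- n_subjects(cohort)
  imp <- category_importance(
    fit$bank, cohort,
    n_perm = config$importance_n_perm,
    seed = derive_seed(config$seed, 6L),
    max_models = config$importance_max_models,
    subjects = if (config$importance_max_subjects < n_train) {
      with_seed(
        derive_seed(config$seed, 7L),
        sort(sample.int(n_train, config$importance_max_subjects))
      )
    } else {
      NULL
    }
  )

  structure(
    list(
      confusion = cr$confusion,
      sensitivity = cr$sensitivity, specificity = cr$specificity,
      roc_auc = auc,
      odds_ratio = or_raw,
      cut_points = cp,
      npv_curve = npv,
      subgroup_table = sub_tab,
      adjusted_or_table = adj,
      en_rf_correlation = en_rf_r,
      category_importance = imp$category,
      n_models = length(fit$bank$models),
      n_selected_features = length(fit$bank$feature_ids)
    ),
    class = "performance_report"
  )
}

#' @export
print.performance_report <- function(x, ...) {
  cat("CAD rule-out algorithm performance\n")
  cat(sprintf(
    "  sensitivity %.0f%%  specificity %.0f%%  (TP %d, FP %d, FN %d, TN %d)\n",
    100 * x$sensitivity, 100 * x$specificity,
    x$confusion[["TP"]], x$confusion[["FP"]], x$confusion[["FN"]], x$confusion[["TN"]]
  ))
  cat(sprintf(
    "  ROC-AUC: combined %.2f, female %.2f, male %.2f\n",
    x$roc_auc[["combined"]], x$roc_auc[["female"]], x$roc_auc[["male"]]
  ))
  cat(sprintf(
    "  cut points: female %.3f, male %.3f (target sensitivity %.0f%%)\n",
    x$cut_points$thresholds[["female"]], x$cut_points$thresholds[["male"]],
    100 * x$cut_points$target
  ))
  cat(sprintf(
    "  odds ratio %.2f (95%% CI %.2f-%.2f); EN-RF Pearson r %.2f\n",
    x$odds_ratio$estimate, x$odds_ratio$ci_lower, x$odds_ratio$ci_upper,
    x$en_rf_correlation
  ))
  cat(sprintf(
    "  NPV: %s\n",
    paste(sprintf(
      "%.2f%% @ %.1f%% prevalence",
      100 * x$npv_curve$npv, 100 * x$npv_curve$prevalence
    ), collapse = ", ")
  ))
  cat(sprintf(
    "  %d models in bank over %d selected features\n",
    x$n_models, x$n_selected_features
  ))
  invisible(x)
}

report_to_list <- function(report) {
  list(
    confusion = as.list(report$confusion),
    sensitivity = report$sensitivity,
    specificity = report$specificity,
    roc_auc = as.list(report$roc_auc),
    odds_ratio = report$odds_ratio,
    cut_points = list(
      target = report$cut_points$target,
      thresholds = as.list(report$cut_points$thresholds),
      achieved = report$cut_points$achieved
    ),
    npv_curve = report$npv_curve,
    subgroup_table = report$subgroup_table,
    adjusted_or_table = report$adjusted_or_table,
    en_rf_correlation = report$en_rf_correlation,
    category_importance = as.list(report$category_importance),
    n_models = report$n_models,
    n_selected_features = report$n_selected_features
  )
}

write_pipeline_artifacts <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_cohort(result$cohort, file.path(out_dir, "cohort"))
  utils::write.csv(result$roles, file.path(out_dir, "subject_roles.csv"),
    row.names = FALSE, fileEncoding = "UTF-8"
  )
  write_screen_result(result$screen, out_dir)
  write_oof_result(result$oof, result$bank, out_dir)
  write_cut_points(result$cut_points, file.path(out_dir, "cut_points.json"))
  jsonlite::write_json(
    report_to_list(result$report),
    file.path(out_dir, "performance_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
  )
  txt <- file.path(out_dir, "performance_report.txt")
  sink(txt)
  on.exit(sink(), add = TRUE)
  print(result$report)
  sink()
  on.exit()

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "manifest.json"))
  manifest <- list(
    seed = result$config$seed,
    package_version = as.character(utils::packageVersion("cadrule")),
    r_version = R.version.string,
    n_models = length(result$bank$models),
    n_selected_features = length(result$bank$feature_ids),
    checksums = as.list(stats::setNames(
      unname(tools::md5sum(files)),
      substring(files, nchar(out_dir) + 2)
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(out_dir)
}
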