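#' Training configuration
#'
#' Settings for repeated stratified out-of-fold (OOF) training of the
#' stacked ensemble. Each iteration draws a fresh stratified `k_folds`
#' partition, trains one stacked model (elastic net + random forest,
#' predictions averaged) per training split, and records each subject's
#' naive prediction from the one model whose training excluded it. Over
#' `n_iterations` iterations the bank holds `k_folds * n_iterations`
#' models; applied to new data they are compressed with
#' `bank_compression`.
#'
#' @param k_folds Folds per iteration.
#' @param n_iterations Number of repeated cross-validation iterations.
#' @param en_l1_ratio Elastic-net mixing parameter (`alpha` in glmnet):
#'   0 is pure ridge, 1 pure lasso.
#' @param en_penalty_strength Optional fixed penalty (`lambda`); when
#'   `NULL` it is chosen per model by internal 3-fold cross-validation on
#'   the training split only.
#' @param rf_n_trees Trees per random forest.
#' @param rf_min_leaf Minimum terminal-node size.
#' @param stack_rule How the two base predictions combine; fixed to the
#'   arithmetic mean.
#' @param bank_compression Reducer across the bagged ensemble at
#'   prediction time: `"median"` (default) or `"mean"`.
#' @param seed Integer seed; fold assignments and model fits derive their
#'   streams from it.
#' @return An object of class `train_config`.
#' @export
train_config <- function(k_folds = 5, n_iterations = 100,
                         en_l1_ratio = 0.5, en_penalty_strength = NULL,
                         rf_n_trees = 500, rf_min_leaf = 5,
                         stack_rule = "mean",
                         bank_compression = c("median", "mean"),
                         seed = 1L) {
  if (k_folds < 2) stop("k_folds must be >= 2", call. = FALSE)
  if (n_iterations < 1) stop("n_iterations must be >= 1", call. = FALSE)
  if (en_l1_ratio < 0 || en_l1_ratio > 1) stop("en_l1_ratio must lie in [0, 1]", call. = FALSE)
  if (!identical(stack_rule, "mean")) stop("stack_rule is fixed to 'mean'", call. = FALSE)
  structure(
    list(
      k_folds = as.integer(k_folds), n_iterations = as.integer(n_iterations),
      en_l1_ratio = en_l1_ratio, en_penalty_strength = en_penalty_strength,
      rf_n_trees = as.integer(rf_n_trees), rf_min_leaf = as.integer(rf_min_leaf),
      stack_rule = "mean",
      bank_compression = match.arg(bank_compression),
      seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

#' Sex-by-class sample weights
#'
#' Weights that equalise the total training mass of the four sex-by-class
#' cells: a subject in cell c of size n_c gets weight N / (4 n_c), so each
#' cell's weights sum to N/4. This counters the confounding between sex
#' and disease in the development population (female-majority CAD-,
#' male-majority CAD+), discouraging the learners from using sex as a
#' proxy for disease.
#'
#' @param label Binary class vector (CAD+ = 1).
#' @param sex Binary sex vector (female = 1).
#' @return Numeric weight vector, one per subject.
#' @export
compute_sample_weights <- function(label, sex) {
  stopifnot_binary(label, "label")
  stopifnot_binary(sex, "sex")
  cells <- cell_of(label, sex)
  counts <- table(cells)
  if (any(counts == 0)) {
    stop(sprintf(
      "empty sex-by-class cell(s): %s",
      paste(names(counts)[counts == 0], collapse = ", ")
    ), call. = FALSE)
  }
  n <- length(label)
  as.numeric(n / (4 * counts[cells]))
}

#' Stratified fold assignment
#'
#' Partitions subjects into `k` folds stratified by class: within each
#' class, subjects are shuffled and dealt cyclically, so per-fold class
#' counts differ from exact proportionality by at most one.
#'
#' @param label Binary class vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold assignment in `1:k`, one per subject.
#' @export
stratified_folds <- function(label, k, seed = 1L) {
  stopifnot_binary(label, "label")
  for (cl in c(0, 1)) {
    if (sum(label == cl) < k) {
      stop(sprintf("class %d has fewer than k = %d subjects", cl, k), call. = FALSE)
    }
  }
  folds <- integer(length(label))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      members <- which(label == cl)
      folds[members[sample.int(length(members))]] <-
        rep_len(sample.int(k), length(members))
    }
  })
  folds
}

#' Train one stacked model
#'
#' Fits the two base learners on \{0,1\}-encoded labels as a regression
#' task — an elastic net (l1 + l2 penalised least squares, sample-weighted,
#' penalty chosen by internal 3-fold cross-validation unless fixed) and a
#' random forest regressor (MSE split criterion, sample-weighted) — and
#' stacks them by averaging their predictions.
#'
#' @param x Numeric feature matrix (subjects x features, named columns).
#' @param y Binary label vector.
#' @param weights Per-subject training weights.
#' @param config A [train_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return An object of class `stack_model`.
#' @export
train_stack <- function(x, y, weights = rep(1, length(y)),
                        config = train_config(), seed = config$seed) {
  stopifnot_binary(y, "y")
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  if (sum(y == 1) < 2 || sum(y == 0) < 2) {
    stop("need at least 2 subjects per class", call. = FALSE)
  }
  x <- as.matrix(x)
  en <- with_seed(derive_seed(seed, 1L), {
    if (is.null(config$en_penalty_strength)) {
      cv <- glmnet::cv.glmnet(x, y,
        family = "gaussian", alpha = config$en_l1_ratio,
        weights = weights, nfolds = 3
      )
      list(fit = cv$glmnet.fit, lambda = cv$lambda.min)
    } else {
      fit <- glmnet::glmnet(x, y,
        family = "gaussian", alpha = config$en_l1_ratio,
        weights = weights, lambda = config$en_penalty_strength
      )
      list(fit = fit, lambda = config$en_penalty_strength)
    }
  })
  rf <- ranger::ranger(
    x = x, y = as.numeric(y),
    num.trees = config$rf_n_trees,
    min.node.size = config$rf_min_leaf,
    mtry = max(1L, floor(sqrt(ncol(x)))),
    case.weights = weights,
    num.threads = 1L,
    seed = derive_seed(seed, 2L)
  )
  structure(
    list(en = en, rf = rf, feature_ids = colnames(x)),
    class = "stack_model"
  )
}

#' Predict from a stacked model
#'
#' @param object A `stack_model`.
#' @param newx Feature matrix with the training columns.
#' @param type `"stack"` for the averaged score, `"en"`, `"rf"`, or
#'   `"all"` for a three-column matrix.
#' @param ... Unused.
#' @return Numeric score vector, or a matrix for `type = "all"`.
#' @export
predict.stack_model <- function(object, newx,
                                type = c("stack", "en", "rf", "all"), ...) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  check_feature_ids(colnames(newx), object$feature_ids)
  newx <- newx[, object$feature_ids, drop = FALSE]
  en <- as.numeric(stats::predict(object$en$fit, newx, s = object$en$lambda))
  rf <- stats::predict(object$rf, data = newx, num.threads = 1L)$predictions
  switch(type,
    en = en,
    rf = rf,
    stack = (en + rf) / 2,
    all = cbind(en = en, rf = rf, stack = (en + rf) / 2)
  )
}

check_feature_ids <- function(have, want) {
  missing <- setdiff(want, have)
  extra <- setdiff(have, want)
  if (length(missing) || length(extra)) {
    stop(sprintf(
      "feature mismatch: missing [%s]; extra [%s]",
      paste(missing, collapse = ", "), paste(extra, collapse = ", ")
    ), call. = FALSE)
  }
  invisible(TRUE)
}

#' Repeated stratified out-of-fold training
#'
#' Runs `n_iterations` rounds of stratified `k_folds` cross-validation on
#' the selected features. In each round, one stacked model is trained per
#' training split — with sample weights recomputed on that split only —
#' and every subject is scored by the single model whose training excluded
#' it (the naive prediction). The per-subject OOF score is the mean of its
#' naive predictions across iterations; all trained models are stored,
#' tagged with iteration, fold and training-subject ids, as the bagged
#' ensemble applied to new data.
#'
#' @param cohort A `cad_cohort`.
#' @param selected_features Character vector of feature ids to train on.
#' @param config A [train_config()].
#' @return List with `bank` (class `model_bank`) and `oof` (class
#'   `oof_result`: per-subject scores plus the per-iteration prediction
#'   matrix and per-learner OOF scores).
#' @export
run_oof <- function(cohort, selected_features, config = train_config()) {
  stopifnot(inherits(cohort, "cad_cohort"))
  if (length(selected_features) == 0) stop("selected_features is empty", call. = FALSE)
  absent <- setdiff(selected_features, colnames(cohort$features))
  if (length(absent)) {
    stop(sprintf(
      "selected features not in cohort: %s", paste(absent, collapse = ", ")
    ), call. = FALSE)
  }
  x <- cohort$features[, selected_features, drop = FALSE]
  if (!all(is.finite(x))) stop("non-finite feature values", call. = FALSE)
  y <- cohort$label
  n <- length(y)
  k <- config$k_folds

  models <- vector("list", k * config$n_iterations)
  pred <- matrix(NA_real_, n, config$n_iterations)
  pred_en <- matrix(NA_real_, n, config$n_iterations)
  pred_rf <- matrix(NA_real_, n, config$n_iterations)

  m <- 0L
  for (iter in seq_len(config$n_iterations)) {
    folds <- stratified_folds(y, k, seed = derive_seed(config$seed, iter, 0L))
    for (f in seq_len(k)) {
      train_idx <- which(folds != f)
      test_idx <- which(folds == f)
      w <- compute_sample_weights(y[train_idx], cohort$sex[train_idx])
      model <- train_stack(
        x[train_idx, , drop = FALSE], y[train_idx], w, config,
        seed = derive_seed(config$seed, iter, f)
      )
      p <- predict(model, x[test_idx, , drop = FALSE], type = "all")
      pred[test_idx, iter] <- p[, "stack"]
      pred_en[test_idx, iter] <- p[, "en"]
      pred_rf[test_idx, iter] <- p[, "rf"]
      m <- m + 1L
      models[[m]] <- list(
        model = model, iteration = iter, fold = f,
        train_subjects = cohort$subject_id[train_idx]
      )
    }
  }

  bank <- structure(
    list(models = models, feature_ids = selected_features, config = config),
    class = "model_bank"
  )
  oof <- structure(
    list(
      scores = data.frame(
        subject_id = cohort$subject_id,
        oof_score = rowMeans(pred),
        en_oof_score = rowMeans(pred_en),
        rf_oof_score = rowMeans(pred_rf),
        stringsAsFactors = FALSE
      ),
      pred_matrix = pred
    ),
    class = "oof_result"
  )
  list(bank = bank, oof = oof)
}

#' @export
print.model_bank <- function(x, ...) {
  cat(sprintf(
    "<model_bank> %d stacked models (%d folds x %d iterations), %d features, %s compression\n",
    length(x$models), x$config$k_folds, x$config$n_iterations,
    length(x$feature_ids), x$config$bank_compression
  ))
  invisible(x)
}

#' Score new subjects with the bagged ensemble
#'
#' Each subject's score is the median (or mean, per the bank's
#' `bank_compression`) of the predictions of every stored stacked model.
#'
#' @param bank A `model_bank`.
#' @param features Feature matrix whose columns match the bank's training
#'   features.
#' @return Numeric score vector.
#' @export
predict_bank <- function(bank, features) {
  stopifnot(inherits(bank, "model_bank"))
  features <- as.matrix(features)
  check_feature_ids(colnames(features), bank$feature_ids)
  features <- features[, bank$feature_ids, drop = FALSE]
  preds <- vapply(
    bank$models,
    function(m) predict(m$model, features, type = "stack"),
    numeric(nrow(features))
  )
  if (nrow(features) == 1L) preds <- matrix(preds, nrow = 1L)
  reducer <- switch(bank$config$bank_compression,
    median = stats::median,
    mean = mean
  )
  apply(preds, 1, reducer)
}

#' Write OOF scores and the bank manifest
#'
#' Serialises per-subject OOF scores to CSV and a JSON manifest describing
#' the bank (configuration, feature ids, per-model iteration/fold tags and
#' training-set sizes). Model objects themselves stay in memory; they are
#' reproducible from the cohort, configuration and seed.
#'
#' @param oof An `oof_result`.
#' @param bank A `model_bank`.
#' @param dir Output directory.
#' @return Invisibly, the file paths.
#' @export
write_oof_result <- function(oof, bank, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "oof_scores.csv")
  js <- file.path(dir, "model_bank_manifest.json")
  utils::write.csv(oof$scores, csv, row.names = FALSE, fileEncoding = "UTF-8")
  cfg <- bank$config
  cfg$en_penalty_strength <- if (is.null(cfg$en_penalty_strength)) "cv" else cfg$en_penalty_strength
  jsonlite::write_json(
    list(
      config = unclass(cfg),
      n_models = length(bank$models),
      feature_ids = bank$feature_ids,
      models = lapply(bank$models, function(m) {
        list(
          iteration = m$iteration, fold = m$fold,
          n_train = length(m$train_subjects)
        )
      })
    ),
    js,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv, js))
}
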