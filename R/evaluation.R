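#' Confusion matrix, sensitivity and specificity
#'
#' @param test_result Logical or 0/1 vector of test positivity.
#' @param label Binary disease vector (CAD+ = 1).
#' @return List with `confusion` (named counts TP, FP, FN, TN),
#'   `sensitivity` = TP/(TP+FN) and `specificity` = TN/(TN+FP).
#' @export
confusion_and_rates <- function(test_result, label) {
  test_result <- as.integer(test_result)
  stopifnot_binary(test_result, "test_result")
  stopifnot_binary(label, "label")
  if (length(test_result) != length(label)) stop("length mismatch", call. = FALSE)
  if (sum(label == 1) == 0 || sum(label == 0) == 0) {
    stop("both disease classes must be present", call. = FALSE)
  }
  tp <- sum(test_result == 1 & label == 1)
  fp <- sum(test_result == 1 & label == 0)
  fn <- sum(test_result == 0 & label == 1)
  tn <- sum(test_result == 0 & label == 0)
  list(
    confusion = c(TP = tp, FP = fp, FN = fn, TN = tn),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp)
  )
}

#' Diagnostic odds ratio from a 2x2 table
#'
#' Cross-product odds ratio (TP x TN) / (FP x FN) with a 95% confidence
#' interval from the normal approximation on the log scale,
#' SE = sqrt(1/TP + 1/FP + 1/FN + 1/TN).
#'
#' @param confusion Named counts `TP`, `FP`, `FN`, `TN` (as returned by
#'   [confusion_and_rates()]), or a list containing such a `confusion`
#'   element.
#' @param conf_level Confidence level.
#' @param continuity Add 0.5 to every cell (required when a cell is zero).
#' @return List with `estimate`, `ci_lower`, `ci_upper`.
#' @export
odds_ratio <- function(confusion, conf_level = 0.95, continuity = FALSE) {
  if (is.list(confusion) && !is.null(confusion$confusion)) {
    confusion <- confusion$confusion
  }
  cc <- confusion[c("TP", "FP", "FN", "TN")]
  if (anyNA(cc)) stop("confusion needs named counts TP, FP, FN, TN", call. = FALSE)
  if (any(cc == 0) && !continuity) {
    stop("zero cell in 2x2 table; set continuity = TRUE for the 0.5 correction",
      call. = FALSE
    )
  }
  if (continuity) cc <- cc + 0.5
  est <- (cc[["TP"]] * cc[["TN"]]) / (cc[["FP"]] * cc[["FN"]])
  se <- sqrt(sum(1 / cc))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(
    estimate = est,
    ci_lower = exp(log(est) - z * se),
    ci_upper = exp(log(est) + z * se)
  )
}

#' ROC area under the curve
#'
#' The Mann-Whitney probability that a random diseased subject scores
#' above a random non-diseased one, with ties counted half; identical to
#' the trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric score vector.
#' @param label Binary disease vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, label) {
  stopifnot_binary(label, "label")
  if (sum(label == 1) == 0 || sum(label == 0) == 0) {
    stop("both disease classes must be present", call. = FALSE)
  }
  rank_auc(scores, label)
}

#' Negative predictive value at a given prevalence
#'
#' NPV by Bayes' rule:
#' `spec (1 - p) / (spec (1 - p) + (1 - sens) p)`. For a rule-out test
#' this quantifies how confidently a negative result excludes disease and
#' degrades as prevalence rises.
#'
#' @param sensitivity,specificity Test operating characteristics in
#'   \[0, 1\].
#' @param prevalence Disease prevalence in \[0, 1\]; may be a vector.
#' @return NPV, vectorised over `prevalence`; a zero denominator yields 0.
#' @export
npv_at_prevalence <- function(sensitivity, specificity, prevalence) {
  stopifnot(
    all(sensitivity >= 0 & sensitivity <= 1),
    all(specificity >= 0 & specificity <= 1),
    all(prevalence >= 0 & prevalence <= 1)
  )
  num <- specificity * (1 - prevalence)
  den <- num + (1 - sensitivity) * prevalence
  ifelse(den == 0, 0, num / den)
}

#' Implied population prevalence from the referral cascade
#'
#' In the diagnostic workflow, only a fraction of symptomatic patients is
#' referred to catheterization, and only a fraction of those has
#' obstructive disease confirmed; their product is the disease prevalence
#' in the overall symptomatic population.
#'
#' @param referral_rate Fraction referred to invasive catheterization.
#' @param confirmation_yield Fraction of referred patients with confirmed
#'   disease.
#' @return Implied prevalence.
#' @export
implied_prevalence <- function(referral_rate = 0.10, confirmation_yield = 0.38) {
  stopifnot(
    referral_rate >= 0, referral_rate <= 1,
    confirmation_yield >= 0, confirmation_yield <= 1
  )
  referral_rate * confirmation_yield
}

#' Subgroup performance table
#'
#' Sensitivity and specificity within each named subgroup. A rate whose
#' class is absent from the subgroup is reported as `NA` with a reason.
#'
#' @param test_result Logical or 0/1 test positivity.
#' @param label Binary disease vector.
#' @param subgroups Named list of logical membership vectors.
#' @return Data frame: `subgroup`, `n`, `n_pos`, `n_neg`, `sensitivity`,
#'   `specificity`, `note`.
#' @export
subgroup_report <- function(test_result, label, subgroups) {
  test_result <- as.integer(test_result)
  rows <- lapply(names(subgroups), function(nm) {
    m <- subgroups[[nm]]
    if (!any(m)) stop(sprintf("subgroup '%s' is empty", nm), call. = FALSE)
    tr <- test_result[m]
    lb <- label[m]
    n_pos <- sum(lb == 1)
    n_neg <- sum(lb == 0)
    sens <- if (n_pos > 0) sum(tr == 1 & lb == 1) / n_pos else NA_real_
    spec <- if (n_neg > 0) sum(tr == 0 & lb == 0) / n_neg else NA_real_
    note <- paste(c(
      if (n_pos == 0) "no positives: sensitivity undefined",
      if (n_neg == 0) "no negatives: specificity undefined"
    ), collapse = "; ")
    data.frame(
      subgroup = nm, n = sum(m), n_pos = n_pos, n_neg = n_neg,
      sensitivity = sens, specificity = spec,
      note = if (nzchar(note)) note else "",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Confounder-adjusted odds ratios
#'
#' Multivariate logistic regression of disease status on test positivity
#' plus clinical covariates, by maximum likelihood. Each predictor's
#' exponentiated coefficient is its odds ratio adjusted for the others,
#' with Wald 95% confidence interval and p-value; rows are sorted by
#' descending odds ratio.
#'
#' @param test_result Logical or 0/1 test positivity.
#' @param label Binary disease outcome.
#' @param covariates Data frame of covariates (binary or continuous).
#' @param conf_level Confidence level for the Wald intervals.
#' @return Data frame: `predictor`, `odds_ratio`, `ci_lower`, `ci_upper`,
#'   `p_value`.
#' @export
adjusted_odds_ratios <- function(test_result, label, covariates = NULL,
                                 conf_level = 0.95) {
  test_result <- as.integer(test_result)
  df <- data.frame(.label = label, test_positive = test_result)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    df <- cbind(df, as.data.frame(covariates))
  }
  mm <- stats::model.matrix(.label ~ ., data = df)
  if (qr(mm)$rank < ncol(mm)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  fit <- suppressWarnings(
    stats::glm(.label ~ ., data = df, family = stats::binomial())
  )
  co <- summary(fit)$coefficients
  if (!fit$converged || any(abs(co[, "Estimate"]) > 15) ||
      any(co[, "Std. Error"] > 100)) {
    stop(paste(
      "logistic fit did not converge (possible separation);",
      "consider a penalized fallback"
    ), call. = FALSE)
  }
  co <- co[rownames(co) != "(Intercept)", , drop = FALSE]
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  out <- data.frame(
    predictor = rownames(co),
    odds_ratio = exp(co[, "Estimate"]),
    ci_lower = exp(co[, "Estimate"] - z * co[, "Std. Error"]),
    ci_upper = exp(co[, "Estimate"] + z * co[, "Std. Error"]),
    p_value = co[, "Pr(>|z|)"],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out[order(-out$odds_ratio), ]
}

#' Pearson correlation between the two base learners' scores
#'
#' @param en_scores,rf_scores Equal-length numeric vectors (length >= 3)
#'   with nonzero variance.
#' @return Sample Pearson correlation coefficient.
#' @export
model_correlation <- function(en_scores, rf_scores) {
  if (length(en_scores) != length(rf_scores) || length(en_scores) < 3) {
    stop("need equal-length vectors of length >= 3", call. = FALSE)
  }
  if (stats::sd(en_scores) == 0 || stats::sd(rf_scores) == 0) {
    stop("zero variance in scores", call. = FALSE)
  }
  stats::cor(en_scores, rf_scores)
}

#' Permutation feature importance by physiological category
#'
#' Model-agnostic importance of each feature: the mean drop in ensemble
#' ROC-AUC when that feature's column is shuffled, over `n_perm` shuffles,
#' scored with [predict_bank()]. Per-feature drops are floored at zero,
#' summed within each physiological category and normalised to proportions
#' summing to one.
#'
#' @param bank A `model_bank`.
#' @param cohort A `cad_cohort` whose features include the bank's.
#' @param n_perm Shuffles per feature.
#' @param seed Integer seed.
#' @param max_models Optional cap on the number of bank models used for
#'   scoring (the first `max_models` in bank order), trading precision for
#'   speed.
#' @param subjects Optional subject indices to evaluate on (default all).
#' @return List with `category` (named proportion vector, descending) and
#'   `per_feature` (data frame: feature_id, category, auc_drop).
#' @export
category_importance <- function(bank, cohort, n_perm = 5, seed = 1L,
                                max_models = NULL, subjects = NULL) {
  stopifnot(inherits(bank, "model_bank"), inherits(cohort, "cad_cohort"))
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  meta <- cohort$feature_meta
  if (!all(bank$feature_ids %in% meta$feature_id)) {
    stop("feature_meta does not cover all bank features", call. = FALSE)
  }
  if (!is.null(subjects)) cohort <- subset_cohort(cohort, subjects)
  if (!is.null(max_models) && max_models < length(bank$models)) {
    bank$models <- bank$models[seq_len(max_models)]
  }
  x <- cohort$features[, bank$feature_ids, drop = FALSE]
  y <- cohort$label
  base_auc <- roc_auc(predict_bank(bank, x), y)
  drops <- with_seed(derive_seed(seed, 633L), {
    vapply(bank$feature_ids, function(fid) {
      mean(vapply(seq_len(n_perm), function(r) {
        xp <- x
        xp[, fid] <- x[sample.int(nrow(x)), fid]
        base_auc - roc_auc(predict_bank(bank, xp), y)
      }, numeric(1)))
    }, numeric(1))
  })
  per_feature <- data.frame(
    feature_id = bank$feature_ids,
    category = meta$category[match(bank$feature_ids, meta$feature_id)],
    auc_drop = unname(drops),
    stringsAsFactors = FALSE
  )
  clipped <- pmax(per_feature$auc_drop, 0)
  all_cats <- unique(meta$category)
  by_cat <- tapply(clipped, factor(per_feature$category, levels = all_cats), sum)
  by_cat[is.na(by_cat)] <- 0
  total <- sum(by_cat)
  category <- if (total > 0) by_cat / total else {
    warning("no positive importance; returning zero shares", call. = FALSE)
    by_cat * 0
  }
  list(
    category = sort(unlist(as.list(category)), decreasing = TRUE),
    per_feature = per_feature
  )
}
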