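test_that("sample weights equalise the four sex-by-class masses", {
  # cell counts implied by a 641/513 class split with 26.7% / 64.5% female
  label <- rep(c(1, 0), c(641, 513))
  sex <- c(rep(c(1, 0), c(171, 470)), rep(c(1, 0), c(331, 182)))
  w <- compute_sample_weights(label, sex)

  # arithmetic oracle N / (4 n_c)
  expect_equal(unique(round(w[label == 0 & sex == 1], 4)), 0.8716)
  expect_equal(unique(round(w[label == 0 & sex == 0], 4)), 1.5852)
  expect_equal(unique(round(w[label == 1 & sex == 1], 4)), 1.6871)
  expect_equal(unique(round(w[label == 1 & sex == 0], 4)), 0.6138)

  masses <- tapply(w, paste(label, sex), sum)
  expect_true(all(abs(masses - 1154 / 4) < 1e-9))

  # balanced cells are a fixed point
  expect_equal(
    compute_sample_weights(rep(c(1, 0), each = 10), rep(c(1, 0), 10)),
    rep(1, 20)
  )

  # an empty cell is an error naming the cell
  expect_error(
    compute_sample_weights(rep(c(1, 0), c(641, 513)), rep(0, 1154)),
    "F\\+"
  )
})

test_that("stratified folds partition subjects with near-proportional classes", {
  label <- rep(c(1, 0), c(641, 513))
  folds <- stratified_folds(label, 5, seed = 3)
  expect_setequal(unique(folds), 1:5)
  expect_length(folds, 1154)
  pos_per_fold <- table(folds[label == 1])
  neg_per_fold <- table(folds[label == 0])
  expect_true(all(pos_per_fold %in% c(128, 129)))
  expect_true(all(neg_per_fold %in% c(102, 103)))

  # exact divisibility: 5 positives in 5 folds gives one each
  lab10 <- rep(c(1, 0), each = 5)
  f10 <- stratified_folds(lab10, 5, seed = 1)
  expect_true(all(table(f10[lab10 == 1]) == 1))

  expect_identical(folds, stratified_folds(label, 5, seed = 3))
  expect_false(identical(folds, stratified_folds(label, 5, seed = 4)))
  expect_error(stratified_folds(rep(c(1, 0), c(3, 50)), 5), "fewer than")
})

test_that("the stack averages its base learners and handles degenerate targets", {
  set.seed(5)
  x <- matrix(rnorm(600), 100, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- as.integer(x[, 1] + rnorm(100, sd = 0.5) > 0)
  m <- train_stack(x, y, config = fast_train(), seed = 7)
  p <- predict(m, x, type = "all")
  expect_equal(p[, "stack"], (p[, "en"] + p[, "rf"]) / 2)

  # near-constant target: predictions hug the constant
  y0 <- rep(0L, 100); y0[c(3, 50)] <- 1L
  m0 <- train_stack(x, y0, config = fast_train(), seed = 8)
  expect_lt(max(abs(predict(m0, x))), 0.6)
  expect_lt(mean(predict(m0, x)), 0.2)

  # strong linear signal generalises
  co_tr <- generate_cohort(cohort_spec(
    n_pos = 150, n_neg = 150, female_frac_pos = 0.5, female_frac_neg = 0.5,
    features_per_category = fpc(linear = 2, null = 4),
    linear_effect = 2.0, seed = 9
  ))
  co_te <- generate_cohort(cohort_spec(
    n_pos = 150, n_neg = 150, female_frac_pos = 0.5, female_frac_neg = 0.5,
    features_per_category = fpc(linear = 2, null = 4),
    linear_effect = 2.0, seed = 10
  ))
  ms <- train_stack(co_tr$features, co_tr$label, config = fast_train(), seed = 11)
  expect_gt(roc_auc(predict(ms, co_te$features), co_te$label), 0.9)

  expect_error(
    train_stack(matrix(c(1, Inf, 2, 3), 2, 2, dimnames = list(NULL, c("a", "b"))),
      c(0, 1),
      config = fast_train()
    ),
    "non-finite|per class"
  )
})

test_that("a model depends only on its training rows (naivety)", {
  co <- null_cohort(60, 60, p = 5, seed = 21)
  folds <- stratified_folds(co$label, 3, seed = 22)
  train_idx <- which(folds != 1)
  w <- compute_sample_weights(co$label[train_idx], co$sex[train_idx])
  fit1 <- train_stack(co$features[train_idx, ], co$label[train_idx], w,
    config = fast_train(), seed = 23
  )
  # perturb a held-out subject; retrain on the identical training rows
  co2 <- co
  co2$features[which(folds == 1)[1], ] <- 99
  fit2 <- train_stack(co2$features[train_idx, ], co2$label[train_idx], w,
    config = fast_train(), seed = 23
  )
  newx <- matrix(rnorm(50), 10, 5, dimnames = list(NULL, colnames(co$features)))
  expect_identical(predict(fit1, newx), predict(fit2, newx))
})

test_that("run_oof stores k x n_iterations tagged models and naive predictions", {
  co <- null_cohort(70, 60, p = 5, seed = 31)
  fit <- run_oof(co, colnames(co$features), fast_train(k_folds = 5, n_iterations = 3, seed = 32))
  expect_length(fit$bank$models, 15)
  tags <- do.call(rbind, lapply(fit$bank$models, function(m) {
    data.frame(iteration = m$iteration, fold = m$fold)
  }))
  expect_equal(sort(unique(tags$iteration)), 1:3)
  expect_true(all(table(tags$iteration) == 5))

  # every subject scored in every iteration, by a model that excluded it
  expect_false(anyNA(fit$oof$pred_matrix))
  expect_equal(dim(fit$oof$pred_matrix), c(130, 3))
  for (m in fit$bank$models) {
    expect_lt(length(m$train_subjects), 130)
  }
  expect_equal(fit$oof$scores$oof_score, rowMeans(fit$oof$pred_matrix))

  # single-iteration case: the score IS the one naive prediction
  fit1 <- run_oof(co, colnames(co$features), fast_train(k_folds = 5, n_iterations = 1, seed = 33))
  expect_equal(fit1$oof$scores$oof_score, fit1$oof$pred_matrix[, 1])

  # determinism
  fit_again <- run_oof(co, colnames(co$features), fast_train(k_folds = 5, n_iterations = 3, seed = 32))
  expect_equal(fit$oof$scores, fit_again$oof$scores)
})

test_that("OOF predictions on label-independent features stay at chance", {
  set.seed(41)
  aucs <- vapply(1:15, function(r) {
    co <- null_cohort(80, 80, p = 6, seed = 400 + r)
    fit <- run_oof(
      co, colnames(co$features),
      fast_train(k_folds = 5, n_iterations = 2, seed = r)
    )
    roc_auc(fit$oof$scores$oof_score, co$label)
  }, numeric(1))
  ci <- t.test(aucs, mu = 0.5)$conf.int
  expect_lt(ci[1], 0.5)
  expect_gt(ci[2], 0.5)
})

test_that("predict_bank compresses the ensemble by its configured reducer", {
  co <- generate_cohort(cohort_spec(
    n_pos = 100, n_neg = 100, female_frac_pos = 0.5, female_frac_neg = 0.5,
    features_per_category = fpc(linear = 2, null = 3),
    linear_effect = 1.5, seed = 51
  ))
  fit <- run_oof(co, colnames(co$features), fast_train(k_folds = 3, n_iterations = 3, seed = 52))
  newco <- generate_cohort(cohort_spec(
    n_pos = 100, n_neg = 100, female_frac_pos = 0.5, female_frac_neg = 0.5,
    features_per_category = fpc(linear = 2, null = 3),
    linear_effect = 1.5, seed = 53
  ))

  # median reducer equals a direct median over per-model predictions
  per_model <- sapply(
    fit$bank$models,
    function(m) predict(m$model, newco$features, type = "stack")
  )
  expect_equal(
    predict_bank(fit$bank, newco$features),
    apply(per_model, 1, median)
  )
  bank_mean <- fit$bank
  bank_mean$config$bank_compression <- "mean"
  expect_equal(
    predict_bank(bank_mean, newco$features),
    rowMeans(per_model)
  )

  # new-cohort AUC tracks the OOF AUC on a strong signal
  auc_new <- roc_auc(predict_bank(fit$bank, newco$features), newco$label)
  auc_oof <- roc_auc(fit$oof$scores$oof_score, co$label)
  expect_lt(abs(auc_new - auc_oof), 0.05)

  # column mismatch is a descriptive error
  bad <- newco$features[, -1]
  expect_error(predict_bank(fit$bank, bad), "missing")
})

test_that("sample weighting reduces the sex shift in disease-negative scores", {
  # features proxy sex, sex confounds disease: unweighted training lets the
  # models score female CAD- subjects higher than male CAD- subjects
  set.seed(61)
  n_pos <- 300; n_neg <- 300
  label <- rep(c(1L, 0L), c(n_pos, n_neg))
  sex <- c(rbinom(n_pos, 1, 0.267), rbinom(n_neg, 1, 0.645))
  x <- matrix(rnorm(600 * 4), 600, 4, dimnames = list(NULL, paste0("f", 1:4)))
  x <- x + 1.5 * sex

  w <- compute_sample_weights(label, sex)
  m_w <- train_stack(x, label, w, config = fast_train(), seed = 62)
  m_u <- train_stack(x, label, rep(1, 600), config = fast_train(), seed = 62)
  gap <- function(m) {
    p <- predict(m, x)
    abs(mean(p[label == 0 & sex == 1]) - mean(p[label == 0 & sex == 0]))
  }
  expect_lt(gap(m_w), gap(m_u))
})

test_that("OOF scores and the bank manifest serialise", {
  co <- null_cohort(40, 40, p = 4, seed = 71)
  fit <- run_oof(co, colnames(co$features), fast_train(k_folds = 4, n_iterations = 2, seed = 72))
  dir <- withr::local_tempdir()
  paths <- write_oof_result(fit$oof, fit$bank, dir)
  back <- read.csv(paths[1])
  expect_equal(back$oof_score, fit$oof$scores$oof_score)
  man <- jsonlite::read_json(paths[2])
  expect_equal(man$n_models, 8)
  expect_equal(man$config$k_folds, 4)
})
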