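test_that("balanced subset draws exactly per_cell from each sex-by-class cell", {
  co <- generate_cohort(cohort_spec(
    n_pos = 300, n_neg = 300,
    female_frac_pos = 0.4, female_frac_neg = 0.6,
    features_per_category = fpc(null = 2), seed = 9
  ))
  idx <- build_balanced_subset(co, per_cell = 50, seed = 4)
  expect_length(idx, 200)
  expect_false(anyDuplicated(idx) > 0)
  cells <- table(co$label[idx], co$sex[idx])
  expect_true(all(cells == 50))
  expect_identical(idx, build_balanced_subset(co, per_cell = 50, seed = 4))
  expect_false(identical(idx, build_balanced_subset(co, per_cell = 50, seed = 5)))

  # per_cell equal to the smallest cell exhausts it; one more errors,
  # naming the deficient cell
  m <- min(table(co$label, co$sex))
  idx2 <- build_balanced_subset(co, per_cell = m, seed = 1)
  expect_equal(length(idx2), 4 * m)
  expect_error(build_balanced_subset(co, per_cell = m + 1, seed = 1), "cell")
})

test_that("Welch t-screen is calibrated under the null and powered under shift", {
  # type-I: pass rate approximately the nominal 1% over simulated nulls
  reps <- 2000
  set.seed(11)
  hits <- 0
  for (r in seq_len(reps)) {
    v <- rnorm(416)
    lab <- rep(c(1, 0), each = 208)
    hits <- hits + screen_t(v, lab, 0.01)$pass
  }
  # binomial(2000, 0.01): mean 20, sd 4.45
  expect_gt(hits, 5)
  expect_lt(hits, 40)

  # power oracle: noncentral t via power.t.test at d = 0.5, n = 208/208
  oracle_power <- power.t.test(
    n = 208, delta = 0.5, sd = 1, sig.level = 0.01
  )$power
  expect_gt(oracle_power, 0.99)
  set.seed(12)
  passes <- vapply(1:100, function(r) {
    v <- c(rnorm(208, 0.5), rnorm(208))
    screen_t(v, rep(c(1, 0), each = 208), 0.01)$pass
  }, logical(1))
  expect_gte(mean(passes), 0.97)

  # degenerate constants
  expect_equal(screen_t(rep(1, 20), rep(c(1, 0), each = 10))$p_value, 1)
  expect_false(screen_t(rep(1, 20), rep(c(1, 0), each = 10))$pass)
})

test_that("AUC screen point estimate, CI behaviour and inverse branch", {
  cfg <- fast_screen(seed = 21)
  lab <- rep(c(1, 0), each = 50)

  # perfect separation
  res <- screen_auc(c(rnorm(50, 10), rnorm(50)), lab, cfg)
  expect_equal(res$auc, 1.0)
  expect_equal(res$lower_ci, 1.0)
  expect_true(res$pass)
  expect_false(res$pass_inverse)

  # point AUC agrees with the pairwise oracle, including ties
  set.seed(22)
  v <- sample(rep(1:5, 20))
  expect_equal(screen_auc(v, lab, cfg)$auc, slow_auc(v, lab))

  # population AUC 0.25 (negated unit shift of d = 1.349 gives pnorm(-1.349/sqrt 2) ~ 0.17;
  # use a direct construction): strongly inverse feature passes via upper CI < 0.48
  set.seed(23)
  lab2 <- rep(c(1, 0), each = 208)
  v2 <- c(rnorm(208, -0.95), rnorm(208)) # population AUC = pnorm(-0.95/sqrt(2)) ~ 0.25
  res2 <- screen_auc(v2, lab2, cfg)
  expect_lt(res2$upper_ci, 0.48)
  expect_true(res2$pass)
  expect_true(res2$pass_inverse)

  # null calibration: few pure-noise features pass at n = 208/208
  set.seed(24)
  passes <- vapply(1:150, function(r) {
    screen_auc(rnorm(416), lab2, cfg, seed = r)$pass
  }, logical(1))
  expect_lt(mean(passes), 0.05)
})

test_that("MI screen anchors at 1 under independence and detects variance signal", {
  cfg <- fast_screen(seed = 31)
  lab <- rep(c(1, 0), each = 208)

  # independence: ratio concentrates near 1 and passes are rare (the
  # bootstrap's duplicate draws bias MI slightly upward, so the screen's
  # null size is a few percent, not zero)
  set.seed(32)
  null_res <- lapply(1:60, function(r) screen_mi(rnorm(416), lab, cfg, seed = r))
  expect_lt(abs(mean(vapply(null_res, `[[`, numeric(1), "ratio")) - 1), 0.25)
  expect_lt(mean(vapply(null_res, `[[`, logical(1), "pass")), 0.1)

  # deterministic relationship: ratio far above the bound
  res <- screen_mi(as.numeric(lab), lab, cfg)
  expect_gt(res$ratio, 5)
  expect_true(res$pass)

  # constant values carry no information
  res0 <- screen_mi(rep(2, 416), lab, cfg)
  expect_equal(res0$ratio, 0)
  expect_false(res0$pass)

  # equal-mean variance-ratio-4 features: MI passes often while t rarely does
  set.seed(33)
  mi_pass <- t_pass <- logical(40)
  for (r in 1:40) {
    v <- c(rnorm(208, 0, 2), rnorm(208, 0, 1))
    mi_pass[r] <- screen_mi(v, lab, cfg, seed = 100 + r)$pass
    t_pass[r] <- screen_t(v, lab, 0.01)$pass
  }
  expect_gt(mean(mi_pass), 0.8)
  expect_lt(mean(t_pass), 0.2)
})

test_that("select_features unions the three screens and recovers planted signal", {
  co <- generate_cohort(cohort_spec(
    n_pos = 210, n_neg = 210,
    female_frac_pos = 0.5, female_frac_neg = 0.5,
    features_per_category = fpc(
      linear = c(10, 10), nonlinear = c(10, 10), inverse = c(5, 5),
      null = c(75, 75), category = c("arterial_compliance", "conduction")
    ),
    linear_effect = 0.8, nonlinear_effect = 4, seed = 41
  ))
  subset <- build_balanced_subset(co, per_cell = 80, seed = 42)
  cfg <- screen_config(
    n_bootstrap = 300, n_permutation = 100, per_cell = 80, seed = 43
  )
  res <- select_features(co, subset, cfg)

  meta <- co$feature_meta
  is_sel <- meta$feature_id %in% res$selected
  recall <- mean(is_sel[meta$role != "null"])
  false_sel <- mean(is_sel[meta$role == "null"])
  expect_gt(recall, 0.8)
  expect_lt(false_sel, 0.1)

  # structural invariants of the result
  expect_identical(
    res$selected,
    res$stats$feature_id[res$stats$pass_t | res$stats$pass_auc | res$stats$pass_mi]
  )
  expect_equal(sum(res$combo_counts), length(res$selected))

  # monotonicity: loosening thresholds never shrinks the selection
  looser <- screen_config(
    p_threshold = 0.05, auc_lower_bound = 0.51,
    n_bootstrap = 300, n_permutation = 100, per_cell = 80, seed = 43
  )
  res2 <- apply_screen_thresholds(res$stats, looser)
  expect_true(all(res$selected %in% res2$selected))

  # screening must only see the subset: statistics are unchanged when
  # subjects outside the subset are perturbed
  co2 <- co
  outside <- setdiff(seq_along(co$label), subset)
  co2$features[outside, ] <- co2$features[outside, ] + 100
  res3 <- select_features(co2, subset, cfg)
  expect_identical(res$stats, res3$stats)
})

test_that("an all-null library yields a selection consistent with combined test sizes", {
  co <- null_cohort(210, 210, p = 120, seed = 51)
  subset <- build_balanced_subset(co, per_cell = 80, seed = 52)
  cfg <- screen_config(n_bootstrap = 300, n_permutation = 100, per_cell = 80, seed = 53)
  res <- suppressWarnings(select_features(co, subset, cfg))
  # union of three tests each with size ~1-5%: well under 15% of 120
  expect_lt(length(res$selected), 18)
})

test_that("a perfectly separating feature is selected by all three tests", {
  co <- null_cohort(60, 60, p = 4, seed = 61)
  co$features[, 2] <- co$label * 10 + rnorm(120, sd = 0.01)
  subset <- seq_along(co$label)
  res <- select_features(co, subset, fast_screen(seed = 62))
  row <- res$stats[2, ]
  expect_true(row$pass_t && row$pass_auc && row$pass_mi)
  expect_true(co$feature_meta$feature_id[2] %in% res$selected)
})

test_that("screening round-trips to disk", {
  co <- null_cohort(40, 40, p = 3, seed = 71)
  res <- suppressWarnings(
    select_features(co, seq_along(co$label), fast_screen(seed = 72))
  )
  dir <- withr::local_tempdir()
  paths <- write_screen_result(res, dir)
  back <- read.csv(paths[1])
  expect_equal(back$auc_point, res$stats$auc_point)
  js <- jsonlite::read_json(paths[2])
  expect_equal(js$n_selected, length(res$selected))
})
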