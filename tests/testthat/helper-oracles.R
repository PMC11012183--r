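# Independent oracles and small fixture builders used across the suite.
# Oracles deliberately avoid the package's internal code paths.

# Brute-force Mann-Whitney AUC by pairwise comparison (ties count half).
slow_auc <- function(values, labels) {
  pos <- values[labels == 1]
  neg <- values[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Exhaustive cut-point oracle: search every observed score (and midpoints
# between adjacent scores) for the largest threshold keeping sensitivity
# at or above target.
oracle_cut_point <- function(scores, label, target) {
  pos <- scores[label == 1]
  u <- sort(unique(scores))
  cand <- sort(unique(c(u, head(u, -1) + diff(u) / 2)))
  feasible <- cand[vapply(cand, function(t) mean(pos >= t) >= target, logical(1))]
  max(feasible)
}

# Compact feature-library matrix for small cohorts.
fpc <- function(linear = 0, nonlinear = 0, inverse = 0, null = 0,
                category = "arterial_compliance") {
  k <- length(category)
  m <- cbind(
    linear = rep_len(linear, k), nonlinear = rep_len(nonlinear, k),
    inverse = rep_len(inverse, k), null = rep_len(null, k)
  )
  rownames(m) <- category
  m
}

# All-null cohort: features carry no class signal.
null_cohort <- function(n_pos, n_neg, p = 6, seed = 1,
                        female_frac_pos = 0.5, female_frac_neg = 0.5) {
  generate_cohort(cohort_spec(
    n_pos = n_pos, n_neg = n_neg,
    female_frac_pos = female_frac_pos, female_frac_neg = female_frac_neg,
    features_per_category = fpc(null = p),
    seed = seed
  ))
}

# Fast training profile: fixed elastic-net penalty (skips internal CV) and
# few shallow trees, for tests where model quality is irrelevant.
fast_train <- function(k_folds = 5, n_iterations = 1, seed = 1) {
  train_config(
    k_folds = k_folds, n_iterations = n_iterations,
    en_penalty_strength = 0.01, rf_n_trees = 25, seed = seed
  )
}

# Small screening profile for unit tests.
fast_screen <- function(seed = 1, ...) {
  screen_config(n_bootstrap = 200, n_permutation = 100, per_cell = 30,
    seed = seed, ...
  )
}
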