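#' Screening configuration
#'
#' Thresholds and resampling sizes for the univariate triple-test feature
#' screen. A feature is retained if it passes at least one of: a Welch
#' t-test at `p_threshold`; a bootstrap ROC-AUC bound (lower CI endpoint
#' above `auc_lower_bound`, or, for inversely predictive features, upper CI
#' endpoint below `auc_inverse_bound`); or a permutation-normalised mutual
#' information ratio whose bootstrap lower CI endpoint exceeds
#' `mi_ratio_bound` (a ratio of 1 means no dependence).
#'
#' @param p_threshold t-test significance level.
#' @param auc_lower_bound Lower AUC bound a feature's bootstrap CI must
#'   clear.
#' @param auc_inverse_bound Upper AUC bound for the inverse-predictivity
#'   branch.
#' @param mi_ratio_bound Bound the MI ratio's bootstrap lower CI endpoint
#'   must exceed.
#' @param confidence Bootstrap confidence level for the AUC and MI-ratio
#'   intervals.
#' @param n_bootstrap Bootstrap resample count.
#' @param n_permutation Label-permutation count for the MI null.
#' @param n_bins Equal-frequency bins used to discretise values for MI.
#' @param per_cell Balanced screening-subset size per sex-by-class cell.
#' @param seed Integer seed; per-feature resampling streams are derived
#'   from it and the feature index.
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(p_threshold = 0.01,
                          auc_lower_bound = 0.52, auc_inverse_bound = 0.48,
                          mi_ratio_bound = 1.2, confidence = 0.95,
                          n_bootstrap = 1000, n_permutation = 200,
                          n_bins = 10, per_cell = 104, seed = 1L) {
  if (p_threshold <= 0 || p_threshold >= 1) stop("p_threshold must lie in (0, 1)", call. = FALSE)
  if (!(auc_inverse_bound < 0.5 && 0.5 < auc_lower_bound)) {
    stop("need auc_inverse_bound < 0.5 < auc_lower_bound", call. = FALSE)
  }
  if (mi_ratio_bound <= 1) stop("mi_ratio_bound must exceed 1", call. = FALSE)
  if (confidence <= 0 || confidence >= 1) stop("confidence must lie in (0, 1)", call. = FALSE)
  if (per_cell < 2) stop("per_cell must be >= 2", call. = FALSE)
  structure(
    list(
      p_threshold = p_threshold,
      auc_lower_bound = auc_lower_bound, auc_inverse_bound = auc_inverse_bound,
      mi_ratio_bound = mi_ratio_bound, confidence = confidence,
      n_bootstrap = as.integer(n_bootstrap),
      n_permutation = as.integer(n_permutation),
      n_bins = as.integer(n_bins),
      per_cell = as.integer(per_cell), seed = as.integer(seed)
    ),
    class = "screen_config"
  )
}

#' Draw a sex-balanced screening subset
#'
#' Samples exactly `per_cell` subjects without replacement from each of the
#' four sex-by-class cells (female/male crossed with CAD+/CAD-), so that
#' univariate screening sees both sexes evenly. With the default
#' `per_cell = 104` the subset holds 416 subjects: 104 females and 104
#' males per class.
#'
#' @param cohort A `cad_cohort`.
#' @param per_cell Subjects to draw per cell.
#' @param seed Integer seed.
#' @return Integer vector of subject indices into the cohort.
#' @export
build_balanced_subset <- function(cohort, per_cell = 104, seed = 1L) {
  stopifnot(inherits(cohort, "cad_cohort"))
  cells <- cell_of(cohort$label, cohort$sex)
  idx <- with_seed(derive_seed(seed, 811L), {
    unlist(lapply(levels(cells), function(cl) {
      members <- which(cells == cl)
      if (length(members) < per_cell) {
        stop(sprintf(
          "cell %s has %d subjects, fewer than per_cell = %d",
          cl, length(members), per_cell
        ), call. = FALSE)
      }
      sort(sample(members, per_cell))
    }), use.names = FALSE)
  })
  sort(idx)
}

#' Welch t-test screen
#'
#' Two-sample Welch t-test of a feature between classes. A feature passes
#' when `p < p_threshold`. If both classes are constant the statistic is
#' undefined; equal constants give p = 1 (no signal), distinct constants
#' p = 0 (perfect separation).
#'
#' @param values Numeric feature vector.
#' @param labels Binary class vector (CAD+ = 1).
#' @param p_threshold Significance level.
#' @return List with `p_value` and `pass`.
#' @export
screen_t <- function(values, labels, p_threshold = 0.01) {
  stopifnot_binary(labels, "labels")
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  a <- values[labels == 1]
  b <- values[labels == 0]
  if (length(a) == 0 || length(b) == 0) stop("both classes must be non-empty", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (a[1] == b[1]) 1 else 0
  } else {
    p <- stats::t.test(a, b, var.equal = FALSE)$p.value
  }
  list(p_value = p, pass = p < p_threshold)
}

# Mann-Whitney ROC-AUC with ties counted half; equals the trapezoidal area
# under the empirical ROC curve.
rank_auc <- function(values, labels) {
  r <- rank(values, ties.method = "average")
  n1 <- sum(labels == 1)
  n0 <- length(labels) - n1
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Bootstrap ROC-AUC screen
#'
#' Point ROC-AUC (rank statistic, ties counted half) with a percentile
#' bootstrap confidence interval, resampling subjects with replacement
#' within each class. A feature passes when the interval's lower endpoint
#' exceeds `auc_lower_bound`, or — the inverse-predictivity branch — when
#' its upper endpoint falls below `auc_inverse_bound`.
#'
#' @param values Numeric feature vector.
#' @param labels Binary class vector.
#' @param config A [screen_config()].
#' @param seed Optional seed overriding `config$seed`.
#' @return List with `auc`, `lower_ci`, `upper_ci`, `pass`,
#'   `pass_inverse`.
#' @export
screen_auc <- function(values, labels, config = screen_config(), seed = config$seed) {
  stopifnot_binary(labels, "labels")
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  if (length(i1) == 0 || length(i0) == 0) stop("both classes must be non-empty", call. = FALSE)
  point <- rank_auc(values, labels)
  lab <- rep(c(1L, 0L), c(length(i1), length(i0)))
  boot <- with_seed(seed, {
    vapply(seq_len(config$n_bootstrap), function(b) {
      v <- c(
        values[i1[sample.int(length(i1), replace = TRUE)]],
        values[i0[sample.int(length(i0), replace = TRUE)]]
      )
      rank_auc(v, lab)
    }, numeric(1))
  })
  alpha <- (1 - config$confidence) / 2
  ci <- unname(stats::quantile(boot, c(alpha, 1 - alpha)))
  pass_fwd <- ci[1] > config$auc_lower_bound
  pass_inv <- ci[2] < config$auc_inverse_bound
  list(
    auc = point, lower_ci = ci[1], upper_ci = ci[2],
    pass = pass_fwd || pass_inv, pass_inverse = pass_inv
  )
}

# Histogram mutual information (nats) between values discretised into
# equal-frequency bins and a binary label, from a precomputed bin index.
mi_from_bins <- function(bins, labels, n_bins) {
  n <- length(labels)
  tab <- tabulate(bins + n_bins * labels, nbins = 2L * n_bins)
  pxy <- tab / n
  px <- tabulate(bins, nbins = n_bins) / n
  py <- c(1 - mean(labels), mean(labels))
  e <- outer(px, py)
  nz <- pxy > 0
  sum(pxy[nz] * log(pxy[nz] / as.vector(e)[nz]))
}

discretise <- function(values, n_bins) {
  br <- unique(stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(values)))
  findInterval(values, br, all.inside = TRUE)
}

#' Mutual-information screen
#'
#' Histogram mutual information between the discretised feature and the
#' class label, normalised by its mean under label permutation so that a
#' ratio of 1 indicates no dependence. A percentile bootstrap lower
#' confidence endpoint of the ratio must exceed `mi_ratio_bound` for the
#' feature to pass. Unlike the t-test, this screen detects distributional
#' differences with equal means (for example class-dependent variance).
#'
#' @inheritParams screen_auc
#' @return List with `mi`, `ratio`, `ratio_lower_ci`, `pass`.
#' @export
screen_mi <- function(values, labels, config = screen_config(), seed = config$seed) {
  stopifnot_binary(labels, "labels")
  if (anyNA(values)) stop("missing values not allowed", call. = FALSE)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  if (length(i1) == 0 || length(i0) == 0) stop("both classes must be non-empty", call. = FALSE)
  n <- length(values)
  nb <- config$n_bins
  bins <- discretise(values, nb)
  mi_obs <- mi_from_bins(bins, labels, nb)

  with_seed(seed, {
    null_mi <- vapply(seq_len(config$n_permutation), function(p) {
      mi_from_bins(bins, sample(labels), nb)
    }, numeric(1))
    null_mean <- mean(null_mi)
    ratio <- if (null_mean > 0) mi_obs / null_mean else if (mi_obs > 0) Inf else 0

    # The permutation-null mean depends on sample size and bin occupancy,
    # both essentially fixed under within-class resampling, so it is
    # estimated once and reused across bootstrap replicates.
    lab <- rep(c(1L, 0L), c(length(i1), length(i0)))
    boot <- vapply(seq_len(config$n_bootstrap), function(b) {
      v <- c(
        values[i1[sample.int(length(i1), replace = TRUE)]],
        values[i0[sample.int(length(i0), replace = TRUE)]]
      )
      bb <- discretise(v, nb)
      if (null_mean > 0) mi_from_bins(bb, lab, nb) / null_mean else 0
    }, numeric(1))
    alpha <- (1 - config$confidence) / 2
    lower <- unname(stats::quantile(boot, alpha))
    list(
      mi = mi_obs, ratio = ratio, ratio_lower_ci = lower,
      pass = lower > config$mi_ratio_bound
    )
  })
}

#' Run the triple-test screen over all features
#'
#' Applies [screen_t()], [screen_auc()] and [screen_mi()] to every feature
#' using only the balanced subset, and retains the union of passers. The
#' three tests target different mechanisms: the t-test linear mean shifts,
#' the AUC bound monotone (including inverse) separations, and MI general
#' distributional differences.
#'
#' @param cohort A `cad_cohort`.
#' @param subset Integer subject indices, typically from
#'   [build_balanced_subset()].
#' @param config A [screen_config()].
#' @return An object of class `screen_result`: list with `stats` (one row
#'   per feature: statistics and pass flags), `selected` (feature ids, in
#'   library order), `combo_counts` (passing-test combination tabulation),
#'   and `config`.
#' @export
select_features <- function(cohort, subset, config = screen_config()) {
  stopifnot(inherits(cohort, "cad_cohort"))
  if (any(subset < 1 | subset > n_subjects(cohort))) {
    stop("subset indices out of range", call. = FALSE)
  }
  x <- cohort$features[subset, , drop = FALSE]
  if (anyNA(x)) stop("missing feature values in screening subset", call. = FALSE)
  labels <- cohort$label[subset]
  p <- ncol(x)
  if (p < 1) stop("cohort has no features", call. = FALSE)

  rows <- vector("list", p)
  for (j in seq_len(p)) {
    v <- x[, j]
    st <- screen_t(v, labels, config$p_threshold)
    sa <- screen_auc(v, labels, config, seed = derive_seed(config$seed, j, 1L))
    sm <- screen_mi(v, labels, config, seed = derive_seed(config$seed, j, 2L))
    rows[[j]] <- data.frame(
      feature_id = colnames(x)[j],
      t_p_value = st$p_value,
      auc_point = sa$auc, auc_lower_ci = sa$lower_ci, auc_upper_ci = sa$upper_ci,
      mi_ratio = sm$ratio, mi_ratio_lower_ci = sm$ratio_lower_ci,
      pass_t = st$pass, pass_auc = sa$pass, pass_mi = sm$pass,
      stringsAsFactors = FALSE
    )
  }
  stats_df <- do.call(rbind, rows)
  finalize_screen(stats_df, config)
}

# Re-derive pass flags, selection and combination counts from stored
# per-feature statistics under (possibly new) thresholds; bootstrap CIs are
# not recomputed.
apply_screen_thresholds <- function(stats_df, config) {
  stats_df$pass_t <- stats_df$t_p_value < config$p_threshold
  stats_df$pass_auc <- stats_df$auc_lower_ci > config$auc_lower_bound |
    stats_df$auc_upper_ci < config$auc_inverse_bound
  stats_df$pass_mi <- stats_df$mi_ratio_lower_ci > config$mi_ratio_bound
  finalize_screen(stats_df, config)
}

finalize_screen <- function(stats_df, config) {
  any_pass <- stats_df$pass_t | stats_df$pass_auc | stats_df$pass_mi
  selected <- stats_df$feature_id[any_pass]
  combo <- ifelse(any_pass, paste0(
    ifelse(stats_df$pass_t, "t", ""),
    ifelse(stats_df$pass_auc, "+auc", ""),
    ifelse(stats_df$pass_mi, "+mi", "")
  ), NA)
  combo <- sub("^\\+", "", combo)
  combo_counts <- table(combo[!is.na(combo)])
  if (length(selected) == 0) {
    warning("no features passed screening", call. = FALSE)
  }
  structure(
    list(
      stats = stats_df, selected = selected,
      combo_counts = combo_counts, config = config
    ),
    class = "screen_result"
  )
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf(
    "<screen_result> %d of %d features selected\n",
    length(x$selected), nrow(x$stats)
  ))
  if (length(x$combo_counts)) {
    print(sort(x$combo_counts, decreasing = TRUE))
  }
  invisible(x)
}

#' Write screening results
#'
#' Serialises a `screen_result` as a CSV of per-feature statistics and
#' flags plus a JSON sidecar with the configuration and test-combination
#' counts.
#'
#' @param result A `screen_result`.
#' @param dir Output directory.
#' @return Invisibly, the two file paths.
#' @export
write_screen_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "screen_stats.csv")
  js <- file.path(dir, "screen_summary.json")
  utils::write.csv(result$stats, csv, row.names = FALSE, fileEncoding = "UTF-8")
  jsonlite::write_json(
    list(
      config = unclass(result$config),
      n_selected = length(result$selected),
      selected = result$selected,
      combo_counts = as.list(result$combo_counts)
    ),
    js,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(csv, js))
}
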