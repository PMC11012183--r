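#' Select a cut point at a target sensitivity
#'
#' Returns the largest threshold t such that the fraction of diseased
#' subjects with score >= t is at least `target` — the threshold that
#' maximises specificity subject to the sensitivity constraint. Candidate
#' thresholds are the observed positive scores (a larger threshold would
#' lower sensitivity without a compensating specificity gain).
#'
#' @param scores Numeric score vector.
#' @param label Binary class vector (CAD+ = 1).
#' @param target Target sensitivity in (0, 1].
#' @return The threshold (a single number).
#' @export
select_cut_point <- function(scores, label, target = 0.9) {
  stopifnot_binary(label, "label")
  if (target <= 0 || target > 1) stop("target must lie in (0, 1]", call. = FALSE)
  pos <- scores[label == 1]
  if (length(pos) == 0) stop("no positive subjects to calibrate on", call. = FALSE)
  cand <- sort(unique(pos))
  feasible <- vapply(cand, function(t) mean(pos >= t) >= target, logical(1))
  max(cand[feasible])
}

#' Calibrate per-sex cut points
#'
#' Selects one cut point per sex at the target sensitivity from
#' calibration scores (typically the OOF scores of the development
#' cohort), recording the achieved per-sex sensitivity and specificity.
#'
#' @param scores Numeric score vector.
#' @param label Binary class vector.
#' @param sex Binary sex vector (female = 1).
#' @param target Target sensitivity.
#' @return An object of class `cut_points`: list with `target`,
#'   `thresholds` (named: female, male) and `achieved` (per-sex
#'   sensitivity and specificity at the threshold).
#' @export
calibrate_cut_points <- function(scores, label, sex, target = 0.9) {
  stopifnot_binary(sex, "sex")
  thresholds <- c(female = NA_real_, male = NA_real_)
  achieved <- data.frame(
    sex = c("female", "male"), sensitivity = NA_real_, specificity = NA_real_,
    stringsAsFactors = FALSE
  )
  for (s in c("female", "male")) {
    in_sex <- if (s == "female") sex == 1 else sex == 0
    t <- select_cut_point(scores[in_sex], label[in_sex], target)
    thresholds[[s]] <- t
    pos <- in_sex & label == 1
    neg <- in_sex & label == 0
    achieved$sensitivity[achieved$sex == s] <- mean(scores[pos] >= t)
    achieved$specificity[achieved$sex == s] <-
      if (any(neg)) mean(scores[neg] < t) else NA_real_
  }
  structure(
    list(target = target, thresholds = thresholds, achieved = achieved),
    class = "cut_points"
  )
}

#' @export
print.cut_points <- function(x, ...) {
  cat(sprintf(
    "<cut_points> target sensitivity %.0f%%: female %.3f, male %.3f\n",
    100 * x$target, x$thresholds[["female"]], x$thresholds[["male"]]
  ))
  invisible(x)
}

#' Apply per-sex cut points
#'
#' Subtracts each subject's sex-specific cut point from the raw score so
#' that zero delineates the decision: a zeroed score >= 0 is
#' test-positive, < 0 test-negative. A score exactly at the cut point is
#' test-positive, preserving the target sensitivity when ties sit at the
#' cut.
#'
#' @param scores Numeric raw score vector.
#' @param sex Binary sex vector (female = 1).
#' @param cp A `cut_points` object.
#' @return List with `zeroed` (score minus sex-specific threshold) and
#'   `test_positive` (logical).
#' @export
apply_cut_points <- function(scores, sex, cp) {
  stopifnot(inherits(cp, "cut_points"))
  if (anyNA(sex) || !all(sex %in% c(0, 1))) {
    stop("unknown sex category: sex must be coded 0 (male) / 1 (female)", call. = FALSE)
  }
  thr <- ifelse(sex == 1, cp$thresholds[["female"]], cp$thresholds[["male"]])
  if (anyNA(thr)) stop("cut point missing for a sex present in the data", call. = FALSE)
  zeroed <- scores - thr
  list(zeroed = zeroed, test_positive = zeroed >= 0)
}

#' Write cut points to JSON
#'
#' @param cp A `cut_points` object.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_cut_points <- function(cp, path) {
  jsonlite::write_json(
    list(
      target_sensitivity = cp$target,
      thresholds = as.list(cp$thresholds),
      achieved = cp$achieved
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
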