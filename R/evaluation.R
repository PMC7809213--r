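#' Presence-background AUC
#'
#' Probability that a randomly drawn presence scores higher than a randomly
#' drawn background point, with ties counted one half (the rank-sum /
#' Mann-Whitney formulation).
#'
#' @param presence_scores,background_scores non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(presence_scores, background_scores) {
  if (!length(presence_scores) || !length(background_scores)) {
    stopf("auc needs non-empty presence and background scores")
  }
  np <- length(presence_scores)
  nb <- length(background_scores)
  r <- rank(c(presence_scores, background_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nb)
}

#' TSS-optimal threshold
#'
#' Scans every unique observed score as a candidate threshold. At threshold
#' `t`, sensitivity is the fraction of test presences scoring `>= t` and
#' specificity the fraction of background points scoring `< t` (background
#' points serve as pseudo-absences); the True Skill Statistic is
#' `sensitivity + specificity - 1`. Returns the maximizing threshold, ties
#' broken toward the smallest threshold.
#'
#' @param presence_test_scores,background_scores non-empty numeric vectors.
#' @return List with `threshold` and `tss_max`.
#' @export
tss_optimal_threshold <- function(presence_test_scores, background_scores) {
  if (!length(presence_test_scores) || !length(background_scores)) {
    stopf("tss_optimal_threshold needs non-empty score vectors")
  }
  cand <- sort(unique(c(presence_test_scores, background_scores)))
  np <- length(presence_test_scores)
  nb <- length(background_scores)
  # sort-and-sweep: counts of scores >= t via cumulative tallies
  sens <- vapply(cand, function(t) sum(presence_test_scores >= t) / np, 0)
  spec <- vapply(cand, function(t) sum(background_scores < t) / nb, 0)
  tss <- sens + spec - 1
  best <- which.max(tss)  # which.max takes the first (smallest) maximizer
  list(threshold = cand[best], tss_max = tss[best])
}

#' Omission rate at a threshold
#'
#' Fraction of occurrence scores strictly below the threshold (predicted
#' unsuitable). An omission of 0 corresponds to predicting 100\% of the
#' region's occurrences as suitable.
#'
#' @param scores non-empty numeric scores at the region's occurrences.
#' @param threshold binarization threshold.
#' @return Fraction in `[0, 1]`.
#' @export
omission_rate <- function(scores, threshold) {
  if (!length(scores)) stopf("omission_rate needs non-empty scores")
  mean(scores < threshold)
}

#' Binarize a suitability map
#'
#' Cells scoring at or above the threshold become 1 ("suitable"; the
#' boundary cell is suitable by convention), others 0; nodata is preserved.
#'
#' @param map a [grid_map()] or numeric vector/matrix.
#' @param threshold finite binarization threshold.
#' @return Same shape as the input, values in `{0, 1, NA}`.
#' @export
binarize <- function(map, threshold) {
  if (!is.finite(threshold)) stopf("threshold must be finite")
  if (inherits(map, "grid_map")) {
    grid_map((map$values >= threshold) * 1, map$transform)
  } else {
    (map >= threshold) * 1
  }
}
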