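# Evaluation of artefact detection against planted ground truth: confusion
# counts over an eligible probe universe, precision-recall curves across all
# thresholds (precision = TP/(TP+FP), recall = TP/(TP+FN)), and the mean
# absolute deviation from the diagonal of replicate scatter comparisons.

truth_ids <- function(truth) {
  probe_index(truth$x, truth$y, attr(truth, "n_cols"))
}

universe_ids <- function(universe, n_cols) {
  if (is.null(universe)) {
    abort_stainr("an eligible-probe universe is required", "format_error")
  }
  sort(unique(probe_index(universe$x, universe$y, n_cols)))
}

#' Confusion counts of a flag mask against spike ground truth
#'
#' Counts, over the eligible universe, spiked probes that are flagged (TP),
#' unspiked flagged probes (FP), unspiked unflagged probes (TN) and spiked
#' unflagged probes (FN).
#'
#' @param mask a `flag_mask`.
#' @param truth a `spike_truth` on the same grid.
#' @param universe data frame of eligible probes with columns `x`, `y`
#'   (typically [eligible_probes()] of the map, matching spiking
#'   eligibility).
#' @return a one-row tibble `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(mask, truth, universe) {
  if (!identical(unname(grid_dims(mask)),
                 c(attr(truth, "n_rows"), attr(truth, "n_cols")))) {
    abort_stainr("mask and ground truth must share dimensions",
                 "dimension_error")
  }
  ids <- universe_ids(universe, attr(mask, "n_cols"))
  spiked <- ids %in% truth_ids(truth)
  flagged <- mask$flagged[ids]
  tibble(
    TP = sum(spiked & flagged),
    FP = sum(!spiked & flagged),
    TN = sum(!spiked & !flagged),
    FN = sum(spiked & !flagged)
  )
}

#' Precision-recall curve over all thresholds
#'
#' Sweeps the threshold over every distinct score value in descending order;
#' at each threshold the flagged set is `score >= threshold` over the
#' universe, so probes tied at a threshold enter the curve together as a
#' single point (no intra-tie interpolation).
#'
#' @param scores a `noise_grid`.
#' @param truth a `spike_truth` on the same grid with at least one spiked
#'   probe inside the universe.
#' @inheritParams confusion_counts
#' @return a `pr_curve`: tibble `threshold`, `recall`, `precision` with
#'   descending thresholds and attribute `positive_count`.
#' @export
pr_curve <- function(scores, truth, universe) {
  ids <- universe_ids(universe, attr(scores, "n_cols"))
  s <- scores$score[ids]
  label <- ids %in% truth_ids(truth)
  pos <- sum(label)
  if (pos == 0) {
    abort_stainr("no spiked probes in the universe: recall undefined",
                 "format_error")
  }
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; label <- label[ord]
  tp <- cumsum(label)
  flagged <- seq_along(s)
  last_of_tie <- c(s[-1] != s[-length(s)], TRUE)
  tibble(
    threshold = s[last_of_tie],
    recall = tp[last_of_tie] / pos,
    precision = tp[last_of_tie] / flagged[last_of_tie]
  ) |>
    structure(positive_count = pos, n_universe = length(ids),
              class = c("pr_curve", class(tibble())))
}

#' Precision at a target recall
#'
#' Reads the precision at the highest threshold whose recall reaches the
#' target (recall always reaches 1 at the minimum threshold).
#'
#' @param curve a [pr_curve()].
#' @param target_recall recall level in `(0, 1]`.
#' @return the precision, a single number.
#' @export
precision_at_recall <- function(curve, target_recall) {
  if (!is.numeric(target_recall) || target_recall <= 0 || target_recall > 1) {
    abort_stainr("target_recall must lie in (0, 1]", "format_error")
  }
  curve$precision[which(curve$recall >= target_recall)[1]]
}

#' Mean absolute deviation from the replicate diagonal
#'
#' Quantifies replicate scatter: the mean of `|a - b|` over the probesets
#' shared by two expression columns (see [probeset_expression()]). Probesets
#' whose intensity was zeroed by correction carry no information and should
#' be passed in `exclude`.
#'
#' @param a,b tibbles with columns `probeset_id`, `expression`.
#' @param exclude probeset ids to drop, e.g. the `zeroed_probesets` of
#'   [correct_by_probeset_mean()] or the `emptied` of [filter_probesets()].
#' @return the mean absolute deviation, a single number.
#' @export
mad_from_diagonal <- function(a, b, exclude = NULL) {
  joined <- inner_join(a, b, by = "probeset_id", suffix = c("_a", "_b"))
  joined <- joined[!(joined$probeset_id %in% exclude), ]
  if (nrow(joined) == 0) {
    abort_stainr("no shared probesets to compare", "format_error")
  }
  mean(abs(joined$expression_a - joined$expression_b))
}
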