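# The threshold criterion: probe j is flagged as corrupted when its noise
# score (raw or window-smoothed) strictly exceeds a threshold t. Thresholds
# are chosen manually from probe noise plots and replicate scatter plots;
# helpers below tabulate flagged counts across candidate thresholds.

#' Flag probes whose noise score exceeds a threshold
#'
#' Applies the strict threshold criterion `score > t` to a noise-score grid
#' (the window-criterion, when the grid was produced by [window_smooth()]).
#' A probe whose score equals `t` exactly is not flagged.
#'
#' @param scores a `noise_grid`.
#' @param t finite threshold.
#' @return a `flag_mask` (tibble `x`, `y`, `flagged`) recording `t` and the
#'   score kind it was applied to.
#' @export
flag_probes <- function(scores, t) {
  if (!is.numeric(t) || length(t) != 1 || !is.finite(t)) {
    abort_stainr("threshold t must be a single finite number", "format_error")
  }
  dims <- grid_dims(scores)
  new_flag_mask(scores$score > t, dims[["n_rows"]], dims[["n_cols"]],
                threshold = t, source_kind = attr(scores, "kind"))
}

#' Flagged-count table across candidate thresholds
#'
#' Supports the manual threshold choice: how many probes each threshold would
#' flag.
#'
#' @param scores a `noise_grid`.
#' @param thresholds candidate thresholds; defaults to the score deciles from
#'   the 90th to the 99.99th percentile.
#' @return a tibble `threshold`, `n_flagged`, `fraction_flagged`.
#' @export
threshold_table <- function(scores, thresholds = NULL) {
  if (is.null(thresholds)) {
    thresholds <- unname(quantile(scores$score,
                                  c(0.9, 0.95, 0.99, 0.995, 0.999, 0.9999)))
  }
  n <- nrow(scores)
  counts <- vapply(thresholds, function(t) sum(scores$score > t), integer(1))
  tibble(threshold = thresholds, n_flagged = counts,
         fraction_flagged = counts / n)
}

#' Convenience quantile threshold
#'
#' Returns the given quantile of the scores (default 99.9th percentile) as a
#' starting threshold. This is a convenience default only; the intended
#' procedure is manual adjustment against probe noise and replicate scatter
#' plots.
#'
#' @param scores a `noise_grid`.
#' @param probs quantile to use.
#' @export
suggest_threshold <- function(scores, probs = 0.999) {
  unname(quantile(scores$score, probs))
}

#' Fraction of flagged probes per probeset
#'
#' Feeds the coloring of [replicate_scatter_plot()].
#'
#' @param map a [probeset_map()].
#' @param mask a `flag_mask` on the same grid.
#' @return a tibble `probeset_id`, `n_probes`, `n_flagged`, `fraction`.
#' @export
flagged_fraction <- function(map, mask) {
  flags <- mask$flagged[map$probe_id]
  tibble(probeset_id = map$probeset_id, flagged = flags) |>
    group_by(.data$probeset_id) |>
    summarise(n_probes = n(), n_flagged = sum(.data$flagged),
              fraction = mean(.data$flagged), .groups = "drop")
}
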