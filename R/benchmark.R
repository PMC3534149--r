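# End-to-end spike-in benchmark: plant a realistically shaped stain on one
# replicate of a synthetic replicate set, score probes against a
# loess-normalized unspiked replicate, and measure detection precision at a
# recall target for both the raw threshold criterion and the window
# criterion.

#' Benchmark stain detection on a spiked replicate simulation
#'
#' Runs one complete simulation: generate `n_replicates` replicate arrays,
#' plant a disc-plus-halo stain ([stain_mask()]) on the first replicate with
#' log2-normal intensities (`mu_log2 = log2(850)`, `sigma_log2 = 1`,
#' [spike_stain()]), score the spiked array by absolute log2 fold-changes
#' against a loess-normalized unspiked replicate ([fc_noise_scores()] with
#' the detection-limit pseudocount), smooth with [window_smooth()], and read
#' the precision of both criteria at the threshold where recall over the
#' spiked probes reaches `recall` ([precision_at_recall()]).
#'
#' Sub-seeds for the baseline, the stain shape and the planted values are
#' derived deterministically from `seed`, so one integer reproduces the run.
#'
#' @param seed integer seed for the whole run.
#' @param n_rows,n_cols grid dimensions.
#' @param n_replicates replicate arrays to generate.
#' @param recall recall target over the spiked probes.
#' @param k,self_weight window-criterion parameters.
#' @param pseudocount detection-limit pseudocount of the fold-change scores.
#' @param ... further arguments to [stain_mask()] (stain geometry).
#' @return a one-row tibble: `seed`, `n_probes`, `n_spiked`,
#'   `precision_window`, `precision_epsilon`.
#' @examples
#' \donttest{
#' benchmark_stain_detection(seed = 1, n_rows = 120, n_cols = 120)
#' }
#' @export
benchmark_stain_detection <- function(seed, n_rows = 300, n_cols = 300,
                                      n_replicates = 3, recall = 0.85,
                                      k = 25, self_weight = 2,
                                      pseudocount = 16, ...) {
  seed <- as.integer(seed)
  set <- generate_baseline_arrays(n_rows, n_cols, n_replicates, seed = seed)
  shape <- stain_mask(n_rows, n_cols, seed = seed + 1000003L, ...)
  spiked <- spike_stain(set$grids[[1]], shape, seed = seed + 2000003L,
                        map = set$map)
  control <- loess_pair_normalize(set$grids[[2]], spiked$grid)
  raw <- fc_noise_scores(spiked$grid, control, pseudocount = pseudocount,
                         absolute = TRUE)
  smoothed <- window_smooth(raw, k = k, self_weight = self_weight)
  universe <- eligible_probes(set$map)
  tibble(
    seed = seed,
    n_probes = n_rows * n_cols,
    n_spiked = nrow(spiked$truth),
    precision_window = precision_at_recall(
      pr_curve(smoothed, spiked$truth, universe), recall),
    precision_epsilon = precision_at_recall(
      pr_curve(raw, spiked$truth, universe), recall)
  )
}
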