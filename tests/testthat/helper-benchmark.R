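# Shared simulation runs for the heavier end-to-end checks. Results are
# computed once per test session and cached.

.bench_cache <- new.env(parent = emptyenv())

# ten-seed spiked-stain benchmark at full 300x300 scale
stain_benchmark_runs <- function() {
  if (is.null(.bench_cache$runs)) {
    .bench_cache$runs <- dplyr::bind_rows(
      lapply(1:10, function(s) benchmark_stain_detection(seed = s))
    )
  }
  .bench_cache$runs
}

# one correction demo on a heavily stained replicate: a disc covering ~15%
# of a 60x60 grid, the substantial-artefact scenario that correction targets
correction_demo <- function(seed, n = 60, radius = 13, k = 5) {
  set <- generate_baseline_arrays(n, n, 3, seed = seed)
  shape <- stain_mask(n, n, radius = radius, seed = seed + 1000003L)
  sp <- spike_stain(set$grids[[1]], shape, seed = seed + 2000003L,
                    map = set$map)
  ctrl <- loess_pair_normalize(set$grids[[2]], sp$grid)
  sw <- window_smooth(fc_noise_scores(sp$grid, ctrl), k = k)
  t <- suggest_threshold(sw, 1 - 0.9 * mean(shape$flagged))
  mask <- flag_probes(sw, t)
  corrected <- suppressWarnings(
    correct_by_probeset_mean(sp$grid, mask, set$map))
  filtered <- filter_probesets(set$map, mask)
  excl <- union(attr(corrected, "zeroed_probesets"), filtered$emptied)
  mad_of <- function(grid1, map) {
    s <- summarize_arrays(array_set(list(grid1, set$grids[[2]]), map),
                          quantile = TRUE)
    mad_from_diagonal(probeset_expression(s, "rep1"),
                      probeset_expression(s, "rep2"), exclude = excl)
  }
  list(
    set = set, spiked = sp, mask = mask, corrected = corrected,
    filtered = filtered,
    mad_spiked = mad_of(sp$grid, set$map),
    mad_mean_replaced = mad_of(corrected, set$map),
    mad_filtered = mad_of(sp$grid, filtered$map)
  )
}
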