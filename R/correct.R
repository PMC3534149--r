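# Correction of flagged probes: either replace the intensity with the mean of
# the probeset's surviving probes on the same array (no cross-array values
# enter, so between-array intensity differences play no role), or remove the
# probes from the probeset definitions and emit a kill list.

#' Replace flagged probe intensities by their probeset's surviving mean
#'
#' Each flagged probe that belongs to a probeset receives the arithmetic mean
#' of the unflagged intensities of that probeset, measured on the same array.
#' If every probe of a probeset is flagged no meaningful estimate exists: all
#' its probes are set to 0, yielding a zero probeset intensity downstream;
#' these probesets should be excluded from further analysis and are reported
#' in the `zeroed_probesets` attribute (with a warning). Flagged probes
#' outside the map, and all unflagged probes, are returned bit-identical.
#'
#' @param grid the array to correct.
#' @param mask a `flag_mask` on the same grid.
#' @param map a [probeset_map()] at granularity `"probeset"` (meta-probesets
#'   share probes, which leaves the replacement pool ill-defined).
#' @return the corrected `probe_grid`, with attribute `zeroed_probesets`.
#' @export
correct_by_probeset_mean <- function(grid, mask, map) {
  check_same_dims(grid, mask, "grid and mask")
  if (map_granularity(map) != "probeset") {
    abort_stainr("mean replacement needs granularity 'probeset'",
                 "format_error")
  }
  values <- grid$intensity
  df <- tibble(
    probeset_id = map$probeset_id,
    idx = map$probe_id,
    flagged = mask$flagged[map$probe_id],
    intensity = values[map$probe_id]
  )
  pooled <- df |>
    group_by(.data$probeset_id) |>
    summarise(
      survivor_mean = mean(.data$intensity[!.data$flagged]),
      all_flagged = all(.data$flagged),
      .groups = "drop"
    )
  df <- inner_join(df, pooled, by = "probeset_id")
  replace_rows <- df$flagged & !df$all_flagged
  values[df$idx[replace_rows]] <- df$survivor_mean[replace_rows]
  values[df$idx[df$all_flagged]] <- 0
  zeroed <- sort(unique(pooled$probeset_id[pooled$all_flagged]))
  if (length(zeroed) > 0) {
    warn(sprintf(
      "%d probeset(s) had every probe flagged and were zeroed; exclude them from further analysis",
      length(zeroed)))
  }
  out <- grid_with_values(grid, values)
  attr(out, "zeroed_probesets") <- zeroed
  out
}

#' Remove flagged probes from the probeset definitions
#'
#' The filtering alternative to mean replacement: flagged probes are dropped
#' from the membership table (the desk-scale analogue of rewriting the PGF
#' annotation) and listed for the Affymetrix Power Tools `--kill-list`
#' option. Probesets that lose all probes are dropped and reported rather
#' than silently zeroed.
#'
#' @param map a [probeset_map()].
#' @param mask a `flag_mask` on the same grid.
#' @return a list: `map` (the filtered [probeset_map()]), `kill_list`
#'   (ascending probe ids removed), `emptied` (ids of probesets that lost
#'   every probe).
#' @export
filter_probesets <- function(map, mask) {
  bad_ids <- flagged_ids(mask)
  keep <- !(map$probe_id %in% bad_ids)
  removed <- sort(unique(map$probe_id[!keep]))
  filtered <- map[keep, ]
  emptied <- sort(setdiff(unique(map$probeset_id),
                          unique(filtered$probeset_id)))
  list(
    map = new_probeset_map(filtered, map_granularity(map)),
    kill_list = removed,
    emptied = emptied
  )
}
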