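# Probeset membership tables travel as plain TSV (a desk-scale stand-in for
# the vendor's PGF/CLF annotation), kill lists as a one-column file that the
# Affymetrix Power Tools --kill-list option accepts.

#' Read a probeset membership TSV
#'
#' Expects a tab-separated file with header columns `probeset_id`, `probe_id`,
#' `x`, `y`, `is_core` (0/1 or logical).
#'
#' @inheritParams probeset_map
#' @param path TSV path.
#' @return a [probeset_map()].
#' @export
read_probeset_map <- function(path, granularity = c("probeset", "meta_probeset"),
                              dims = NULL) {
  granularity <- match.arg(granularity)
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  probeset_map(tbl, granularity = granularity, dims = dims)
}

#' Write flagged probes as a kill list
#'
#' Writes the linear probe ids of flagged probes that appear in the probeset
#' map, one per line in ascending order under a single `probe_id` header.
#' Probes flagged but absent from the map (controls, background features) are
#' omitted: they take no part in summarization, so downstream tools have
#' nothing to kill.
#'
#' @param mask a `flag_mask`.
#' @param map a [probeset_map()] on the same grid.
#' @param path output file path.
#' @return the ids written, invisibly.
#' @export
write_kill_list <- function(mask, map, path) {
  ids <- intersect(flagged_ids(mask), map$probe_id)
  writeLines(c("probe_id", format(sort(ids), scientific = FALSE, trim = TRUE)),
             con = path)
  invisible(sort(ids))
}
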