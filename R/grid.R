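# Probe lattice containers. A probe grid is a tibble with one row per lattice
# position (columns x, y, intensity), ordered by probe_id, with the geometry
# (n_rows, n_cols) and array metadata stored as attributes. Coordinates are
# 0-based: x in [0, n_cols), y in [0, n_rows). probe_id is the 1-based
# row-major linearization y * n_cols + x + 1.

grid_roles <- c("total", "newly_transcribed", "pre_existing", "generic")

#' Convert between probe ids and lattice coordinates
#'
#' Probes are numbered 1-based and row-major: `probe_id = y * n_cols + x + 1`,
#' with 0-based coordinates. All stainr APIs exchange `(x, y)` pairs; linear
#' ids appear only in probeset maps and kill lists.
#'
#' @param x,y 0-based lattice coordinates.
#' @param probe_id 1-based linear probe id.
#' @param n_cols number of columns of the grid.
#' @return `probe_index()` returns integer ids; `probe_coords()` a tibble with
#'   columns `x` and `y`.
#' @examples
#' probe_index(1, 1, n_cols = 4)
#' probe_coords(6, n_cols = 4)
#' @export
probe_index <- function(x, y, n_cols) {
  as.integer(y) * as.integer(n_cols) + as.integer(x) + 1L
}

#' @rdname probe_index
#' @export
probe_coords <- function(probe_id, n_cols) {
  id0 <- as.integer(probe_id) - 1L
  tibble(x = id0 %% as.integer(n_cols), y = id0 %/% as.integer(n_cols))
}

lattice_tbl <- function(n_rows, n_cols) {
  tibble(
    x = rep.int(0:(n_cols - 1L), n_rows),
    y = rep(0:(n_rows - 1L), each = n_cols)
  )
}

new_probe_grid <- function(tbl, n_rows, n_cols, label, role, cel_meta = NULL) {
  structure(
    tbl,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    label = label, role = role, cel_meta = cel_meta,
    class = c("probe_grid", class(tibble()))
  )
}

#' Build a probe intensity grid
#'
#' @param intensities a numeric matrix (`n_rows` x `n_cols`, indexed
#'   `[y + 1, x + 1]`), or a numeric vector in probe-id order together with
#'   `n_rows`/`n_cols`, or a data frame with columns `x`, `y`, `intensity`
#'   covering every lattice position.
#' @param n_rows,n_cols grid dimensions (inferred from a matrix or data frame).
#' @param label free-text array name.
#' @param role RNA fraction measured by the array: `"total"`,
#'   `"newly_transcribed"`, `"pre_existing"` or `"generic"`.
#' @param cel_meta opaque CEL metadata carried along for round-trip writing
#'   (see [read_cel_text()]); `NULL` for grids born in memory.
#' @return a `probe_grid`: a tibble with columns `x`, `y`, `intensity` in
#'   probe-id order, carrying `n_rows`, `n_cols`, `label` and `role` as
#'   attributes.
#' @examples
#' g <- probe_grid(matrix(1:6, nrow = 2, byrow = TRUE), label = "toy")
#' grid_dims(g)
#' @export
probe_grid <- function(intensities, n_rows = NULL, n_cols = NULL,
                       label = "", role = "generic", cel_meta = NULL) {
  role <- match.arg(role, grid_roles)
  if (is.matrix(intensities)) {
    n_rows <- nrow(intensities)
    n_cols <- ncol(intensities)
    values <- as.vector(t(intensities))
  } else if (is.data.frame(intensities)) {
    need <- c("x", "y", "intensity")
    if (!all(need %in% names(intensities))) {
      abort_stainr("a probe grid data frame needs columns x, y, intensity",
                   "format_error")
    }
    n_cols <- n_cols %||% (max(intensities$x) + 1L)
    n_rows <- n_rows %||% (max(intensities$y) + 1L)
    values <- rep(NA_real_, n_rows * n_cols)
    values[probe_index(intensities$x, intensities$y, n_cols)] <-
      intensities$intensity
  } else {
    if (is.null(n_rows) || is.null(n_cols)) {
      abort_stainr("n_rows and n_cols are required for vector intensities",
                   "format_error")
    }
    values <- as.numeric(intensities)
  }
  if (length(values) != n_rows * n_cols) {
    abort_stainr(
      sprintf("expected %d intensities for a %d x %d grid, got %d",
              n_rows * n_cols, n_rows, n_cols, length(values)),
      "consistency_error"
    )
  }
  if (anyNA(values) || any(!is.finite(values))) {
    abort_stainr("intensities must be finite at every lattice position",
                 "consistency_error")
  }
  if (any(values < 0)) {
    abort_stainr("intensities must be >= 0", "consistency_error")
  }
  tbl <- lattice_tbl(n_rows, n_cols)
  tbl$intensity <- values
  new_probe_grid(tbl, n_rows, n_cols, label, role, cel_meta)
}

#' Grid geometry and matrix views
#'
#' `grid_dims()` returns the `(n_rows, n_cols)` of any stainr grid-shaped
#' table (probe grids, noise-score grids, flag masks). `grid_matrix()`
#' materializes the value column as a matrix indexed `[y + 1, x + 1]`.
#'
#' @param grid a `probe_grid`, `noise_grid` or `flag_mask`.
#' @param value the column to spread (defaults to the table's value column).
#' @export
grid_dims <- function(grid) {
  c(n_rows = attr(grid, "n_rows"), n_cols = attr(grid, "n_cols"))
}

#' @rdname grid_dims
#' @export
grid_matrix <- function(grid, value = NULL) {
  value <- value %||% intersect(c("intensity", "score", "flagged"), names(grid))[1]
  matrix(grid[[value]], nrow = attr(grid, "n_rows"),
         ncol = attr(grid, "n_cols"), byrow = TRUE)
}

grid_label <- function(grid) attr(grid, "label") %||% ""

same_dims <- function(a, b) {
  identical(unname(grid_dims(a)), unname(grid_dims(b)))
}

check_same_dims <- function(a, b, what = "grids") {
  if (!same_dims(a, b)) {
    abort_stainr(sprintf("%s must share dimensions", what), "dimension_error")
  }
  invisible(TRUE)
}

# rebuild a grid with new intensities, keeping metadata
grid_with_values <- function(grid, values, label = NULL, role = NULL) {
  tbl <- lattice_tbl(attr(grid, "n_rows"), attr(grid, "n_cols"))
  tbl$intensity <- as.numeric(values)
  new_probe_grid(tbl, attr(grid, "n_rows"), attr(grid, "n_cols"),
                 label %||% attr(grid, "label"), role %||% attr(grid, "role"),
                 attr(grid, "cel_meta"))
}

#' @export
print.probe_grid <- function(x, ...) {
  cat(sprintf("# probe_grid: %d x %d (%s, role %s)\n",
              attr(x, "n_rows"), attr(x, "n_cols"),
              if (nzchar(grid_label(x))) grid_label(x) else "unlabeled",
              attr(x, "role")))
  NextMethod()
}

new_noise_grid <- function(scores, n_rows, n_cols, kind, pseudocount = NA_real_,
                           control_desc = "", k = NA_integer_,
                           self_weight = NA_real_) {
  tbl <- lattice_tbl(n_rows, n_cols)
  tbl$score <- as.numeric(scores)
  structure(
    tbl,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    kind = kind, pseudocount = pseudocount, control_desc = control_desc,
    k = k, self_weight = self_weight,
    class = c("noise_grid", class(tibble()))
  )
}

#' @export
print.noise_grid <- function(x, ...) {
  extra <- if (identical(attr(x, "kind"), "windowed")) {
    sprintf(", k = %d, self-weight %g", attr(x, "k"), attr(x, "self_weight"))
  } else ""
  cat(sprintf("# noise_grid: %d x %d (kind %s%s)\n",
              attr(x, "n_rows"), attr(x, "n_cols"), attr(x, "kind"), extra))
  NextMethod()
}

new_flag_mask <- function(flagged, n_rows, n_cols, threshold = NA_real_,
                          source_kind = NA_character_) {
  tbl <- lattice_tbl(n_rows, n_cols)
  tbl$flagged <- as.logical(flagged)
  structure(
    tbl,
    n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
    threshold = threshold, source_kind = source_kind,
    class = c("flag_mask", class(tibble()))
  )
}

#' @export
print.flag_mask <- function(x, ...) {
  cat(sprintf("# flag_mask: %d x %d, %d flagged (threshold %s)\n",
              attr(x, "n_rows"), attr(x, "n_cols"), sum(x$flagged),
              format(attr(x, "threshold"))))
  NextMethod()
}

#' Linear probe ids of the flagged positions of a mask
#'
#' @param mask a `flag_mask`.
#' @return sorted integer probe ids.
#' @export
flagged_ids <- function(mask) {
  sort(probe_index(mask$x[mask$flagged], mask$y[mask$flagged],
                   attr(mask, "n_cols")))
}

new_probeset_map <- function(tbl, granularity) {
  structure(as_tibble(tbl), granularity = granularity,
            class = c("probeset_map", class(tibble())))
}

#' Build a probe-to-probeset membership table
#'
#' @param entries a data frame with columns `probeset_id`, `probe_id`, `x`,
#'   `y`, `is_core`.
#' @param granularity `"probeset"` (each probe belongs to at most one
#'   probeset) or `"meta_probeset"` (gene-level groupings that may share
#'   probes).
#' @param dims optional `(n_rows, n_cols)`; when given, `probe_id` is checked
#'   against the row-major linearization of `(x, y)`.
#' @return a `probeset_map` tibble.
#' @export
probeset_map <- function(entries, granularity = c("probeset", "meta_probeset"),
                         dims = NULL) {
  granularity <- match.arg(granularity)
  need <- c("probeset_id", "probe_id", "x", "y", "is_core")
  if (!all(need %in% names(entries))) {
    abort_stainr(paste("probeset map needs columns",
                       paste(need, collapse = ", ")), "format_error")
  }
  tbl <- as_tibble(entries)[need]
  tbl$probeset_id <- as.character(tbl$probeset_id)
  tbl$probe_id <- as.integer(tbl$probe_id)
  tbl$x <- as.integer(tbl$x)
  tbl$y <- as.integer(tbl$y)
  tbl$is_core <- as.logical(tbl$is_core)
  if (anyDuplicated(tbl[c("probeset_id", "probe_id")]) > 0) {
    abort_stainr("duplicated (probeset_id, probe_id) pair", "duplicate_error")
  }
  if (granularity == "probeset" &&
      anyDuplicated(tbl$probe_id) > 0) {
    abort_stainr(
      "at granularity 'probeset' each probe may belong to one probeset only",
      "consistency_error"
    )
  }
  if (!is.null(dims)) {
    n_rows <- dims[[1]]; n_cols <- dims[[2]]
    if (any(tbl$x < 0 | tbl$x >= n_cols | tbl$y < 0 | tbl$y >= n_rows)) {
      abort_stainr("map coordinates fall outside the grid", "consistency_error")
    }
    if (any(tbl$probe_id != probe_index(tbl$x, tbl$y, n_cols))) {
      abort_stainr("probe_id inconsistent with (x, y) linearization",
                   "consistency_error")
    }
  }
  new_probeset_map(tbl, granularity)
}

map_granularity <- function(map) attr(map, "granularity")

#' Probes eligible for spiking and evaluation
#'
#' The evaluation universe defaults to the core-annotated probes of the map,
#' which are also the only probes the spiking simulator touches.
#'
#' @param map a `probeset_map`.
#' @param core_only drop entries with `is_core = FALSE`.
#' @return a tibble with distinct `probe_id`, `x`, `y`.
#' @export
eligible_probes <- function(map, core_only = TRUE) {
  tbl <- if (core_only) map[map$is_core, ] else map
  distinct(as_tibble(tbl)[c("probe_id", "x", "y")])
}

#' Bundle replicate grids with a probeset map
#'
#' @param grids a list of `probe_grid`s with identical dimensions and unique
#'   labels.
#' @param map a `probeset_map` whose coordinates lie within the grid.
#' @return an `array_set` (list with elements `grids` and `map`).
#' @export
array_set <- function(grids, map) {
  if (length(grids) < 1) abort_stainr("need at least one grid", "format_error")
  for (g in grids) {
    check_same_dims(grids[[1]], g, "all grids of an array set")
  }
  labels <- vapply(grids, grid_label, character(1))
  if (any(!nzchar(labels)) || anyDuplicated(labels) > 0) {
    abort_stainr("array set grids need unique non-empty labels", "format_error")
  }
  dims <- grid_dims(grids[[1]])
  if (any(map$x >= dims[["n_cols"]] | map$y >= dims[["n_rows"]])) {
    abort_stainr("map coordinates fall outside the grids", "consistency_error")
  }
  names(grids) <- labels
  structure(list(grids = grids, map = map), class = "array_set")
}

#' @export
print.array_set <- function(x, ...) {
  dims <- grid_dims(x$grids[[1]])
  cat(sprintf("# array_set: %d arrays of %d x %d, %d probeset entries (%s)\n",
              length(x$grids), dims[["n_rows"]], dims[["n_cols"]],
              nrow(x$map), map_granularity(x$map)))
  invisible(x)
}
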