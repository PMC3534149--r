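# Text CEL (version 3) reading and writing. The version-3 dialect is an INI
# style text file with [CEL], [HEADER] and [INTENSITY] sections; intensities
# live in the MEAN column of [INTENSITY]. stainr treats everything outside the
# intensity data lines as opaque: the lines before and after the data block
# are preserved verbatim so that read -> write round-trips byte-identically
# on canonically formatted files, and sections such as [MASKS], [OUTLIERS]
# and [MODIFIED] survive untouched.

cel_data_line <- function(x, y, mean, stdv, npixels) {
  sprintf("%d\t%d\t%s\t%s\t%d", x, y,
          formatC(mean, format = "f", digits = 1),
          formatC(stdv, format = "f", digits = 1), npixels)
}

#' Read a version-3 text CEL file
#'
#' @param path path to a text CEL file whose first section is `[CEL]` with
#'   `Version=3`.
#' @param label array name for the resulting grid; defaults to the file name.
#' @param role RNA fraction of the array, see [probe_grid()].
#' @return a [probe_grid()] with the MEAN column as intensities. The STDV and
#'   NPIXELS columns plus every line outside the intensity data block are kept
#'   in the grid's `cel_meta` attribute so [write_cel_text()] can reproduce
#'   the file.
#' @seealso [write_cel_text()]
#' @export
read_cel_text <- function(path, label = basename(path), role = "generic") {
  if (!file.exists(path)) {
    abort_stainr(sprintf("no such file: %s", path), "io_error")
  }
  lines <- readLines(path)
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || trimws(lines[first]) != "[CEL]") {
    abort_stainr("not a text CEL file: first section must be [CEL]",
                 "format_error")
  }
  version <- grep("^Version=", lines, value = TRUE)
  if (length(version) == 0 || trimws(version[1]) != "Version=3") {
    abort_stainr("unsupported CEL dialect: need Version=3", "format_error")
  }
  header_at <- match("[HEADER]", trimws(lines))
  if (is.na(header_at)) abort_stainr("missing [HEADER] section", "format_error")
  get_field <- function(name) {
    hit <- grep(sprintf("^%s=", name), lines, value = TRUE)[1]
    if (is.na(hit)) {
      abort_stainr(sprintf("missing %s= in [HEADER]", name), "format_error")
    }
    as.integer(sub(sprintf("^%s=", name), "", hit))
  }
  n_cols <- get_field("Cols")
  n_rows <- get_field("Rows")
  int_at <- match("[INTENSITY]", trimws(lines))
  if (is.na(int_at)) {
    abort_stainr("missing [INTENSITY] section", "format_error")
  }
  ncells_line <- grep("^NumberCells=", lines)
  ncells_line <- ncells_line[ncells_line > int_at][1]
  if (is.na(ncells_line)) {
    abort_stainr("missing NumberCells= in [INTENSITY]", "format_error")
  }
  n_cells <- as.integer(sub("^NumberCells=", "", lines[ncells_line]))
  if (n_cells != n_rows * n_cols) {
    abort_stainr(
      sprintf("NumberCells=%d inconsistent with Rows x Cols = %d",
              n_cells, n_rows * n_cols),
      "consistency_error"
    )
  }
  cellheader_at <- grep("^CellHeader=", lines)
  cellheader_at <- cellheader_at[cellheader_at > int_at][1]
  if (is.na(cellheader_at)) {
    abort_stainr("missing CellHeader= in [INTENSITY]", "format_error")
  }
  data_rows <- lines[(cellheader_at + 1):(cellheader_at + n_cells)]
  fields <- strsplit(trimws(data_rows), "[ \t]+")
  bad <- lengths(fields) < 3
  if (any(bad)) {
    abort_stainr("malformed intensity line in [INTENSITY]", "parse_error")
  }
  as_num <- function(i) suppressWarnings(as.numeric(vapply(fields, `[`, "", i)))
  xs <- as_num(1); ys <- as_num(2); means <- as_num(3)
  stdv <- as_num(4); npix <- as_num(5)
  if (anyNA(xs) || anyNA(ys) || anyNA(means)) {
    abort_stainr("non-numeric X/Y/MEAN value in [INTENSITY]", "parse_error")
  }
  ids <- probe_index(xs, ys, n_cols)
  values <- numeric(n_cells); values[ids] <- means
  stdv_v <- numeric(n_cells); stdv_v[ids] <- ifelse(is.na(stdv), 0, stdv)
  npix_v <- integer(n_cells)
  npix_v[ids] <- as.integer(ifelse(is.na(npix), 1L, npix))
  meta <- list(
    pre = lines[1:cellheader_at],
    post = if (cellheader_at + n_cells < length(lines)) {
      lines[(cellheader_at + n_cells + 1):length(lines)]
    } else character(0),
    stdv = stdv_v,
    npixels = npix_v
  )
  probe_grid(values, n_rows = n_rows, n_cols = n_cols,
             label = label, role = role, cel_meta = meta)
}

#' Write a probe grid as a version-3 text CEL file
#'
#' Emits the grid's intensities into the MEAN column. For grids that came from
#' [read_cel_text()] the surrounding lines (header, CellHeader, trailing
#' sections) are re-emitted verbatim, giving a byte-identical round trip on
#' canonically formatted files; STDV and NPIXELS travel along unchanged. For
#' grids born in memory a minimal `[CEL]`/`[HEADER]`/`[INTENSITY]` skeleton is
#' generated with STDV=0 and NPIXELS=1. MEAN values are printed with one
#' decimal, the canonical dialect precision.
#'
#' @param grid a [probe_grid()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cel_text <- function(grid, path) {
  dims <- grid_dims(grid)
  n <- dims[["n_rows"]] * dims[["n_cols"]]
  meta <- attr(grid, "cel_meta")
  if (is.null(meta)) {
    meta <- list(
      pre = c(
        "[CEL]", "Version=3", "",
        "[HEADER]",
        sprintf("Cols=%d", dims[["n_cols"]]),
        sprintf("Rows=%d", dims[["n_rows"]]), "",
        "[INTENSITY]",
        sprintf("NumberCells=%d", n),
        "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS"
      ),
      post = character(0),
      stdv = numeric(n),
      npixels = rep(1L, n)
    )
  }
  data_rows <- cel_data_line(grid$x, grid$y, grid$intensity,
                             meta$stdv, meta$npixels)
  ok <- tryCatch({
    writeLines(c(meta$pre, data_rows, meta$post), con = path)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_stainr(sprintf("cannot write %s: %s", path, conditionMessage(ok)),
                 "io_error")
  }
  invisible(path)
}
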