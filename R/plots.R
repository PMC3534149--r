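# The two diagnostic plots: the probe noise plot (scores color-coded at
# their lattice position; with residual scores this is the classic residual
# plot) and the replicate scatter plot (probeset values of the affected array
# against the control, colored by the fraction of flagged probes).

block_max_downsample <- function(mat, target) {
  f <- ceiling(max(dim(mat)) / target)
  if (f <= 1) return(list(mat = mat, factor = 1L))
  nr <- ceiling(nrow(mat) / f); nc <- ceiling(ncol(mat) / f)
  out <- matrix(-Inf, nr, nc)
  ri <- (seq_len(nrow(mat)) - 1L) %/% f + 1L
  ci <- (seq_len(ncol(mat)) - 1L) %/% f + 1L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    agg <- tapply(col, ri, max)
    out[, ci[j]] <- pmax(out[, ci[j]], agg)
  }
  list(mat = out, factor = as.integer(f))
}

#' Plot a noise-score grid as an image
#'
#' `autoplot()` renders scores at their array position with y pointing down
#' (array orientation): a diverging colormap centered on 0 for signed
#' fold-change scores, a sequential one for absolute or windowed scores.
#' Grids larger than `downsample` pixels per side are reduced by block
#' maximum so stains stay visible. `probe_noise_plot()` writes the image to
#' a file.
#'
#' @param object,scores a `noise_grid`.
#' @param downsample maximum rendered pixels per side.
#' @param ... ignored.
#' @return a ggplot (`autoplot`); the output path, invisibly
#'   (`probe_noise_plot`).
#' @exportS3Method ggplot2::autoplot
autoplot.noise_grid <- function(object, downsample = 2000, ...) {
  kind <- attr(object, "kind")
  ds <- block_max_downsample(grid_matrix(object, "score"), downsample)
  mat <- ds$mat
  df <- tibble(
    x = rep((0:(ncol(mat) - 1L)) * ds$factor, each = nrow(mat)),
    y = rep((0:(nrow(mat) - 1L)) * ds$factor, ncol(mat)),
    score = as.vector(mat)
  )
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        fill = .data$score)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_x_continuous(expand = c(0, 0)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y", fill = "noise score",
                  title = sprintf("probe noise plot (%s)", kind)) +
    ggplot2::theme_minimal()
  signed <- identical(kind, "fc") && any(df$score < 0)
  if (signed) {
    lim <- max(abs(df$score))
    p + ggplot2::scale_fill_gradient2(low = "blue", mid = "white",
                                      high = "red", limits = c(-lim, lim))
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' @rdname autoplot.noise_grid
#' @param out image file path (extension decides the device, e.g. `.png`,
#'   `.pdf`).
#' @param width,height,dpi passed to [ggplot2::ggsave()].
#' @export
probe_noise_plot <- function(scores, out, downsample = 2000,
                             width = 6, height = 5, dpi = 150) {
  p <- autoplot.noise_grid(scores, downsample = downsample)
  ok <- tryCatch({
    ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_stainr(sprintf("cannot write %s: %s", out, conditionMessage(ok)),
                 "io_error")
  }
  invisible(out)
}

#' @exportS3Method ggplot2::autoplot
autoplot.flag_mask <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$x, y = .data$y,
                                       fill = .data$flagged)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(expand = c(0, 0)) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey90",
                                          `TRUE` = "firebrick")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x", y = "y", fill = "flagged") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall,
                                       y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "recall", y = "precision") +
    ggplot2::theme_minimal()
}

flag_fraction_class <- function(fraction) {
  cut(fraction, breaks = c(-Inf, 0, 0.25, 0.5, 0.75, 1),
      labels = c("0%", "≤25%", "≤50%", "≤75%", "100%"))
}

#' Replicate scatter plot of probeset values
#'
#' Plots probeset expression values of an affected array against a control
#' with the identity diagonal; points are binned by the fraction of their
#' probes flagged as corrupted (classes 0, <=25%, <=50%, <=75%, 100%) and the
#' panel is annotated with the mean absolute deviation from the diagonal
#' (computed excluding fully flagged, i.e. zeroed, probesets).
#'
#' @param a,b tibbles `probeset_id`, `expression` (see
#'   [probeset_expression()]); `a` is the affected array, `b` the control.
#' @param flags_fraction tibble `probeset_id`, `fraction` with the flagged
#'   probe fraction in `[0, 1]`; probesets missing from it count as 0.
#' @param out optional image path; when given the plot is also written there.
#' @param ... passed to [ggplot2::ggsave()] when `out` is given.
#' @return the ggplot, invisibly when `out` is given.
#' @export
replicate_scatter_plot <- function(a, b, flags_fraction = NULL, out = NULL,
                                   ...) {
  df <- inner_join(a, b, by = "probeset_id", suffix = c("_a", "_b"))
  if (nrow(df) == 0) {
    abort_stainr("no shared probesets to plot", "format_error")
  }
  if (is.null(flags_fraction)) {
    flags_fraction <- tibble(probeset_id = character(), fraction = numeric())
  }
  df <- left_join(df, flags_fraction, by = "probeset_id")
  df$fraction[is.na(df$fraction)] <- 0
  df$flagged_class <- flag_fraction_class(df$fraction)
  mad <- mad_from_diagonal(a, b,
                           exclude = df$probeset_id[df$fraction >= 1])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$expression_b,
                                        y = .data$expression_a,
                                        color = .data$flagged_class)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::scale_color_manual(
      values = c("0%" = "grey40", "≤25%" = "#2c7bb6",
                 "≤50%" = "#abd9e9", "≤75%" = "#fdae61",
                 "100%" = "#d7191c"),
      drop = FALSE
    ) +
    ggplot2::annotate("text", x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                      label = sprintf("MAD from diagonal: %.3g", mad)) +
    ggplot2::labs(x = "control (log2)", y = "affected array (log2)",
                  color = "probes flagged") +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, ...)
    return(invisible(p))
  }
  p
}
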