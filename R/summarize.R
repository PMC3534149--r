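# RMA-style probeset summarization. Probeset expression values are estimated
# from the additive model log2(y_ij) = mu + probe_i + array_j + e_ij, fitted
# per probeset by Tukey median polish; the chip effect mu + array_j is the
# probeset's expression on array j, and the residuals e_ij provide an
# alternative probe noise channel.

#' Median polish of a probe-by-array matrix
#'
#' Alternating row-first/column median sweeps decompose the matrix into
#' overall + row (probe) + column (array) effects + residuals. Sweeping stops
#' when the total absolute residual changes by less than `tol` between
#' iterations (or hits zero), or after `max_iter` iterations.
#'
#' @param values a finite numeric matrix, probes in rows and arrays in
#'   columns, on the log2 scale.
#' @param max_iter,tol iteration cap and absolute convergence tolerance on
#'   the change in the sum of absolute residuals.
#' @return a list with `overall`, `row_effects`, `chip_effects`
#'   (`overall + column effect`, one per array), `residuals` (same shape as
#'   `values`), `iterations`, `converged`.
#' @export
median_polish_fit <- function(values, max_iter = 10L, tol = 0.01) {
  if (!is.matrix(values)) values <- as.matrix(values)
  if (nrow(values) < 1 || ncol(values) < 1) {
    abort_stainr("median polish needs a non-empty matrix", "format_error")
  }
  if (any(!is.finite(values))) {
    abort_stainr("median polish needs finite values", "format_error")
  }
  z <- values
  overall <- 0
  row_eff <- numeric(nrow(z))
  col_eff <- numeric(ncol(z))
  oldsum <- 0
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter && !converged) {
    iter <- iter + 1L
    rdelta <- apply(z, 1, median)
    z <- z - rdelta
    row_eff <- row_eff + rdelta
    delta <- median(col_eff)
    col_eff <- col_eff - delta
    overall <- overall + delta
    cdelta <- apply(z, 2, median)
    z <- sweep(z, 2, cdelta)
    col_eff <- col_eff + cdelta
    delta <- median(row_eff)
    row_eff <- row_eff - delta
    overall <- overall + delta
    newsum <- sum(abs(z))
    converged <- newsum == 0 || abs(newsum - oldsum) < tol
    oldsum <- newsum
  }
  list(overall = overall, row_effects = row_eff,
       chip_effects = overall + col_eff, residuals = z,
       iterations = iter, converged = converged)
}

#' Summarize an array set to probeset expression values
#'
#' Optionally quantile-normalizes the arrays, log2-transforms the intensities
#' with the detection-limit pseudocount (so zero-intensity probes enter as
#' `log2(0 + c)`), and fits [median_polish_fit()] per probeset (or
#' meta-probeset, if that is the map's granularity).
#'
#' @param set an [array_set()].
#' @param quantile apply [quantile_normalize()] first.
#' @param core_only restrict to core-annotated probes.
#' @param pseudocount added before the log2 transform.
#' @param ... passed to [median_polish_fit()].
#' @return a `probeset_summary`: list with `expression` (tibble `probeset_id`,
#'   `array`, `expression`), `residuals` (tibble `probeset_id`, `probe_id`,
#'   `x`, `y`, `array`, `residual`) and `iterations_used`; probesets left with
#'   no usable probes are skipped with a warning.
#' @export
summarize_arrays <- function(set, quantile = TRUE, core_only = TRUE,
                             pseudocount = 16, ...) {
  grids <- set$grids
  if (quantile && length(grids) >= 2) grids <- quantile_normalize(grids)
  labels <- vapply(set$grids, grid_label, character(1))
  dims <- grid_dims(set$grids[[1]])
  lmat <- log2(vapply(grids, function(g) g$intensity,
                      numeric(nrow(grids[[1]]))) + pseudocount)
  map <- set$map
  if (core_only) map <- map[map$is_core, ]
  empty_sets <- setdiff(unique(set$map$probeset_id), unique(map$probeset_id))
  if (length(empty_sets) > 0) {
    warn(sprintf("skipping %d probeset(s) with no usable probes",
                 length(empty_sets)))
  }
  if (nrow(map) == 0) {
    abort_stainr("no probes left to summarize", "format_error")
  }
  groups <- split(seq_len(nrow(map)), map$probeset_id)
  n_sets <- length(groups)
  n_arr <- length(labels)
  expr <- matrix(NA_real_, n_sets, n_arr,
                 dimnames = list(names(groups), labels))
  resid_list <- vector("list", n_sets)
  iters <- integer(n_sets)
  for (i in seq_len(n_sets)) {
    rows <- groups[[i]]
    sub <- lmat[map$probe_id[rows], , drop = FALSE]
    fit <- median_polish_fit(sub, ...)
    expr[i, ] <- fit$chip_effects
    iters[i] <- fit$iterations
    resid_list[[i]] <- tibble(
      probeset_id = names(groups)[i],
      probe_id = rep(map$probe_id[rows], n_arr),
      x = rep(map$x[rows], n_arr),
      y = rep(map$y[rows], n_arr),
      array = rep(labels, each = length(rows)),
      residual = as.vector(fit$residuals)
    )
  }
  expression <- tibble(
    probeset_id = rep(rownames(expr), n_arr),
    array = rep(labels, each = n_sets),
    expression = as.vector(expr)
  )
  structure(
    list(expression = expression,
         residuals = bind_rows(resid_list),
         iterations_used = max(iters)),
    arrays = labels, n_rows = dims[["n_rows"]], n_cols = dims[["n_cols"]],
    granularity = map_granularity(set$map),
    quantile = quantile, pseudocount = pseudocount,
    class = "probeset_summary"
  )
}

#' @export
print.probeset_summary <- function(x, ...) {
  cat(sprintf(
    "# probeset_summary: %d probesets x %d arrays (%s, quantile %s), <= %d polish iterations\n",
    length(unique(x$expression$probeset_id)), length(attr(x, "arrays")),
    attr(x, "granularity"), attr(x, "quantile"), x$iterations_used))
  invisible(x)
}

#' Expression column of one array
#'
#' @param summary a [summarize_arrays()] result.
#' @param array array label.
#' @return tibble `probeset_id`, `expression`, as consumed by
#'   [mad_from_diagonal()] and [replicate_scatter_plot()].
#' @export
probeset_expression <- function(summary, array) {
  if (!array %in% attr(summary, "arrays")) {
    abort_stainr(sprintf("unknown array label: %s", array), "format_error")
  }
  out <- summary$expression[summary$expression$array == array, ]
  out[c("probeset_id", "expression")]
}

#' @rdname probeset_expression
#' @export
expression_wide <- function(summary) {
  tidyr::pivot_wider(summary$expression, names_from = "array",
                     values_from = "expression")
}

#' Residual-based probe noise scores
#'
#' Places the absolute median-polish residuals of one array at their probe
#' positions; probes outside the map score 0. Large absolute residuals mark
#' probes whose measurements the additive probeset model cannot reconcile
#' with the other arrays, the residual channel of artefact detection.
#'
#' @param summary a [summarize_arrays()] result.
#' @param array array label present in the summary.
#' @return a `noise_grid` of kind `"abs_residual"`. If a probe belongs to
#'   several meta-probesets the largest absolute residual wins.
#' @export
residual_noise_scores <- function(summary, array) {
  if (!array %in% attr(summary, "arrays")) {
    abort_stainr(sprintf("unknown array label: %s", array), "format_error")
  }
  nr <- attr(summary, "n_rows"); nc <- attr(summary, "n_cols")
  res <- summary$residuals[summary$residuals$array == array, ]
  scores <- numeric(nr * nc)
  ids <- probe_index(res$x, res$y, nc)
  vals <- abs(res$residual)
  ord <- order(vals)  # later (larger) assignments win
  scores[ids[ord]] <- vals[ord]
  new_noise_grid(scores, nr, nc, kind = "abs_residual",
                 pseudocount = attr(summary, "pseudocount"),
                 control_desc = sprintf("median-polish residuals, array %s",
                                        array))
}
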