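# broom-style tidiers for stainr's fitted objects.

#' Tidy an RNA-fraction model
#'
#' @param x a [fit_fraction_model()] result.
#' @param ... ignored.
#' @return one row per scaling coefficient: `term`, `estimate`.
#' @exportS3Method generics::tidy
tidy.fraction_model <- function(x, ...) {
  tibble(term = c("lambda1", "lambda2"),
         estimate = c(x$lambda1, x$lambda2))
}

#' @rdname tidy.fraction_model
#' @exportS3Method generics::glance
glance.fraction_model <- function(x, ...) {
  tibble(residual_sum_sq = x$residual_sum_sq, n_probes = x$n_probes)
}

#' Tidy a probeset summary
#'
#' @param x a [summarize_arrays()] result.
#' @param ... ignored.
#' @return the long expression table: `probeset_id`, `array`, `expression`.
#' @exportS3Method generics::tidy
tidy.probeset_summary <- function(x, ...) {
  x$expression
}

#' @rdname tidy.probeset_summary
#' @exportS3Method generics::glance
glance.probeset_summary <- function(x, ...) {
  tibble(
    n_probesets = length(unique(x$expression$probeset_id)),
    n_arrays = length(attr(x, "arrays")),
    granularity = attr(x, "granularity"),
    quantile_normalized = attr(x, "quantile"),
    iterations_used = x$iterations_used
  )
}

#' Tidy a precision-recall curve
#'
#' @param x a [pr_curve()].
#' @param ... ignored.
#' @return the curve as a plain tibble.
#' @exportS3Method generics::tidy
tidy.pr_curve <- function(x, ...) {
  tibble(threshold = x$threshold, recall = x$recall, precision = x$precision)
}

#' @rdname tidy.pr_curve
#' @exportS3Method generics::glance
glance.pr_curve <- function(x, ...) {
  tibble(positive_count = attr(x, "positive_count"),
         n_universe = attr(x, "n_universe"),
         n_thresholds = nrow(x))
}

#' Tidy a flag mask
#'
#' @param x a `flag_mask`.
#' @param ... ignored.
#' @return the flagged positions: `x`, `y`, `probe_id`.
#' @exportS3Method generics::tidy
tidy.flag_mask <- function(x, ...) {
  out <- x[x$flagged, c("x", "y")]
  out$probe_id <- probe_index(out$x, out$y, attr(x, "n_cols"))
  as_tibble(out)
}

#' @rdname tidy.flag_mask
#' @exportS3Method generics::glance
glance.flag_mask <- function(x, ...) {
  tibble(n_flagged = sum(x$flagged), n_probes = nrow(x),
         threshold = attr(x, "threshold"),
         source_kind = attr(x, "source_kind"))
}
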