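# Normalizations used before scoring and summarization: quantile (the RMA
# companion), pairwise loess on the MA plane (before replicate fold-change
# scoring), and the RNA-fraction linear model T = lambda1 * N + lambda2 * P
# that turns metabolic-labeling fractions into a biological control.

#' Quantile-normalize a set of arrays
#'
#' Forces every array onto the common distribution obtained by averaging the
#' sorted intensity vectors across arrays, preserving within-array ranks.
#' Tied values receive the mean of the reference quantiles over their tied
#' ranks.
#'
#' @param grids a list of at least two [probe_grid()]s with identical
#'   dimensions.
#' @return a list of normalized `probe_grid`s in the same order.
#' @export
quantile_normalize <- function(grids) {
  if (length(grids) < 2) {
    abort_stainr("quantile normalization needs at least 2 arrays",
                 "format_error")
  }
  for (g in grids) check_same_dims(grids[[1]], g)
  m <- vapply(grids, function(g) g$intensity, numeric(nrow(grids[[1]])))
  norm <- limma::normalizeQuantiles(m, ties = TRUE)
  purrr::map2(grids, seq_along(grids),
              function(g, j) grid_with_values(g, norm[, j]))
}

#' Loess-normalize one array against a control
#'
#' Removes the loess trend of `M = log2(target / control)` against
#' `A = mean log2 intensity` from the target, so that fold-changes to the
#' control are free of intensity-dependent bias before probe noise scoring.
#' The fit is locally linear with a symmetric (robust) family, so a spatial
#' artefact occupying a few percent of the probes does not drag the trend.
#' On grids above `max_fit_points` probes the curve is fitted on an
#' A-stratified subsample of that size (deterministic: every k-th probe in A
#' order) and evaluated everywhere by interpolation.
#'
#' @param target,control [probe_grid()]s with identical dimensions.
#' @param pseudocount added to intensities before taking logs; intensities
#'   plus pseudocount must be positive. Default 0 (use on strictly positive
#'   grids).
#' @param span,robust_iterations loess span and total robust-fitting
#'   iterations (initial fit plus reweightings).
#' @param max_fit_points subsample cap for the loess fit.
#' @return the normalized target `probe_grid`.
#' @export
loess_pair_normalize <- function(target, control, pseudocount = 0,
                                 span = 2 / 3, robust_iterations = 3,
                                 max_fit_points = 50000) {
  check_same_dims(target, control)
  vt <- target$intensity + pseudocount
  vc <- control$intensity + pseudocount
  if (any(vt <= 0) || any(vc <= 0)) {
    abort_stainr("intensities plus pseudocount must be positive",
                 "format_error")
  }
  lt <- log2(vt); lc <- log2(vc)
  m <- lt - lc
  a <- (lt + lc) / 2
  if (diff(range(a)) < sqrt(.Machine$double.eps)) {
    abort_stainr("degenerate input: constant average intensity A",
                 "format_error")
  }
  if (diff(range(m)) < sqrt(.Machine$double.eps)) {
    # constant log-ratio: the trend is that constant (robust loess cannot
    # reweight residuals that are identically zero)
    trend <- m
  } else {
    idx <- seq_along(a)
    if (length(a) > max_fit_points) {
      idx <- order(a)[unique(round(seq(1, length(a),
                                       length.out = max_fit_points)))]
    }
    fit <- loess(
      m[idx] ~ a[idx], span = span, degree = 1, family = "symmetric",
      control = loess.control(iterations = robust_iterations,
                              surface = "interpolate")
    )
    a_clamped <- pmin(pmax(a, min(a[idx])), max(a[idx]))
    trend <- predict(fit, newdata = a_clamped)
  }
  corrected <- pmax(2^(lt - trend) - pseudocount, 0)
  grid_with_values(target, corrected)
}

#' Fit the RNA-fraction model T = lambda1 * N + lambda2 * P
#'
#' Total RNA is split by metabolic labeling into newly transcribed (N) and
#' pre-existing (P) fractions, so T = N + P must hold approximately for every
#' probe after accounting for the different RNA amounts hybridized. The
#' nonnegative scaling factors minimizing the residual sum of squares of
#' `T - lambda1 * N - lambda2 * P` are found by least squares (nonnegative
#' least squares when the unconstrained optimum leaves the positive orthant).
#'
#' @param total,new,pre [probe_grid()]s of the three fractions, identical
#'   dimensions.
#' @return a `fraction_model` with elements `lambda1`, `lambda2`,
#'   `residual_sum_sq`, `n_probes`; see [tidy.fraction_model()].
#' @export
fit_fraction_model <- function(total, new, pre) {
  check_same_dims(total, new)
  check_same_dims(total, pre)
  X <- cbind(N = new$intensity, P = pre$intensity)
  if (qr(X)$rank < 2) {
    abort_stainr("N and P are collinear: fraction model is rank-deficient",
                 "rank_error")
  }
  y <- total$intensity
  coefs <- lm.fit(X, y)$coefficients
  if (any(coefs < 0)) {
    coefs <- pracma::lsqnonneg(X, y)$x
  }
  rss <- sum((y - X %*% coefs)^2)
  structure(
    list(lambda1 = unname(coefs[1]), lambda2 = unname(coefs[2]),
         residual_sum_sq = rss, n_probes = length(y)),
    class = "fraction_model"
  )
}

#' @export
print.fraction_model <- function(x, ...) {
  cat(sprintf(
    "RNA-fraction model: T = %.4g N + %.4g P  (RSS %.4g over %d probes)\n",
    x$lambda1, x$lambda2, x$residual_sum_sq, x$n_probes))
  invisible(x)
}

#' Biological control from labeled RNA fractions
#'
#' The normalized sum `lambda1 * N + lambda2 * P` predicts the total-RNA
#' measurement probe by probe and serves as the control value in probe noise
#' scores for T.
#'
#' @param model a fitted [fit_fraction_model()].
#' @param new,pre the fraction grids.
#' @return a `probe_grid` of control values, role `"generic"`.
#' @export
control_from_fractions <- function(model, new, pre) {
  check_same_dims(new, pre)
  values <- model$lambda1 * new$intensity + model$lambda2 * pre$intensity
  grid_with_values(new, values,
                   label = sprintf("%.3g*N + %.3g*P",
                                   model$lambda1, model$lambda2),
                   role = "generic")
}
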