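# Probe noise scores. The per-probe score is the pseudocounted log2
# fold-change of a probe against its control value,
#     s_j = log2((v_j + c) / (v'_j + c)),
# with the pseudocount c at the platform's detection limit. The window score
# replaces s_j by a distance-weighted average over the (2k+1) x (2k+1)
# neighborhood, exploiting the spatial coherence of stains.

#' Fold-change probe noise scores
#'
#' Scores each probe as `log2((v + c) / (v' + c))`, where `v` is the probe's
#' intensity on the scored array and `v'` its control value: a replicate, the
#' per-probe median of replicates ([median_control()]), or the normalized sum
#' of labeled RNA fractions ([control_from_fractions()]). The pseudocount `c`
#' is the estimated detection limit of the platform (default 16) and keeps
#' zero intensities finite.
#'
#' @param target,control [probe_grid()]s with identical dimensions.
#' @param pseudocount detection-limit pseudocount, strictly positive.
#' @param absolute return `|s|` (the detection default) instead of signed
#'   scores (useful for diagnostic plots).
#' @return a `noise_grid` of kind `"fc"`: a tibble `x`, `y`, `score`.
#' @export
fc_noise_scores <- function(target, control, pseudocount = 16,
                            absolute = TRUE) {
  check_same_dims(target, control)
  if (!is.numeric(pseudocount) || pseudocount <= 0) {
    abort_stainr("pseudocount must be > 0", "format_error")
  }
  s <- log2((target$intensity + pseudocount) /
              (control$intensity + pseudocount))
  if (absolute) s <- abs(s)
  dims <- grid_dims(target)
  new_noise_grid(s, dims[["n_rows"]], dims[["n_cols"]], kind = "fc",
                 pseudocount = pseudocount,
                 control_desc = grid_label(control))
}

#' Per-probe median across replicate arrays
#'
#' The fold-change against the per-probe median of all replicates is the
#' fallback control when no artefact-free replicate or biological control is
#' available.
#'
#' @param grids a non-empty list of [probe_grid()]s with identical dimensions.
#' @return a `probe_grid` of per-probe medians (a single grid is returned
#'   unchanged).
#' @export
median_control <- function(grids) {
  if (length(grids) == 0) {
    abort_stainr("median control needs at least one array", "format_error")
  }
  for (g in grids) check_same_dims(grids[[1]], g)
  if (length(grids) == 1) return(grids[[1]])
  m <- vapply(grids, function(g) g$intensity, numeric(nrow(grids[[1]])))
  grid_with_values(grids[[1]], apply(m, 1, median),
                   label = "median of replicates", role = "generic")
}

window_kernel <- function(k, self_weight) {
  offs <- -k:k
  d <- sqrt(outer(offs^2, offs^2, "+"))
  w <- 1 / d
  w[k + 1, k + 1] <- self_weight
  w
}

# zero-padded 2D convolution by shifted accumulation; exact truncation at
# borders, used when the kernel does not fit inside the grid
shift_convolve <- function(s, kern, k) {
  nr <- nrow(s); nc <- ncol(s)
  out <- matrix(0, nr, nc)
  for (dy in -k:k) {
    ylo <- max(1, 1 - dy); yhi <- min(nr, nr - dy)
    if (ylo > yhi) next
    yr <- ylo:yhi
    for (dx in -k:k) {
      xlo <- max(1, 1 - dx); xhi <- min(nc, nc - dx)
      if (xlo > xhi) next
      xr <- xlo:xhi
      w <- kern[dy + k + 1, dx + k + 1]
      out[yr, xr] <- out[yr, xr] + w * s[yr + dy, xr + dx, drop = FALSE]
    }
  }
  out
}

#' Distance-weighted window smoothing of noise scores
#'
#' Replaces each probe's score by the weighted average of the scores in the
#' `(2k + 1) x (2k + 1)` window centered on it. Weights are `1/d(p, j)` with
#' Euclidean distance on the probe lattice, and `self_weight` (default 2) for
#' the center probe. At array borders the window is truncated to the probes
#' that exist. Thresholding the smoothed scores is the window-criterion for
#' artefact detection.
#'
#' Implemented as two translation-invariant convolutions (scores and an
#' all-ones mask against the weight kernel, zero-padded), whose ratio
#' reproduces border truncation exactly; the FFT route (EBImage) is used when
#' the kernel fits inside the grid, a direct shifted accumulation otherwise.
#'
#' @param scores a `noise_grid` (for residual scores, already absolute).
#' @param k window half-width in probes; must satisfy
#'   `k < max(n_rows, n_cols)`.
#' @param self_weight weight of the center probe.
#' @return a `noise_grid` of kind `"windowed"` recording `k` and
#'   `self_weight`.
#' @export
window_smooth <- function(scores, k = 25, self_weight = 2) {
  k <- as.integer(k)
  if (k < 1) abort_stainr("k must be >= 1", "format_error")
  dims <- grid_dims(scores)
  nr <- dims[["n_rows"]]; nc <- dims[["n_cols"]]
  if (k >= max(nr, nc)) {
    abort_stainr("window half-width k must be smaller than the larger grid dimension",
                 "format_error")
  }
  if (any(!is.finite(scores$score))) {
    abort_stainr("scores must be finite", "format_error")
  }
  s <- grid_matrix(scores, "score")
  kern <- window_kernel(k, self_weight)
  use_fft <- (2 * k + 1) <= min(nr, nc) &&
    requireNamespace("EBImage", quietly = TRUE)
  if (use_fft) {
    num <- EBImage::filter2(s, kern, boundary = 0)
    den <- EBImage::filter2(matrix(1, nr, nc), kern, boundary = 0)
  } else {
    num <- shift_convolve(s, kern, k)
    den <- shift_convolve(matrix(1, nr, nc), kern, k)
  }
  sw <- num / den
  new_noise_grid(as.vector(t(sw)), nr, nc, kind = "windowed",
                 pseudocount = attr(scores, "pseudocount"),
                 control_desc = attr(scores, "control_desc"),
                 k = k, self_weight = self_weight)
}
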