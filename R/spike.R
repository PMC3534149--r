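# Spike-in simulation: artefact-free replicate baselines, random probe
# spiking, procedurally generated stain shapes, and projection of a stain
# observed on a denser array onto a coarser one. Every spiked probe is
# recorded in a ground-truth table so detection can be benchmarked.

new_spike_truth <- function(tbl, n_rows, n_cols, delta = NA_real_,
                            mu_log2 = NA_real_, sigma_log2 = NA_real_,
                            seed = NA_integer_) {
  structure(as_tibble(tbl),
            n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
            delta = delta, mu_log2 = mu_log2, sigma_log2 = sigma_log2,
            seed = seed,
            class = c("spike_truth", class(tibble())))
}

#' Assemble a spike ground-truth table
#'
#' Builds the planted-artefact record consumed by [confusion_counts()] and
#' [pr_curve()], e.g. when reading a ground truth back from TSV.
#'
#' @param positions data frame with columns `x`, `y` and optionally
#'   `planted_value`.
#' @param n_rows,n_cols dimensions of the grid the artefact was planted on.
#' @return a `spike_truth` tibble.
#' @export
spike_truth <- function(positions, n_rows, n_cols) {
  if (!all(c("x", "y") %in% names(positions))) {
    abort_stainr("ground truth needs columns x and y", "format_error")
  }
  if (nrow(positions) > 0 &&
      (max(positions$x) >= n_cols || max(positions$y) >= n_rows ||
       min(positions$x) < 0 || min(positions$y) < 0)) {
    abort_stainr("spiked positions fall outside the grid",
                 "consistency_error")
  }
  tbl <- tibble(
    x = as.integer(positions$x), y = as.integer(positions$y),
    planted_value = if ("planted_value" %in% names(positions)) {
      as.numeric(positions$planted_value)
    } else rep(NA_real_, nrow(positions))
  )
  new_spike_truth(tbl, n_rows, n_cols)
}

#' @export
print.spike_truth <- function(x, ...) {
  cat(sprintf("# spike_truth: %d spiked probes on %d x %d\n",
              nrow(x), attr(x, "n_rows"), attr(x, "n_cols")))
  NextMethod()
}

# scattered probeset assignment: probeset p owns linear probes (0-based)
# p, p + m, ..., p + (probes_per_set - 1) m, so members sit m cells apart in
# row-major order and are never 4-adjacent unless a small multiple of m hits
# the row length exactly
scatter_probesets <- function(n_rows, n_cols, probes_per_set) {
  n <- n_rows * n_cols
  m <- n %/% probes_per_set
  if (m < 2) {
    abort_stainr("grid too small for at least two scattered probesets",
                 "format_error")
  }
  if (any(seq_len(probes_per_set - 1) * m == n_cols)) {
    abort_stainr("grid too small: scattered probesets would be adjacent",
                 "format_error")
  }
  used <- 0:(m * probes_per_set - 1)
  probe_id <- used + 1L
  tibble(
    probeset_id = sprintf("PS%05d", used %% m + 1L),
    probe_id = probe_id,
    x = used %% n_cols,
    y = used %/% n_cols,
    is_core = TRUE
  )
}

#' Generate artefact-free replicate arrays
#'
#' Emulates replicate measurements of one sample on an Affymetrix-style grid:
#' each probe has a true log2 intensity drawn once from
#' `Normal(mean_log2, sd_log2)` and shared across replicates, plus
#' independent per-replicate log2 noise `Normal(0, replicate_sd)`;
#' intensities are `2^value`. Probesets tile the probes in groups of
#' `probes_per_set`, scattered so that probes of one probeset are never
#' adjacent on the lattice (mirroring real array layouts); all probesets are
#' core.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param n_replicates number of replicate arrays (>= 2).
#' @param seed RNG seed; the result is bitwise reproducible.
#' @param mean_log2,sd_log2 distribution of true per-probe log2 intensities.
#' @param replicate_sd standard deviation of per-replicate log2 noise.
#' @param probes_per_set probes per probeset (4, the exon-array norm).
#' @return an [array_set()] with grids labeled `rep1`, `rep2`, ...
#' @export
generate_baseline_arrays <- function(n_rows, n_cols, n_replicates, seed,
                                     mean_log2 = 8, sd_log2 = 2,
                                     replicate_sd = 0.25,
                                     probes_per_set = 4) {
  if (n_replicates < 2) {
    abort_stainr("need at least 2 replicates", "format_error")
  }
  map <- scatter_probesets(n_rows, n_cols, probes_per_set)
  n <- n_rows * n_cols
  grids <- withr::with_seed(seed, {
    true_log2 <- rnorm(n, mean_log2, sd_log2)
    lapply(seq_len(n_replicates), function(r) {
      noise <- if (replicate_sd > 0) rnorm(n, 0, replicate_sd) else 0
      probe_grid(2^(true_log2 + noise), n_rows = n_rows, n_cols = n_cols,
                 label = sprintf("rep%d", r), role = "total")
    })
  })
  array_set(grids, new_probeset_map(map, "probeset"))
}

spike_values <- function(grid, positions, mu_log2, sigma_log2, seed) {
  values <- grid$intensity
  planted <- withr::with_seed(seed, {
    2^rnorm(nrow(positions), mu_log2, sigma_log2)
  })
  ids <- probe_index(positions$x, positions$y, attr(grid, "n_cols"))
  values[ids] <- planted
  dims <- grid_dims(grid)
  truth <- new_spike_truth(
    tibble(x = positions$x, y = positions$y, planted_value = planted),
    dims[["n_rows"]], dims[["n_cols"]],
    mu_log2 = mu_log2, sigma_log2 = sigma_log2, seed = seed
  )
  list(grid = grid_with_values(grid, values), truth = truth)
}

#' Randomly spike corrupted intensities into an array
#'
#' Each eligible probe (core-mapped, mirroring real spiking eligibility) is
#' independently corrupted with probability `delta`; corrupted intensities
#' are `2^z` with `z ~ Normal(mu_log2, sigma_log2)`. The defaults
#' `mu_log2 = log2(850)`, `sigma_log2 = 1` reproduce the intensity
#' distribution observed inside real drying stains.
#'
#' @param grid the array to corrupt.
#' @param map a [probeset_map()]; only its (core) probes are eligible.
#' @param delta per-probe spiking probability in `[0, 1]`.
#' @param mu_log2,sigma_log2 log2-scale location and spread of planted
#'   values (interpretation of the log-normal is on the log2 scale; set
#'   `mu_log2 = log(850)/log(2)` style conversions yourself for a natural-log
#'   reading).
#' @param seed RNG seed.
#' @param core_only restrict eligibility to `is_core` probes.
#' @return a list: `grid` (the spiked `probe_grid`), `truth` (a `spike_truth`
#'   tibble `x`, `y`, `planted_value` with the generation parameters as
#'   attributes).
#' @export
random_spike <- function(grid, map, delta, mu_log2 = log2(850),
                         sigma_log2 = 1, seed = 1, core_only = TRUE) {
  if (!is.numeric(delta) || delta < 0 || delta > 1) {
    abort_stainr("delta must lie in [0, 1]", "format_error")
  }
  eligible <- eligible_probes(map, core_only = core_only)
  out <- withr::with_seed(seed, {
    picked <- eligible[runif(nrow(eligible)) < delta, ]
    planted <- 2^rnorm(nrow(picked), mu_log2, sigma_log2)
    list(picked = picked, planted = planted)
  })
  values <- grid$intensity
  ids <- probe_index(out$picked$x, out$picked$y, attr(grid, "n_cols"))
  values[ids] <- out$planted
  dims <- grid_dims(grid)
  truth <- new_spike_truth(
    tibble(x = out$picked$x, y = out$picked$y, planted_value = out$planted),
    dims[["n_rows"]], dims[["n_cols"]],
    delta = delta, mu_log2 = mu_log2, sigma_log2 = sigma_log2, seed = seed
  )
  list(grid = grid_with_values(grid, values), truth = truth)
}

#' Spike a fixed stain shape with log-normal intensities
#'
#' Corrupts exactly the flagged positions of `shape` (intersected with the
#' eligible probes when a map is given) with intensities `2^z`,
#' `z ~ Normal(mu_log2, sigma_log2)` — the contiguous-stain counterpart of
#' [random_spike()].
#'
#' @param grid the array to corrupt.
#' @param shape a `flag_mask` marking the stain, e.g. from [stain_mask()].
#' @inheritParams random_spike
#' @return as [random_spike()].
#' @export
spike_stain <- function(grid, shape, mu_log2 = log2(850), sigma_log2 = 1,
                        seed = 1, map = NULL, core_only = TRUE) {
  check_same_dims(grid, shape, "grid and stain shape")
  positions <- shape[shape$flagged, c("x", "y")]
  if (!is.null(map)) {
    positions <- semi_join(positions, eligible_probes(map, core_only),
                           by = c("x", "y"))
  }
  spike_values(grid, positions, mu_log2, sigma_log2, seed)
}

#' Procedural stain shape: dense disc plus diffuse halo
#'
#' Generates the shape of a drying-type artefact: a filled disc (the stain
#' core, where the array dried out) surrounded by an annulus of sparse
#' corrupted probes (the diffuse rim). With the default radius the shape
#' covers about 2% of the grid.
#'
#' @param n_rows,n_cols grid dimensions.
#' @param center_x,center_y disc center (defaults to the grid center).
#' @param radius disc radius in probes; default sized so the disc covers
#'   ~1.9% of the grid.
#' @param halo_width annulus width in probes beyond the disc.
#' @param halo_density fraction of annulus probes included.
#' @param seed RNG seed for the halo draw.
#' @return a `flag_mask` marking the stain probes.
#' @export
stain_mask <- function(n_rows, n_cols, center_x = NULL, center_y = NULL,
                       radius = NULL, halo_width = 4, halo_density = 0.15,
                       seed = 1) {
  center_x <- center_x %||% (n_cols %/% 2)
  center_y <- center_y %||% (n_rows %/% 2)
  radius <- radius %||% round(sqrt(0.019 * n_rows * n_cols / pi))
  tbl <- lattice_tbl(n_rows, n_cols)
  d <- sqrt((tbl$x - center_x)^2 + (tbl$y - center_y)^2)
  disc <- d <= radius
  annulus <- d > radius & d <= radius + halo_width
  halo <- withr::with_seed(seed, {
    annulus & runif(length(d)) < halo_density
  })
  new_flag_mask(disc | halo, n_rows, n_cols, source_kind = "stain_shape")
}

#' Project a stain observed on a denser array onto a coarser array
#'
#' Downscales a stain by mapping each `factor` x `factor` block of source
#' probes to one target probe (row-major block coordinates). Every block
#' containing at least one stain probe spikes its target probe with the
#' maximum source intensity over the stain probes of the block, rescaled by
#' the ratio of the arrays' 75th intensity percentiles to account for their
#' different intensity ranges. Blocks at odd grid edges are truncated blocks.
#'
#' @param shape_mask `flag_mask` marking the stain on the source grid.
#' @param source the (denser) array carrying the stain intensities.
#' @param target the (coarser) artefact-free array to spike.
#' @param factor block edge length (positive integer).
#' @return as [random_spike()] (the `truth` has `NA` generation parameters —
#'   values are transferred, not drawn).
#' @export
project_artefact <- function(shape_mask, source, target, factor = 2) {
  check_same_dims(shape_mask, source, "stain mask and source")
  factor <- as.integer(factor)
  if (factor < 1) abort_stainr("factor must be >= 1", "format_error")
  stain <- shape_mask[shape_mask$flagged, c("x", "y")]
  if (nrow(stain) == 0) {
    dims <- grid_dims(target)
    return(list(grid = target,
                truth = new_spike_truth(
                  tibble(x = integer(), y = integer(),
                         planted_value = numeric()),
                  dims[["n_rows"]], dims[["n_cols"]])))
  }
  stain$intensity <- source$intensity[
    probe_index(stain$x, stain$y, attr(source, "n_cols"))]
  stain$bx <- stain$x %/% factor
  stain$by <- stain$y %/% factor
  tdims <- grid_dims(target)
  if (max(stain$bx) >= tdims[["n_cols"]] || max(stain$by) >= tdims[["n_rows"]]) {
    abort_stainr("projected stain footprint exceeds the target grid",
                 "consistency_error")
  }
  scale <- unname(quantile(target$intensity, 0.75) /
                    quantile(source$intensity, 0.75))
  blocks <- stain |>
    group_by(.data$bx, .data$by) |>
    summarise(planted_value = max(.data$intensity) * scale, .groups = "drop")
  values <- target$intensity
  ids <- probe_index(blocks$bx, blocks$by, tdims[["n_cols"]])
  values[ids] <- blocks$planted_value
  truth <- new_spike_truth(
    tibble(x = blocks$bx, y = blocks$by,
           planted_value = blocks$planted_value),
    tdims[["n_rows"]], tdims[["n_cols"]]
  )
  list(grid = grid_with_values(target, values), truth = truth)
}
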