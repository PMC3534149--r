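# Independent oracles and small fixture builders shared across tests.

# naive O(n * k^2) evaluation of the distance-weighted window average,
# truncating the window at the borders; the reference the convolution route
# is checked against
naive_window_smooth <- function(score_matrix, k, self_weight = 2) {
  nr <- nrow(score_matrix); nc <- ncol(score_matrix)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      num <- 0; den <- 0
      for (di in -k:k) {
        for (dj in -k:k) {
          ii <- i + di; jj <- j + dj
          if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
          w <- if (di == 0 && dj == 0) self_weight else 1 / sqrt(di^2 + dj^2)
          num <- num + w * score_matrix[ii, jj]
          den <- den + w
        }
      }
      out[i, j] <- num / den
    }
  }
  out
}

# brute-force confusion counts from explicit sets of probe ids
brute_confusion <- function(flagged_ids, spiked_ids, universe_ids) {
  c(
    TP = length(intersect(universe_ids, intersect(flagged_ids, spiked_ids))),
    FP = length(intersect(universe_ids, setdiff(flagged_ids, spiked_ids))),
    TN = length(setdiff(setdiff(universe_ids, flagged_ids), spiked_ids)),
    FN = length(intersect(universe_ids, setdiff(spiked_ids, flagged_ids)))
  )
}

# a noise grid built directly from a matrix of scores
toy_scores <- function(score_matrix, kind = "fc") {
  g <- probe_grid(pmax(2^score_matrix, 0))
  ng <- fc_noise_scores(g, probe_grid(matrix(1, nrow(score_matrix),
                                             ncol(score_matrix))),
                        pseudocount = 1, absolute = FALSE)
  ng$score <- as.vector(t(score_matrix))
  attr(ng, "kind") <- kind
  ng
}

# a mask flagging the given linear probe ids on an nr x nc grid
toy_mask <- function(probe_ids, nr, nc, threshold = NA_real_) {
  scores <- numeric(nr * nc)
  scores[probe_ids] <- 1
  flag_probes(toy_scores(matrix(scores, nr, nc, byrow = TRUE)),
              if (is.na(threshold)) 0.5 else threshold)
}

# a spike_truth at the given linear ids
toy_truth <- function(probe_ids, nr, nc) {
  spike_truth(probe_coords(probe_ids, nc), nr, nc)
}

# small map: consecutive probes grouped into probesets of `size`
toy_map <- function(nr, nc, size = 2, core = TRUE) {
  n <- nr * nc
  ids <- seq_len(n - n %% size)
  probeset_map(data.frame(
    probeset_id = sprintf("PS%02d", (ids - 1) %/% size + 1),
    probe_id = ids,
    x = (ids - 1) %% nc,
    y = (ids - 1) %/% nc,
    is_core = core
  ), granularity = "probeset", dims = c(nr, nc))
}

expect_grid_equal <- function(a, b, tol = 1e-12) {
  expect_equal(grid_dims(a), grid_dims(b))
  expect_equal(a$intensity, b$intensity, tolerance = tol)
}

# canonical 3 x 2 text CEL fixture written in the dialect stainr emits
write_cel_fixture <- function(path, means = c(10, 20, 30, 40, 50, 60)) {
  lines <- c(
    "[CEL]", "Version=3", "",
    "[HEADER]", "Cols=2", "Rows=3", "",
    "[INTENSITY]", "NumberCells=6",
    "CellHeader=X\tY\tMEAN\tSTDV\tNPIXELS",
    sprintf("%d\t%d\t%.1f\t%.1f\t%d",
            rep(0:1, 3), rep(0:2, each = 2), means, rep(0, 6), rep(9L, 6)),
    "",
    "[MASKS]", "NumberCells=0", "CellHeader=X\tY"
  )
  writeLines(lines, path)
  path
}
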