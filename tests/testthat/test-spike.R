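test_that("baseline generation is seeded, replicate-consistent and calibrated", {
  a <- generate_baseline_arrays(10, 10, 3, seed = 71)
  b <- generate_baseline_arrays(10, 10, 3, seed = 71)
  for (i in 1:3) expect_identical(a$grids[[i]]$intensity,
                                  b$grids[[i]]$intensity)
  expect_false(identical(
    a$grids[[1]]$intensity,
    generate_baseline_arrays(10, 10, 3, seed = 72)$grids[[1]]$intensity))

  # zero replicate noise collapses the replicates
  flat <- generate_baseline_arrays(10, 10, 2, seed = 71, replicate_sd = 0)
  expect_identical(flat$grids[[1]]$intensity, flat$grids[[2]]$intensity)

  # CLT bound on the mean log2 intensity at 1e5 probes (sd 2 -> se ~0.0063)
  big <- generate_baseline_arrays(400, 250, 2, seed = 73)
  expect_lt(abs(mean(log2(big$grids[[1]]$intensity)) - 8), 0.05)

  expect_error(generate_baseline_arrays(2, 2, 1, seed = 1),
               class = "stainr_format_error")
  expect_error(generate_baseline_arrays(1, 4, 2, seed = 1),
               class = "stainr_format_error")
})

test_that("probes of one probeset are never 4-adjacent on the lattice", {
  for (dims in list(c(10, 10), c(6, 9), c(12, 5))) {
    map <- generate_baseline_arrays(dims[1], dims[2], 2, seed = 74)$map
    by_set <- split(map[c("x", "y")], map$probeset_id)
    expect_true(all(vapply(by_set, function(m) {
      if (nrow(m) < 2) return(TRUE)
      d <- as.matrix(dist(cbind(m$x, m$y), method = "manhattan"))
      all(d[upper.tri(d)] > 1)
    }, logical(1))))
    expect_true(all(table(map$probeset_id) == 4))
  }
})

test_that("random spiking respects delta boundaries and eligibility", {
  set <- generate_baseline_arrays(10, 10, 2, seed = 75)
  g <- set$grids[[1]]

  out0 <- random_spike(g, set$map, delta = 0, seed = 1)
  expect_identical(out0$grid$intensity, g$intensity)
  expect_equal(nrow(out0$truth), 0)

  out1 <- random_spike(g, set$map, delta = 1, seed = 1)
  expect_equal(nrow(out1$truth), nrow(eligible_probes(set$map)))

  # unspiked probes are bit-identical after spiking
  out <- random_spike(g, set$map, delta = 0.3, seed = 2)
  spiked_ids <- probe_index(out$truth$x, out$truth$y, 10)
  rest <- setdiff(seq_len(100), spiked_ids)
  expect_identical(out$grid$intensity[rest], g$intensity[rest])
  expect_true(all(out$truth$planted_value > 0))

  expect_error(random_spike(g, set$map, delta = 1.2, seed = 1),
               class = "stainr_format_error")
})

test_that("spiked counts and planted values match their distributions", {
  set <- generate_baseline_arrays(100, 100, 2, seed = 76)
  g <- set$grids[[1]]
  n_eligible <- nrow(eligible_probes(set$map))
  expect_equal(n_eligible, 10000)
  out <- random_spike(g, set$map, delta = 0.05, seed = 3)
  # central 99.9% binomial interval: 500 +/- ~72
  expect_gt(nrow(out$truth), 500 - 72)
  expect_lt(nrow(out$truth), 500 + 72)

  # law of large numbers on the log2 values: mu = log2(850), sigma = 1
  big <- random_spike(g, set$map, delta = 1, seed = 4)
  expect_lt(abs(mean(log2(big$truth$planted_value)) - log2(850)),
            3 / sqrt(10000))
})

test_that("ground-truth tables validate their positions", {
  t1 <- spike_truth(data.frame(x = c(0, 2), y = c(1, 0),
                               planted_value = c(500, 900)), 2, 3)
  expect_s3_class(t1, "spike_truth")
  expect_equal(nrow(t1), 2)
  expect_error(spike_truth(data.frame(x = 3, y = 0), 2, 3),
               class = "stainr_consistency_error")
  expect_error(spike_truth(data.frame(a = 1), 2, 3),
               class = "stainr_format_error")
})

test_that("stain masks cover ~2% with a connected disc", {
  shape <- stain_mask(300, 300, seed = 5)
  frac <- mean(shape$flagged)
  expect_gt(frac, 0.015); expect_lt(frac, 0.03)
  # the disc core is present: the grid center is flagged
  expect_true(shape$flagged[probe_index(150, 150, 300)])

  out <- spike_stain(probe_grid(matrix(100, 300, 300)), shape, seed = 6)
  expect_equal(nrow(out$truth), sum(shape$flagged))
  expect_identical(out$grid$intensity[!shape$flagged],
                   rep(100, sum(!shape$flagged)))
})

test_that("artefact projection takes block maxima scaled by q75 ratios", {
  # 4 x 4 source with a fully masked 2 x 2 block at the origin
  src_mat <- matrix(1, 4, 4)
  src_mat[1:2, 1:2] <- c(100, 150, 200, 120)  # column-major: (y,x)
  source <- probe_grid(src_mat)
  shape <- toy_mask(c(1, 2, 5, 6), 4, 4)  # probes of block (0,0)
  target <- probe_grid(matrix(1, 2, 2))

  out <- project_artefact(shape, source, target, factor = 2)
  q_ratio <- quantile(target$intensity, 0.75) / quantile(source$intensity, 0.75)
  expect_equal(out$truth$planted_value, 200 * unname(q_ratio))
  expect_equal(nrow(out$truth), 1)
  expect_equal(out$grid$intensity[1], 200 * unname(q_ratio))
  # untouched blocks keep their values
  expect_equal(out$grid$intensity[-1], rep(1, 3))

  # doubling the target q75 doubles the planted value
  target2 <- probe_grid(matrix(2, 2, 2))
  out2 <- project_artefact(shape, source, target2, factor = 2)
  expect_equal(out2$truth$planted_value, 2 * out$truth$planted_value)

  # footprint beyond the target bounds errors
  shape_far <- toy_mask(16, 4, 4)  # probe at (3, 3) -> block (1, 1) ok
  expect_silent(project_artefact(shape_far, source, target, factor = 2))
  tiny <- probe_grid(matrix(1, 1, 1))
  expect_error(project_artefact(shape_far, source, tiny, factor = 2),
               class = "stainr_consistency_error")
})

test_that("projection preserves stain connectivity at the coarser scale", {
  shape <- stain_mask(60, 60, radius = 10, halo_density = 0, seed = 7)
  source <- probe_grid(matrix(50, 60, 60))
  target <- probe_grid(matrix(50, 30, 30))
  out <- project_artefact(shape, source, target, factor = 2)
  pts <- out$truth[c("x", "y")]
  # BFS over 4-neighbors reaches every projected probe
  key <- paste(pts$x, pts$y)
  seen <- key[1]; frontier <- key[1]
  while (length(frontier) > 0) {
    xy <- do.call(rbind, strsplit(frontier, " "))
    nb <- unique(c(
      paste(as.integer(xy[, 1]) + 1, xy[, 2]),
      paste(as.integer(xy[, 1]) - 1, xy[, 2]),
      paste(xy[, 1], as.integer(xy[, 2]) + 1),
      paste(xy[, 1], as.integer(xy[, 2]) - 1)
    ))
    frontier <- setdiff(intersect(nb, key), seen)
    seen <- union(seen, frontier)
  }
  expect_equal(sort(seen), sort(key))
})
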