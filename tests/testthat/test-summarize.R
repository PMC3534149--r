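test_that("median polish decomposes additive matrices exactly", {
  fit <- median_polish_fit(rbind(c(1, 2), c(3, 4)))
  expect_equal(fit$chip_effects, c(2, 3))
  expect_equal(fit$residuals, matrix(0, 2, 2), ignore_attr = TRUE)
  expect_true(fit$converged)

  # constant matrix
  fit <- median_polish_fit(matrix(7, 3, 4))
  expect_equal(fit$chip_effects, rep(7, 4))
  expect_true(all(fit$residuals == 0))

  # single-probe matrix: chip effects are the probe's values
  fit <- median_polish_fit(matrix(c(5, 9, 2), 1, 3))
  expect_equal(fit$chip_effects, c(5, 9, 2))
  expect_true(all(fit$residuals == 0))

  # general additive structure: mu + probe_i + array_j
  probe <- c(-1, 0, 2, 0.5); array <- c(0, 1.5, -0.5)
  mat <- outer(probe, array, "+") + 6
  fit <- median_polish_fit(mat)
  expect_equal(fit$residuals, matrix(0, 4, 3), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_equal(fit$chip_effects, 6 + array + median(probe))

  expect_error(median_polish_fit(matrix(numeric(0), 0, 0)),
               class = "stainr_format_error")
})

test_that("median polish agrees with the stats reference implementation", {
  set.seed(21)
  for (i in 1:10) {
    nr <- sample(2:6, 1); nc <- sample(2:5, 1)
    mat <- matrix(rnorm(nr * nc), nr, nc)
    mine <- median_polish_fit(mat, max_iter = 100, tol = 1e-10)
    ref <- stats::medpolish(mat, eps = 1e-12, maxiter = 100,
                            trace.iter = FALSE)
    expect_equal(mine$residuals, ref$residuals, ignore_attr = TRUE,
                 tolerance = 1e-6)
    expect_equal(mine$chip_effects, ref$overall + ref$col, tolerance = 1e-6)
  }
})

test_that("chip effects are equivariant under per-array shifts of additive data", {
  # exact for additive matrices: the column effect absorbs the shift
  probe <- c(-2, 0, 1, 3, 0.5); array <- c(0, -1, 2)
  mat <- outer(probe, array, "+") + 8
  base <- median_polish_fit(mat, max_iter = 50, tol = 1e-9)
  shifted <- mat; shifted[, 2] <- shifted[, 2] + 1.25
  fit <- median_polish_fit(shifted, max_iter = 50, tol = 1e-9)
  expect_equal(fit$chip_effects - base$chip_effects, c(0, 1.25, 0),
               tolerance = 1e-10)
})

test_that("replicate arrays summarize to identical expression columns", {
  set <- generate_baseline_arrays(6, 6, 2, seed = 31, replicate_sd = 0)
  s <- summarize_arrays(set, quantile = FALSE)
  wide <- expression_wide(s)
  expect_equal(wide$rep1, wide$rep2)
  expect_equal(mad_from_diagonal(probeset_expression(s, "rep1"),
                                 probeset_expression(s, "rep2")), 0)
})

test_that("a factor-2 scaling of one probeset shifts its chip effect by one", {
  set <- generate_baseline_arrays(6, 6, 2, seed = 32, replicate_sd = 0)
  map <- set$map
  ps1 <- map[map$probeset_id == map$probeset_id[1], ]
  v <- set$grids[[2]]$intensity
  v[ps1$probe_id] <- v[ps1$probe_id] * 2
  grids <- set$grids
  grids[[2]] <- probe_grid(v, n_rows = 6, n_cols = 6, label = "rep2")
  # pseudocount-free transform isolates the pure log2 shift
  s <- summarize_arrays(array_set(grids, map), quantile = FALSE,
                        pseudocount = 1e-9)
  wide <- tidyr::pivot_wider(s$expression, names_from = "array",
                             values_from = "expression")
  delta <- wide$rep2 - wide$rep1
  names(delta) <- wide$probeset_id
  expect_equal(unname(delta[map$probeset_id[1]]), 1, tolerance = 1e-6)
  expect_equal(unname(delta[names(delta) != map$probeset_id[1]]),
               rep(0, length(delta) - 1), tolerance = 1e-6)
})

test_that("quantile = FALSE leaves intensities untouched before the log", {
  set <- generate_baseline_arrays(6, 6, 2, seed = 33)
  raw <- summarize_arrays(set, quantile = FALSE)
  qn <- summarize_arrays(set, quantile = TRUE)
  expect_false(isTRUE(all.equal(raw$expression$expression,
                                qn$expression$expression)))
  # recompute the raw route by hand for one probeset
  map1 <- set$map[set$map$probeset_id == "PS00001", ]
  lmat <- log2(cbind(set$grids[[1]]$intensity,
                     set$grids[[2]]$intensity)[map1$probe_id, ] + 16)
  byhand <- median_polish_fit(lmat)$chip_effects
  wide <- raw$expression[raw$expression$probeset_id == "PS00001", ]
  expect_equal(wide$expression, byhand)
})

test_that("residual noise scores localize a planted probe-level outlier", {
  set <- generate_baseline_arrays(8, 8, 3, seed = 34)
  # inflate one mapped probe by +5 log2 units on rep2
  target <- set$map$probe_id[10]
  grids <- set$grids
  v <- grids[[2]]$intensity
  v[target] <- v[target] * 32
  grids[[2]] <- probe_grid(v, n_rows = 8, n_cols = 8, label = "rep2")
  s <- summarize_arrays(array_set(grids, set$map), quantile = FALSE)
  scores <- residual_noise_scores(s, "rep2")
  expect_equal(attr(scores, "kind"), "abs_residual")
  expect_equal(which.max(scores$score), target)

  # perfectly additive data leave an all-zero residual grid
  flat <- generate_baseline_arrays(6, 6, 2, seed = 35, replicate_sd = 0)
  s0 <- summarize_arrays(flat, quantile = FALSE)
  expect_equal(max(abs(residual_noise_scores(s0, "rep1")$score)), 0)

  # unmapped positions score zero
  unmapped <- setdiff(seq_len(64), set$map$probe_id)
  if (length(unmapped) > 0) {
    expect_true(all(scores$score[unmapped] == 0))
  }
  expect_error(residual_noise_scores(s, "nope"),
               class = "stainr_format_error")
})
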