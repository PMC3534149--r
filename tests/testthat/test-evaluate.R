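test_that("confusion counts partition the universe", {
  # 10 probes, 3 spiked, 4 flagged, 3 overlapping
  truth <- toy_truth(c(1, 2, 3), 2, 5)
  mask <- toy_mask(c(1, 2, 3, 7), 2, 5)
  uni <- probe_coords(1:10, n_cols = 5)
  cc <- confusion_counts(mask, truth, uni)
  expect_equal(as.list(cc), list(TP = 3L, FP = 1L, TN = 6L, FN = 0L))

  # empty mask
  cc0 <- confusion_counts(toy_mask(integer(0), 2, 5), truth, uni)
  expect_equal(as.list(cc0), list(TP = 0L, FP = 0L, TN = 7L, FN = 3L))

  # mask identical to truth: a perfect detector
  ccp <- confusion_counts(toy_mask(c(1, 2, 3), 2, 5), truth, uni)
  expect_equal(ccp$FP + ccp$FN, 0L)

  expect_error(confusion_counts(toy_mask(1, 3, 5), truth, uni),
               class = "stainr_dimension_error")
})

test_that("confusion counts agree with set-logic enumeration of all masks", {
  # every flag subset of a 6-probe universe, against a fixed truth
  uni_ids <- 1:6
  uni <- probe_coords(uni_ids, n_cols = 3)
  truth <- toy_truth(c(2, 5), 2, 3)
  for (code in 0:63) {
    flagged <- uni_ids[bitwAnd(bitwShiftR(code, 0:5), 1) == 1]
    cc <- confusion_counts(toy_mask(flagged, 2, 3), truth, uni)
    ref <- brute_confusion(flagged, c(2, 5), uni_ids)
    expect_equal(unlist(as.list(cc)), ref)
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 6L)
  }
})

test_that("PR curves enumerate thresholds with ties entering together", {
  s <- toy_scores(matrix(c(3, 2, 1), 1, 3))
  truth <- toy_truth(c(1, 2), 1, 3)
  uni <- probe_coords(1:3, n_cols = 3)
  curve <- pr_curve(s, truth, uni)
  expect_equal(curve$threshold, c(3, 2, 1))
  expect_equal(curve$recall, c(0.5, 1, 1))
  expect_equal(curve$precision, c(1, 1, 2 / 3))

  # tied scores collapse to a single point
  s_tie <- toy_scores(matrix(c(2, 2, 1), 1, 3))
  curve_tie <- pr_curve(s_tie, truth, uni)
  expect_equal(nrow(curve_tie), 2)
  expect_equal(curve_tie$recall, c(1, 1))

  # all probes spiked: precision 1 everywhere
  all_true <- toy_truth(1:3, 1, 3)
  expect_true(all(pr_curve(s, all_true, uni)$precision == 1))

  # no spiked probes: recall undefined
  expect_error(pr_curve(s, toy_truth(integer(0), 1, 3), uni),
               class = "stainr_format_error")

  # recall is non-decreasing along the curve
  set.seed(81)
  s_rand <- toy_scores(matrix(sample(rnorm(20), 30, replace = TRUE), 5, 6))
  t_rand <- toy_truth(sample(30, 8), 5, 6)
  cr <- pr_curve(s_rand, t_rand, probe_coords(1:30, n_cols = 6))
  expect_true(all(diff(cr$recall) >= 0))
  expect_true(all(cr$precision >= 0 & cr$precision <= 1))
  expect_true(all(diff(cr$threshold) < 0))
})

test_that("precision and recall match their defining ratios across thresholds", {
  set.seed(82)
  s <- toy_scores(matrix(rnorm(36), 6, 6))
  truth <- toy_truth(sample(36, 10), 6, 6)
  uni <- probe_coords(1:36, n_cols = 6)
  curve <- pr_curve(s, truth, uni)
  for (i in seq_len(nrow(curve))) {
    # flag everything at or above the threshold (strict > of a nudged t)
    mask <- flag_probes(s, curve$threshold[i] - 1e-12)
    cc <- confusion_counts(mask, truth, uni)
    expect_equal(curve$precision[i], cc$TP / (cc$TP + cc$FP))
    expect_equal(curve$recall[i], cc$TP / (cc$TP + cc$FN))
  }
})

test_that("precision_at_recall reads the highest qualifying threshold", {
  s <- toy_scores(matrix(c(3, 2, 1), 1, 3))
  truth <- toy_truth(c(1, 2), 1, 3)
  curve <- pr_curve(s, truth, probe_coords(1:3, n_cols = 3))
  expect_equal(precision_at_recall(curve, 0.85), 1)
  expect_equal(precision_at_recall(curve, 0.4), 1)
  expect_equal(precision_at_recall(curve, 1), 1)

  # perfectly separating scores give precision 1 at any recall
  s_sep <- toy_scores(matrix(c(5, 4, 1, 0.5), 1, 4))
  t_sep <- toy_truth(c(1, 2), 1, 4)
  c_sep <- pr_curve(s_sep, t_sep, probe_coords(1:4, n_cols = 4))
  for (r in c(0.3, 0.9, 1)) {
    expect_equal(precision_at_recall(c_sep, r), 1)
  }
  expect_error(precision_at_recall(curve, 0), class = "stainr_format_error")
})

test_that("MAD from the diagonal is a symmetric shift-aware metric", {
  tb <- function(ids, v) tibble::tibble(probeset_id = ids, expression = v)
  a <- tb(c("P1", "P2"), c(0, 1))
  expect_equal(mad_from_diagonal(a, a), 0)
  b <- tb(c("P1", "P2"), c(2, 3))
  expect_equal(mad_from_diagonal(a, b), 2)
  expect_equal(mad_from_diagonal(tb(c("P1", "P2"), c(0, 1)),
                                 tb(c("P1", "P2"), c(0, 3))), 1)

  # symmetry and triangle inequality over three summaries
  set.seed(83)
  ids <- sprintf("P%02d", 1:30)
  u <- tb(ids, rnorm(30)); v <- tb(ids, rnorm(30)); w <- tb(ids, rnorm(30))
  expect_equal(mad_from_diagonal(u, v), mad_from_diagonal(v, u))
  expect_lte(mad_from_diagonal(u, w),
             mad_from_diagonal(u, v) + mad_from_diagonal(v, w))

  # exclusions and empty intersections
  expect_equal(mad_from_diagonal(a, tb(c("P1", "P2"), c(2, 1)),
                                 exclude = "P1"), 0)
  expect_error(mad_from_diagonal(a, tb("P9", 1)),
               class = "stainr_format_error")
})
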