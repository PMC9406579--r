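test_that("confusion counts tally the four cell types", {
  gt <- matrix(c(1, 0, 1, 0), 2, 2)    # column-major: [[1,1],[0,0]]
  pred <- matrix(c(1, 1, 0, 0), 2, 2)  # [[1,0],[1,0]]
  cc <- confusion_counts(pred, gt)
  expect_equal(cc$tp, 1); expect_equal(cc$fn, 1)
  expect_equal(cc$fp, 1); expect_equal(cc$tn, 1)
  ones <- matrix(1, 4, 4)
  cc1 <- confusion_counts(ones, ones)
  expect_equal(cc1$tp, 16); expect_equal(cc1$tn + cc1$fp + cc1$fn, 0)
  zeros <- matrix(0, 4, 4)
  cc0 <- confusion_counts(zeros, zeros)
  expect_equal(cc0$tn, 16); expect_equal(cc0$tp + cc0$fp + cc0$fn, 0)
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)), "0 and 1")
  expect_error(confusion_counts(matrix(0, 2, 2), matrix(0, 3, 3)), "grid")
})

test_that("accuracy, Dice and IoU follow their closed forms", {
  expect_equal(accuracy(list(tp = 1, tn = 1, fp = 1, fn = 1)), 0.5)
  expect_equal(accuracy(list(tp = 2, tn = 12, fp = 1, fn = 1)), 0.875)
  expect_equal(accuracy(list(tp = 8, tn = 8, fp = 0, fn = 0)), 1)
  expect_equal(dice(list(tp = 2, tn = 0, fp = 2, fn = 2)), 0.5)
  expect_equal(dice(list(tp = 5, tn = 0, fp = 0, fn = 0)), 1)
  expect_equal(dice(list(tp = 0, tn = 0, fp = 3, fn = 4)), 0)
  expect_equal(iou(list(tp = 2, tn = 0, fp = 2, fn = 2)), 1 / 3)
  expect_equal(iou(list(tp = 5, tn = 0, fp = 0, fn = 0)), 1)
  expect_warning(expect_equal(dice(list(tp = 0, tn = 9, fp = 0, fn = 0)), 1),
                 "empty")
  expect_error(accuracy(list(tp = 0, tn = 0, fp = 0, fn = 0)), "zero")
})

test_that("count-based metrics equal direct set arithmetic on random mask pairs", {
  for (seed in 1:200) {
    a <- random_mask(16, seed)
    b <- random_mask(16, seed + 10000)
    cc <- confusion_counts(a, b)
    inter <- sum(a * b)
    uni <- sum(pmax(a, b))
    expect_identical(iou(cc), inter / uni)
    expect_identical(dice(cc), 2 * inter / (sum(a) + sum(b)))
    expect_identical(accuracy(cc), mean(a == b))
    # algebraic identity and ordering
    expect_equal(iou(cc), dice(cc) / (2 - dice(cc)))
    expect_gte(accuracy(cc), iou(cc))
  }
})

test_that("average Hausdorff distance: identities and the 3-4-5 case", {
  m <- random_mask(16, 3)
  expect_equal(average_hausdorff(m, m), 0)
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[4, 5] <- 1
  expect_equal(average_hausdorff(a, b), 5)
  expect_error(average_hausdorff(a, matrix(0, 8, 8)), "empty")
})

test_that("average Hausdorff matches the all-pairs brute-force oracle", {
  for (seed in 1:100) {
    a <- random_mask(16, seed)
    b <- random_mask(16, seed + 555)
    got <- average_hausdorff(a, b)
    expect_equal(got, bf_average_hausdorff(a, b), tolerance = 1e-9)
    # symmetry
    expect_equal(got, average_hausdorff(b, a), tolerance = 1e-12)
  }
})

test_that("anisotropic spacing scales the distances", {
  a <- matrix(0, 8, 8); a[1, 1] <- 1
  b <- matrix(0, 8, 8); b[1, 4] <- 1   # 3 columns apart
  expect_equal(average_hausdorff(a, b, spacing = c(1, 2)), 6)
  expect_equal(average_hausdorff(a, b, spacing = c(2, 2)), 6)
})

test_that("ROC AUC equals the exhaustive pairwise oracle and its limiting cases", {
  gt <- matrix(c(rep(1, 6), rep(0, 14)), 4, 5)
  expect_equal(roc_auc(gt, gt), 1)
  expect_equal(roc_auc(matrix(0.4, 4, 5), gt), 0.5)
  for (seed in 1:20) {
    set.seed(seed)
    prob <- matrix(round(runif(20), 2), 4, 5)  # rounding forces some ties
    expect_equal(roc_auc(prob, gt), bf_auc(prob, gt))
  }
  skip_if_not_installed("pROC")
  set.seed(99)
  prob <- matrix(runif(20), 4, 5)
  ref <- as.numeric(pROC::auc(pROC::roc(as.vector(gt), as.vector(prob),
                                        quiet = TRUE, direction = "<")))
  expect_equal(roc_auc(prob, gt), ref)
  expect_error(roc_auc(matrix(0.5, 2, 2), matrix(1, 2, 2)), "single class")
})

test_that("AUC is invariant under strictly monotone transforms", {
  set.seed(77)
  gt <- (matrix(runif(64), 8, 8) > 0.6) * 1
  prob <- matrix(runif(64), 8, 8)
  base <- roc_auc(prob, gt)
  expect_equal(roc_auc(prob^3, gt), base)
  expect_equal(roc_auc(1 / (1 + exp(-5 * prob)) , gt), base)
})

test_that("evaluate_case wires thresholding and all five metrics together", {
  gt <- random_mask(24, 41)
  rep1 <- evaluate_case(gt, gt, threshold = 0.5)
  expect_equal(rep1$acc, 1); expect_equal(rep1$dsc, 1)
  expect_equal(rep1$iou, 1); expect_equal(rep1$avgdist, 0)
  expect_equal(rep1$auc, 1)
  # threshold 0 turns any positive map into the all-ones prediction
  prob <- matrix(runif(24 * 24, 0.01, 1), 24, 24)
  cc <- confusion_counts((prob >= 0) * 1, gt)
  expect_equal(cc$tp + cc$fp, 24 * 24)
  rep0 <- evaluate_case(prob, gt, threshold = 0)
  expect_equal(rep0$iou, sum(gt) / (24 * 24))
})

test_that("a one-pixel dilated prediction adds exactly the dilation ring as false positives", {
  gt <- matrix(0, 16, 16); gt[5:10, 6:12] <- 1
  # 4-connectivity dilation by explicit shifts
  dil <- gt
  dil[1:15, ] <- pmax(dil[1:15, ], gt[2:16, ])
  dil[2:16, ] <- pmax(dil[2:16, ], gt[1:15, ])
  dil[, 1:15] <- pmax(dil[, 1:15], gt[, 2:16])
  dil[, 2:16] <- pmax(dil[, 2:16], gt[, 1:15])
  cc <- confusion_counts(dil, gt)
  expect_equal(cc$fp, sum(dil) - sum(gt))
  expect_equal(cc$fn, 0)
  expect_equal(cc$fp, 2 * 6 + 2 * 7)  # ring of a 6x7 rectangle, 4-connectivity
})

test_that("aggregate metrics are unweighted means with missing values excluded", {
  cases <- dplyr::bind_rows(
    evaluate_case(random_mask(16, 1), random_mask(16, 2)),
    evaluate_case(matrix(0, 16, 16), random_mask(16, 3))  # empty pred: no avgdist
  )
  agg <- aggregate_metrics(cases)
  expect_equal(agg$n_cases, 2)
  expect_equal(agg$n_missing_avgdist, 1)
  expect_equal(agg$dsc, mean(cases$dsc))
  expect_equal(agg$avgdist, cases$avgdist[1])
})
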