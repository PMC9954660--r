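# Segmentation metrics against hand-enumerated cases and brute-force oracles.

test_that("confusion counts match per-pixel enumeration on a 3x3 toy", {
  gt <- matrix(0, 3, 3); gt[1, 1] <- 1; gt[1, 2] <- 1; gt[2, 1] <- 1
  pr <- matrix(0, 3, 3); pr[1, 1] <- 1; pr[1, 2] <- 1; pr[3, 3] <- 1
  pr[3, 2] <- 1; pr[2, 2] <- 1
  cc <- confusion_counts(pr, gt)
  expect_equal(cc$tp, 2)
  expect_equal(cc$fp, 3)
  expect_equal(cc$fn, 1)
  expect_equal(cc$tn, 3)
})

test_that("identical and complementary masks give extreme counts", {
  set.seed(4)
  m <- random_mask(6, 7, 0.4)
  cc <- confusion_counts(m, m)
  expect_equal(cc$tp, sum(m))
  expect_equal(cc$tn, length(m) - sum(m))
  expect_equal(cc$fp + cc$fn, 0)
  expect_equal(accuracy(cc), 1)
  cc2 <- confusion_counts(1 - m, m)
  expect_equal(cc2$tp + cc2$tn, 0)
  expect_equal(accuracy(cc2), 0)
  expect_equal(dice(cc2), 0)
})

test_that("accuracy, dice and iou reproduce hand-computed values", {
  # TP=2, TN=5, FP=2, FN=1 over 10 pixels -> ACC 0.7
  gt <- matrix(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2, 5)
  pr <- matrix(c(1, 1, 0, 1, 1, 0, 0, 0, 0, 0), 2, 5)
  expect_equal(accuracy(confusion_counts(pr, gt)), 0.7)
  # TP=3, FP=1, FN=1 -> DSC 6/8, IoU 3/5; cross-checked by set overlap
  gt2 <- matrix(c(1, 1, 1, 1, 0, 0), 2, 3)
  pr2 <- matrix(c(1, 1, 1, 0, 1, 0), 2, 3)
  cc <- confusion_counts(pr2, gt2)
  expect_equal(dice(cc), 0.75)
  expect_equal(iou(cc), 0.6)
  orc <- oracle_overlap_metrics(pr2, gt2)
  expect_equal(dice(cc), orc$dsc)
  expect_equal(iou(cc), orc$iou)
})

test_that("metrics agree with set-overlap oracles on random masks", {
  set.seed(11)
  for (i in 1:60) {
    h <- sample(2:32, 1); w <- sample(2:32, 1)
    pr <- random_mask(h, w, runif(1, 0.05, 0.8))
    gt <- random_mask(h, w, runif(1, 0.05, 0.8))
    cc <- confusion_counts(pr, gt)
    orc <- oracle_overlap_metrics(pr, gt)
    expect_equal(accuracy(cc), orc$acc, tolerance = 1e-12)
    expect_equal(dice(cc), orc$dsc, tolerance = 1e-12)
    expect_equal(iou(cc), orc$iou, tolerance = 1e-12)
    # algebraic identity and ordering
    expect_equal(dice(cc), 2 * iou(cc) / (1 + iou(cc)), tolerance = 1e-12)
    expect_gte(dice(cc), iou(cc))
    # permutation invariance
    p <- sample(h * w)
    cc2 <- confusion_counts(matrix(pr[p], h, w), matrix(gt[p], h, w))
    expect_equal(unclass(cc2), unclass(cc))
  }
})

test_that("empty-vs-empty convention is deterministic", {
  z <- matrix(0, 4, 4)
  cc <- confusion_counts(z, z)
  expect_equal(dice(cc), 1)
  expect_equal(iou(cc), 1)
  expect_equal(accuracy(cc), 1)
})

test_that("average Hausdorff distance matches hand-computed cases", {
  set.seed(2)
  m <- random_mask(9, 9, 0.3); m[1, 1] <- 1
  expect_equal(avg_hausdorff(m, m), 0)
  # single pixels offset by (3, 4) -> Euclidean distance 5 both ways
  expect_equal(avg_hausdorff(point_mask(8, 8, 1, 1), point_mask(8, 8, 4, 5)), 5)
  # gt {(0,0),(0,2)}, pred {(0,0)} -> (mean(0,2) + mean(0)) / 2 = 0.5
  gt <- matrix(0, 4, 4); gt[1, 1] <- 1; gt[1, 3] <- 1
  pr <- point_mask(4, 4, 1, 1)
  expect_equal(avg_hausdorff(pr, gt), 0.5)
})

test_that("average Hausdorff distance is symmetric and matches the brute-force oracle", {
  set.seed(21)
  for (i in 1:40) {
    h <- sample(3:32, 1); w <- sample(3:32, 1)
    pr <- random_mask(h, w, runif(1, 0.05, 0.5))
    gt <- random_mask(h, w, runif(1, 0.05, 0.5))
    if (sum(pr) == 0 || sum(gt) == 0) next
    a <- avg_hausdorff(pr, gt)
    expect_equal(a, oracle_ahd(pr, gt), tolerance = 1e-10)
    expect_equal(a, avg_hausdorff(gt, pr), tolerance = 1e-12)
    expect_true(a == 0 || !identical(pr, gt))
  }
})

test_that("empty masks raise a distinct condition", {
  z <- matrix(0, 4, 4)
  m <- point_mask(4, 4, 2, 2)
  expect_error(avg_hausdorff(z, m), class = "rda_empty_mask_error")
  expect_error(avg_hausdorff(m, z), class = "rda_empty_mask_error")
})

test_that("boundary mode measures outline-to-outline distance", {
  # filled 5x5 square vs same square: boundary distance still 0
  m <- matrix(0, 9, 9); m[3:7, 3:7] <- 1
  expect_equal(avg_hausdorff(m, m, boundary = TRUE), 0)
  # concentric squares: boundary distance smaller than point-set distance
  inner <- matrix(0, 11, 11); inner[5:7, 5:7] <- 1
  outer_ <- matrix(0, 11, 11); outer_[3:9, 3:9] <- 1
  expect_lt(0, avg_hausdorff(inner, outer_, boundary = TRUE))
})

test_that("roc_auc follows the rank formulation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  # fg {0.9, 0.4}, bg {0.6, 0.1}: 3 wins of 4 pairs
  expect_equal(roc_auc(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)), 0.75)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), class = "rda_single_class_error")
})

test_that("roc_auc matches exhaustive pairwise counting and negation identity", {
  set.seed(33)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    s <- sample(round(runif(n, 0, 1), sample(c(1, 2, 6), 1)))  # force ties sometimes
    g <- rbinom(n, 1, 0.4)
    if (sum(g) == 0 || sum(g) == n) next
    a <- roc_auc(s, g)
    expect_equal(a, oracle_auc(s, g), tolerance = 1e-12)
    expect_equal(roc_auc(-s, g), 1 - a, tolerance = 1e-12)
  }
})

test_that("evaluate_masks assembles a per-slice table with NA for empty masks", {
  set.seed(5)
  gt <- list(random_mask(8, 8, 0.4), matrix(0, 8, 8))
  pr <- list(random_mask(8, 8, 0.4), matrix(0, 8, 8))
  tb <- evaluate_masks(pr, gt, ids = c("a", "b"))
  expect_equal(nrow(tb), 2)
  expect_true(is.na(tb$avgdist[2]))
  expect_equal(tb$dsc[2], 1)  # empty-vs-empty convention
  sm <- summarise_metrics(tb)
  expect_equal(nrow(sm), 1)
})
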