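# Metric suite: confusion tallies, overlap metrics and their identities,
# the soft dice loss, dataset aggregation and paired run comparison.

test_that("confusion counts match naive enumeration", {
  pred <- matrix(c(1, 0, 1, 0), 2, 2)   # column-major: [[1,1],[0,0]] rows
  truth <- matrix(c(1, 1, 0, 0), 2, 2)
  cc <- confusion_counts(pred, truth)
  expect_identical(cc[c("TP", "FP", "FN", "TN")],
                   list(TP = 1L, FP = 1L, FN = 1L, TN = 1L))
  set.seed(31)
  for (i in 1:5) {
    p <- matrix(rbinom(256, 1, 0.4), 16, 16)
    t <- matrix(rbinom(256, 1, 0.3), 16, 16)
    expect_identical(unclass(confusion_counts(p, t))[c("TP", "FP", "FN", "TN")],
                     oracle_confusion(p, t))
  }
  expect_error(confusion_counts(matrix(1, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(1, 2, 2)), "binary")
})

test_that("perfect and inverted predictions give the degenerate tallies", {
  set.seed(32)
  t <- matrix(rbinom(64, 1, 0.5), 8, 8)
  same <- confusion_counts(t, t)
  expect_identical(same$FP + same$FN, 0L)
  inv <- confusion_counts(1 - t, t)
  expect_identical(inv$TP + inv$TN, 0L)
})

test_that("overlap metrics follow their closed forms", {
  c1 <- list(TP = 1, FP = 1, FN = 1, TN = 1)
  expect_equal(jaccard(c1), 1 / 3)
  expect_equal(dice(c1), 0.5)
  expect_equal(dice(c1), 2 * (1 / 3) / (1 / 3 + 1))
  expect_equal(precision(c1), 0.5)
  expect_equal(recall(c1), 0.5)
  expect_equal(precision(list(TP = 5, FP = 0, FN = 3, TN = 0)), 1)
  expect_equal(recall(list(TP = 5, FP = 2, FN = 0, TN = 0)), 1)
  # disjoint non-empty masks
  expect_equal(jaccard(list(TP = 0, FP = 4, FN = 4, TN = 0)), 0)
  expect_equal(dice(list(TP = 0, FP = 4, FN = 4, TN = 0)), 0)
})

test_that("empty-mask conventions return perfect agreement", {
  empty <- list(TP = 0, FP = 0, FN = 0, TN = 16)
  expect_equal(jaccard(empty), 1)
  expect_equal(dice(empty), 1)
  expect_equal(precision(empty), 1)
  expect_equal(recall(empty), 1)
})

test_that("dice equals 2J/(J+1) over many random confusion counts", {
  set.seed(33)
  n <- 10000
  tp <- sample(0:500, n, replace = TRUE)
  fp <- sample(0:500, n, replace = TRUE)
  fn <- sample(0:500, n, replace = TRUE)
  worst <- 0
  for (i in seq_len(n)) {
    cc <- list(TP = tp[i], FP = fp[i], FN = fn[i], TN = 1)
    j <- jaccard(cc)
    worst <- max(worst, abs(dice(cc) - 2 * j / (j + 1)))
  }
  expect_lt(worst, 1e-12)
})

test_that("metric symmetries and bounds hold on random mask pairs", {
  set.seed(34)
  for (i in 1:20) {
    p <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    t <- matrix(rbinom(256, 1, runif(1, 0.1, 0.9)), 16, 16)
    expect_equal(jaccard(confusion_counts(p, t)),
                 jaccard(confusion_counts(t, p)))
    expect_equal(precision(confusion_counts(p, t)),
                 recall(confusion_counts(t, p)))
    j <- jaccard(confusion_counts(p, t)); d <- dice(confusion_counts(p, t))
    expect_gte(d, j)
    expect_true(all(c(j, d) >= 0 & c(j, d) <= 1))
  }
})

test_that("soft dice loss matches hand evaluation and its binary limit", {
  t <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  expect_equal(dice_loss(1 - t, t), 1, tolerance = 1e-5)
  # uniform probability 1/2 against a half-filled 2x2 truth, by hand:
  # num = 2*(0.5+0.5) + eps, den = 4*0.5 + 2 + eps -> loss = 1 - 2/4
  expect_equal(dice_loss(matrix(0.5, 2, 2), t), 1 - 2 / 4, tolerance = 1e-6)
  expect_error(dice_loss(matrix(0.5, 2, 2), matrix(1, 3, 3)), "shape")
  expect_error(dice_loss(matrix(1.5, 2, 2), t), "\\[0, 1\\]")
})

test_that("mean IoU is the plain average and is permutation invariant", {
  expect_equal(mean_iou(c(1, 0))$mean, 0.5)
  expect_equal(mean_iou(0.7)$mean, 0.7)
  set.seed(35)
  v <- runif(30)
  m1 <- mean_iou(v); m2 <- mean_iou(sample(v))
  expect_equal(m1$mean, m2$mean)
  expect_equal(m1$mean, sum(v) / 30)
  expect_error(mean_iou(numeric(0)), "empty")
})

test_that("paired run comparison reproduces the hand-computed t statistic", {
  set.seed(36)
  a <- runif(30, 0.9, 0.95)
  b <- a - 0.01 + rnorm(30, 0, 0.002)
  res <- compare_runs(a, b, paired = TRUE)
  d <- a - b
  tstat <- mean(d) / (sd(d) / sqrt(30))
  p_hand <- 2 * stats::pt(-abs(tstat), df = 29)
  expect_equal(res$statistic, tstat, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_equal(res$df, 29)
})

test_that("degenerate and invalid comparisons are handled explicitly", {
  a <- c(0.9, 0.91, 0.92)
  expect_equal(compare_runs(a, a)$p_value, 1)
  expect_equal(compare_runs(a + 0.01, a)$p_value, 0)  # constant shift, sd 0
  expect_error(compare_runs(a, a[1:2], paired = TRUE), "equally many")
  expect_error(compare_runs(a[1], a[1]), "at least two")
})

test_that("metric reports aggregate per-image metrics", {
  set.seed(37)
  truths <- lapply(1:4, function(i) matrix(rbinom(64, 1, 0.4), 8, 8))
  preds <- truths
  preds[[1]][1, 1] <- 1L - preds[[1]][1, 1]
  rep <- metric_report(preds, truths)
  expect_equal(rep$n_images, 4)
  expect_true(rep$miou < 1 && rep$miou > 0.9)
  expect_equal(rep$per_image$jaccard[2], 1)
})
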