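test_that("confusion counts match a per-pixel oracle", {
  set.seed(1)
  for (rep in 1:5) {
    p <- random_mask(9, 11); t <- random_mask(9, 11)
    cc <- confusion_counts(p, t)
    oc <- counts_oracle(p, t)
    expect_equal(cc$tp, oc$tp)
    expect_equal(cc$fp, oc$fp)
    expect_equal(cc$fn, oc$fn)
    expect_equal(cc$tn, oc$tn)
  }
  expect_error(confusion_counts(random_mask(3, 3), random_mask(3, 4)),
               "shape mismatch")
  expect_error(confusion_counts(matrix(0.5, 2, 2), matrix(0, 2, 2)),
               "binary")
})

test_that("Dice/IoU identities and conventions hold", {
  set.seed(2)
  for (rep in 1:20) {
    cc <- confusion_counts(random_mask(8, 8), random_mask(8, 8))
    d <- dice_coefficient(cc); j <- jaccard_index(cc)
    expect_equal(d, dice_from_jaccard(j), tolerance = 1e-12)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
  }
  empty <- confusion_counts(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(dice_coefficient(empty), 1.0)
  expect_equal(jaccard_index(empty), 1.0)
  pr <- precision_recall(empty)
  expect_true(is.na(pr["precision"]))
  expect_true(is.na(pr["recall"]))
})

test_that("AUC matches the pROC reference implementation", {
  skip_if_not_installed("pROC")
  set.seed(3)
  for (rep in 1:5) {
    prob <- matrix(stats::runif(64), 8, 8)
    truth <- random_mask(8, 8)
    if (sum(truth) == 0 || sum(truth) == 64) next
    ref <- as.numeric(pROC::auc(pROC::roc(as.vector(truth), as.vector(prob),
                                          quiet = TRUE, direction = "<")))
    expect_equal(auc_roc(prob, truth), ref, tolerance = 1e-10)
  }
  expect_true(is.na(auc_roc(matrix(0.5, 2, 2), matrix(1, 2, 2))))
})

test_that("HD95 matches a brute-force oracle on small masks", {
  set.seed(4)
  for (rep in 1:6) {
    p <- random_mask(12, 12, 0.3); t <- random_mask(12, 12, 0.3)
    if (sum(p) == 0 || sum(t) == 0) next
    expect_equal(hd95(p, t), hd95_oracle(p, t), tolerance = 1e-9)
  }
  m <- matrix(0, 8, 8); m[3:6, 3:6] <- 1
  expect_equal(hd95(m, m), 0)
  expect_true(is.na(hd95(m, matrix(0, 8, 8))))
})

test_that("Dice loss is correct and its gradient passes finite differences", {
  set.seed(5)
  prob <- matrix(stats::runif(36), 6, 6)
  truth <- random_mask(6, 6)
  l <- dice_loss(prob, truth)
  expect_true(l >= 0 && l <= 1)
  expect_lt(dice_loss(truth, truth), dice_loss(1 - truth, truth))
  g <- imauseg:::dice_loss_grad(prob, truth)
  eps <- 1e-6
  for (idx in list(c(1, 1), c(3, 4), c(6, 6))) {
    dp <- matrix(0, 6, 6); dp[idx[1], idx[2]] <- eps
    fd <- (dice_loss(prob + dp, truth) - dice_loss(prob - dp, truth)) /
      (2 * eps)
    expect_lt(abs(fd - g[idx[1], idx[2]]), 1e-7)
  }
})

test_that("MAE and prediction evaluation behave", {
  prob <- matrix(c(0.2, 0.8, 0.6, 0.4), 2, 2)
  truth <- matrix(c(0, 1, 1, 0), 2, 2)
  expect_equal(mean_absolute_error(prob, truth), mean(c(0.2, 0.2, 0.4, 0.4)))
  row <- evaluate_prediction(prob, truth, sample_id = "s1")
  expect_equal(row$dice, 1)
  expect_equal(row$mae, 0.3)
  expect_identical(row$sample_id, "s1")
})
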