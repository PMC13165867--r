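test_that("fold aggregation uses the mean and population std", {
  x <- data.frame(m = c(1, 2, 3, 4))
  agg <- aggregate_folds(x)
  expect_equal(unname(agg$mean["m"]), 2.5)
  expect_equal(unname(agg$std["m"]), sqrt(mean((c(1, 2, 3, 4) - 2.5)^2)))
  expect_error(aggregate_folds(data.frame(m = 1)), "at least 2")
})

test_that("fixed-decimal serialization rounds half away from zero", {
  expect_identical(format_fixed(0.91785), "0.9179")
  expect_identical(format_fixed(0.05848), "0.0585")
  expect_identical(format_fixed(0.86852), "0.8685")
  expect_identical(format_fixed(-0.00005), "-0.0001")
})

test_that("paired t-test matches stats::t.test and flags degeneracy", {
  set.seed(10)
  a <- rnorm(8); b <- rnorm(8)
  res <- paired_t_test(a, b)
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(res$p_value, ref$p.value)
  expect_equal(res$statistic, unname(ref$statistic))
  expect_false(res$degenerate)
  deg <- paired_t_test(a, a + 0.5)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p_value))
  expect_equal(deg$mean_difference, -0.5)
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("external validation report computes the drops", {
  rep <- external_validation_report(list(dice = 0.9, auc = 0.95),
                                    list(dice = 0.85, auc = 0.93))
  expect_equal(rep$dice_drop, 0.05)
  expect_equal(rep$dice_drop_pct_points, 5)
  expect_equal(rep$auc_drop, 0.02, tolerance = 1e-12)
  expect_error(external_validation_report(list(dice = 0.9), list(dice = 0.8)),
               "auc")
})

test_that("delta helpers difference against the baseline and pairwise", {
  tab <- data.frame(variant = c("a", "b", "c"), dice = c(0.8, 0.85, 0.9))
  out <- ablation_deltas(tab, "dice")
  expect_equal(out$delta_dice, c(0, 0.05, 0.1))
  pw <- pairwise_differences(tab, "dice", "variant")
  expect_equal(nrow(pw), 6)
  expect_equal(pw$difference[pw$a == "c" & pw$b == "a"], 0.1)
})

test_that("bundled reference tables load with the expected shapes", {
  cv <- reference_table("cv_folds")
  expect_equal(nrow(cv), 5)
  expect_true(all(c("dice", "iou", "precision", "recall", "mae") %in%
                    names(cv)))
  expect_equal(nrow(reference_table("architecture")), 4)
  expect_equal(nrow(reference_table("controlled")), 4)
  expect_equal(nrow(reference_table("preprocessing")), 4)
  expect_equal(nrow(reference_table("external")), 6)
})
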