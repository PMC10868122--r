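test_that("confusion counts tally the four cells", {
  y <- c(rep(1, 5), rep(0, 5))
  expect_equal(confusion_counts(y, y),
               c(TP = 5L, TN = 5L, FP = 0L, FN = 0L))
  half <- c(rep(1, 50), rep(0, 50))
  expect_equal(confusion_counts(half, rep(1, 100)),
               c(TP = 50L, TN = 0L, FP = 50L, FN = 0L))
  set.seed(41)
  yt <- rbinom(100, 1, 0.4); yp <- rbinom(100, 1, 0.6)
  cc <- confusion_counts(yt, yp)
  tally <- c(TP = 0L, TN = 0L, FP = 0L, FN = 0L)
  for (i in 1:100) {
    cell <- if (yt[i] == 1 && yp[i] == 1) "TP"
      else if (yt[i] == 0 && yp[i] == 0) "TN"
      else if (yt[i] == 0) "FP" else "FN"
    tally[cell] <- tally[cell] + 1L
  }
  expect_equal(cc, tally)
  expect_error(confusion_counts(yt, yp[-1]), "lengths")
  expect_error(confusion_counts(c(0, 2), c(0, 1)), "binary")
})

test_that("metrics match the printed formulas, zero denominators give 0", {
  perfect <- classification_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(perfect$Acc, 1); expect_equal(perfect$MCC, 1)
  expect_equal(perfect$F1, 1)

  allpos <- classification_metrics(c(TP = 50, TN = 0, FP = 50, FN = 0))
  expect_equal(allpos$Sn, 1); expect_equal(allpos$Sp, 0)
  expect_equal(allpos$Acc, 0.5); expect_equal(allpos$MCC, 0)

  r <- classification_metrics(c(TP = 40, TN = 30, FP = 20, FN = 10))
  expect_equal(r$Sn, 40 / 50)
  expect_equal(r$Sp, 30 / 50)
  expect_equal(r$Acc, 70 / 100)
  expect_equal(r$MCC, (40 * 30 - 20 * 10) / sqrt(60 * 50 * 50 * 40))
  expect_equal(r$F1, 80 / (80 + 20 + 10))
})

test_that("auroc is the Mann-Whitney pair statistic with half ties", {
  y <- c(0, 0, 1, 1)
  expect_equal(auroc(y, c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auroc(y, c(0.9, 0.8, 0.2, 0.1)), 0)
  set.seed(42)
  for (i in 1:10) {
    y <- c(rep(1, 8), rep(0, 12))[sample(20)]
    s <- sample(seq(0, 1, by = 0.1), 20, replace = TRUE)  # forces ties
    expect_equal(auroc(y, s), oracle_auroc(y, s))
  }
  expect_error(auroc(rep(1, 5), runif(5)), "both classes")
})

test_that("auroc agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(43)
  y <- rbinom(60, 1, 0.5); y[1:2] <- c(0, 1)
  s <- runif(60)
  expect_equal(auroc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("stratified 70/30 split is exhaustive, disjoint, proportional", {
  lab <- c(rep(1, 5), rep(0, 5))
  sp <- split_70_30(lab, seed = 1)
  expect_length(sp$train, 7L)
  expect_length(sp$test, 3L)
  expect_identical(split_70_30(lab, seed = 1), sp)
  set.seed(44)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    lab <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(lab)) < 2) next
    sp <- split_70_30(lab, seed = i)
    expect_equal(sort(c(sp$train, sp$test)), seq_len(n))
    expect_length(sp$train, round(0.7 * n))
    for (cls in 0:1) {
      expect_lte(abs(sum(lab[sp$train] == cls) -
                       0.7 * sum(lab == cls)), 1)
    }
  }
})

test_that("kfold plans are balanced partitions", {
  expect_equal(sort(table(kfold_plan(10, 10, seed = 1))),
               sort(table(1:10)))
  sizes <- as.integer(table(kfold_plan(25, 10, seed = 2)))
  expect_equal(sort(sizes), c(rep(2L, 5), rep(3L, 5)))
  set.seed(45)
  for (i in 1:20) {
    k <- sample(2:10, 1); n <- k + sample(0:90, 1)
    f <- kfold_plan(n, k, seed = i)
    expect_length(f, n)
    expect_setequal(unique(f), seq_len(k))
    expect_lte(diff(range(table(f))), 1L)
  }
  expect_error(kfold_plan(5, 10), "at least")
})

test_that("pooled two-proportion z test matches the closed form", {
  eq <- z_two_proportion(50, 100, 50, 100)
  expect_equal(eq$z, 0); expect_equal(eq$p, 1)
  r <- z_two_proportion(90, 100, 60, 100)
  pool <- 150 / 200
  z_hand <- (0.9 - 0.6) / sqrt(pool * (1 - pool) * (1 / 100 + 1 / 100))
  expect_equal(r$z, z_hand)
  expect_equal(r$p, 2 * pnorm(-abs(z_hand)))
  swapped <- z_two_proportion(60, 100, 90, 100)
  expect_equal(swapped$z, -r$z)
  expect_equal(swapped$p, r$p)
  expect_error(z_two_proportion(1, 0, 1, 5), "positive")
})

test_that("McNemar switches between exact and corrected forms", {
  sym <- mcnemar_test(30, 30)
  expect_equal(sym$statistic, 0); expect_equal(sym$p, 1)
  ex <- mcnemar_test(10, 0)
  expect_equal(ex$method, "exact binomial")
  expect_equal(ex$p, 2 * 0.5^10)
  expect_equal(mcnemar_test(3, 9)$p, mcnemar_test(9, 3)$p)
  big <- mcnemar_test(40, 20)
  expect_equal(big$statistic, (abs(40 - 20) - 1)^2 / 60)
  expect_error(mcnemar_test(0, 0), "undefined")
})

test_that("resampled paired t test is null for self-comparison", {
  toy <- toy_separable(n = 40, p = 6)
  r <- resampled_paired_ttest(toy$X, toy$y, "decision_tree",
                              "decision_tree", trials = 3, seed = 1)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_length(r$diffs, 3L)
  expect_error(resampled_paired_ttest(toy$X, toy$y, "hgb", "xgb",
                                      trials = 1), "two trials")
})

test_that("resampled t test separates a real model from a stunted one", {
  set.seed(46)
  toy <- toy_separable(n = 60, p = 6)
  weak <- model_spec("decision_tree", max_depth = 1,
                     min_samples_leaf = 500)  # forced root-only tree
  r <- resampled_paired_ttest(toy$X, toy$y, "decision_tree", weak,
                              trials = 6, seed = 2)
  expect_lt(r$p, 0.05)
  expect_gt(mean(r$diffs), 0)
})
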