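# Confusion matrices, accuracy, cross-validation, baselines.

test_that("confusion counts follow the fatigued-positive convention", {
  act <- rep(c("fatigued", "alert"), each = 10)
  cm <- confusion_matrix(act, act)
  expect_identical(unname(unclass(cm)), c(10L, 0L, 0L, 10L))
  allalert <- confusion_matrix(rep("alert", 20), rep("fatigued", 20))
  expect_identical(unname(unclass(allalert)), c(0L, 20L, 0L, 0L))
  pred <- c(rep("fatigued", 18), rep("alert", 2),   # 18 TP, 2 FN
            rep("fatigued", 1), rep("alert", 19))   # 1 FP, 19 TN
  act2 <- rep(c("fatigued", "alert"), each = 20)
  expect_identical(unname(unclass(confusion_matrix(pred, act2))),
                   c(18L, 2L, 1L, 19L))
  expect_error(confusion_matrix("alert", c("alert", "alert")),
               class = "mmfatigue_invalid_parameter")
})

test_that("accuracy is the correct fraction in percent", {
  expect_equal(accuracy(c(18, 2, 1, 19)), 92.5)
  expect_equal(accuracy(c(16, 4, 6, 14)), 75)
  expect_equal(accuracy(c(0, 0, 0, 40)), 100)
  expect_error(accuracy(c(0, 0, 0, 0)),
               class = "mmfatigue_invalid_parameter")
  # swapping the positive/negative convention leaves accuracy unchanged
  set.seed(1)
  for (i in 1:20) {
    cm <- sample(0:30, 4)
    if (sum(cm) == 0) next
    expect_equal(accuracy(cm), accuracy(cm[c(4, 3, 2, 1)]))
  }
})

test_that("stratified folds partition each class evenly", {
  labels <- rep(c("alert", "fatigued"), each = 21)
  fold <- stratified_folds(labels, 3, seed = 2)
  expect_identical(sort(unique(fold)), 1:3)
  for (f in 1:3)
    expect_identical(as.integer(table(labels[fold == f])), c(7L, 7L))
  expect_identical(stratified_folds(labels, 3, seed = 2), fold)
  expect_error(stratified_folds(c("alert", "fatigued"), 3),
               class = "mmfatigue_invalid_parameter")
})

separable_records <- function(n, seed) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    fat <- i > n / 2
    mu <- if (fat) 1 else 0
    make_record(sprintf("S%02d", i),
      v = c(0.3 + mu + rnorm(1, 0, 0.2), 0.03, 0.03, 0.06,
            3 + 4 * mu + rnorm(1, 0, 0.5), 1 + 2 * mu),
      t = c(15000 + 2000 * mu + rnorm(1, 0, 400),
            5e5 + 2e5 * mu + rnorm(1, 0, 3e4),
            5e5 + 2e5 * mu + rnorm(1, 0, 3e4),
            4e5 + 2e5 * mu + rnorm(1, 0, 3e4),
            4e5 + 2e5 * mu + rnorm(1, 0, 3e4)),
      k = c(52, round(2 * mu + runif(1)), 3 * mu + runif(1),
            9.5 + 1.3 * mu + rnorm(1, 0, 0.2)),
      s = c(190 - 35 * mu + rnorm(1, 0, 5), 0.66, -6 - 3 * mu,
            0.2 - 0.08 * mu, 1.8 + 0.5 * mu + rnorm(1, 0, 0.1)),
      label = if (fat) "fatigued" else "alert")
  })
}

test_that("cross-validation averages fold accuracies and is seeded", {
  recs <- separable_records(24, seed = 3)
  rep1 <- suppressWarnings(kfold_cv(recs, k = 3, seed = 5,
                                    resolution = 0.05))
  expect_equal(rep1$average, mean(rep1$accuracies))
  sizes <- vapply(rep1$confusions, function(cm) sum(unclass(cm)),
                  numeric(1))
  expect_identical(unname(sizes), rep(8, 3))
  expect_gte(rep1$average, 90)
  rep2 <- suppressWarnings(kfold_cv(recs, k = 3, seed = 5,
                                    resolution = 0.05))
  expect_identical(rep1$accuracies, rep2$accuracies)
  # leave-one-out on a separable cohort is perfect
  loo <- suppressWarnings(kfold_cv(separable_records(12, seed = 4),
                                   k = 6, seed = 1, resolution = 0.05))
  expect_equal(loo$average, 100)
})

test_that("baselines train on a fixed split and report counts", {
  recs <- separable_records(30, seed = 6)
  tab <- suppressWarnings(baseline_comparison(recs, seed = 1))
  expect_setequal(tab$classifier,
                  c("knn", "random_tree", "random_forest", "svm", "mlp",
                    "fusion"))
  expect_equal(tab$accuracy, 100 * tab$correct / tab$n_test)
  expect_true(all(tab$correct + tab$incorrect == tab$n_test))
  expect_true(all(tab$accuracy >= 80))
  tab2 <- suppressWarnings(baseline_comparison(recs, seed = 1))
  expect_identical(tab, tab2)
  expect_error(baseline_comparison(recs, classifiers = "adaboost"),
               class = "mmfatigue_invalid_parameter")
})
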