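# Splits, metrics, confidence summaries, and the CV harness.

test_that("kfold_split partitions deterministically with near-equal sizes", {
  folds <- kfold_split(10, 5, seed = 3)
  expect_length(folds, 5L)
  expect_equal(vapply(folds, length, integer(1)), rep(2L, 5))
  expect_equal(sort(unlist(folds)), 1:10)
  expect_identical(folds, kfold_split(10, 5, seed = 3))
  # uneven n: sizes differ by at most one
  folds2 <- kfold_split(13, 5, seed = 1)
  expect_equal(sort(unlist(folds2)), 1:13)
  expect_lte(diff(range(vapply(folds2, length, integer(1)))), 1L)
  expect_error(kfold_split(3, 5), "at least k")
})

test_that("stratified folds balance the classes", {
  labels <- rep(0:2, each = 20)
  folds <- kfold_split(60, 5, seed = 9, labels = labels)
  expect_equal(sort(unlist(folds)), 1:60)
  for (f in folds) expect_equal(unname(table(labels[f])), rep(4L, 3),
                                ignore_attr = TRUE)
})

test_that("classification metrics match a hand-computed confusion matrix", {
  m <- classification_metrics(c(0, 0, 1, 1), c(0, 1, 1, 1), 2)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$per_class$precision, c(1, 2 / 3))
  expect_equal(m$per_class$recall, c(0.5, 1))
  expect_equal(m$per_class$f1, c(2 / 3, 0.8))
  # perfect predictions
  mp <- classification_metrics(0:2, 0:2, 3)
  expect_equal(mp$accuracy, 1)
  expect_equal(unname(mp$weighted), rep(1, 3))
  # all-one-class predictions on a balanced 3-class set
  expect_warning(
    mc <- classification_metrics(rep(0:2, each = 4), rep(1L, 12), 3),
    "zero denominator")
  expect_equal(mc$accuracy, 1 / 3)
  expect_error(classification_metrics(0:2, 0:1, 3), "length")
})

test_that("weighted recall equals accuracy on random confusions", {
  set.seed(21)
  for (r in 1:20) {
    nc <- sample(2:5, 1)
    n <- sample(20:60, 1)
    y <- sample(0:(nc - 1), n, replace = TRUE)
    p <- sample(0:(nc - 1), n, replace = TRUE)
    if (length(unique(y)) < nc) next  # degenerate support handled elsewhere
    m <- classification_metrics(y, p, nc)
    expect_equal(unname(m$weighted["recall"]), m$accuracy, tolerance = 1e-12)
  }
})

test_that("cv_confidence reports mean +/- margin with selectable estimator", {
  c1 <- cv_confidence(rep(0.9, 5))
  expect_equal(c1$mean, 0.9)
  expect_equal(c1$margin, 0)
  expect_equal(c(c1$ci_low, c1$ci_high), c(0.9, 0.9))
  c2 <- cv_confidence(c(0.8, 1.0))
  expect_equal(c2$mean, 0.9)
  expect_equal(c2$margin, sd(c(0.8, 1.0)), tolerance = 1e-12)
  expect_equal(c2$margin, 0.1414, tolerance = 1e-3)
  expect_equal(c2$ci_low, c2$mean - c2$margin)
  expect_equal(c2$ci_high, c2$mean + c2$margin)
  c3 <- cv_confidence(c(0.8, 0.9, 1.0), estimator = "se")
  expect_equal(c3$margin, sd(c(0.8, 0.9, 1.0)) / sqrt(3))
  c4 <- cv_confidence(c(0.8, 0.9, 1.0), estimator = "t95")
  expect_gt(c4$margin, c3$margin)
  expect_error(cv_confidence(0.9), "at least 2")
})

test_that("a small CV experiment emits a coherent, serialisable report", {
  d <- tiny_two_class(n_per_class = 12L)
  cfg <- fast_config(epochs = 4L)
  rep <- run_cv_experiment(d$images, d$labels, "CZ", 1L, cfg, k = 3L, seed = 5)
  expect_s3_class(rep, "cv_report")
  expect_length(rep$fold_accuracies, 3L)
  expect_true(all(rep$fold_accuracies >= 0 & rep$fold_accuracies <= 1))
  expect_equal(rep$mean, mean(rep$fold_accuracies), tolerance = 1e-12)
  expect_lte(rep$ci_low, rep$mean)
  expect_gte(rep$ci_high, rep$mean)
  expect_equal(rep$ci_low, rep$mean - rep$margin)
  # round trip
  back <- cv_report_from_json(cv_report_json(rep))
  expect_equal(back$fold_accuracies, rep$fold_accuracies)
  expect_equal(back$mean, rep$mean)
  expect_equal(back$per_class, rep$per_class, ignore_attr = TRUE)
  # tabular and tidy views
  row <- report_row(rep)
  expect_equal(names(row), c("model", "optimizer", "train_acc", "test_acc",
                             "precision", "recall", "f1", "mean_cv_acc",
                             "margin", "ci_low", "ci_high"))
  td <- tidy.cv_report(rep)
  expect_equal(td$accuracy, rep$fold_accuracies)
})

test_that("entangler comparison uses identical folds for both arms", {
  d <- tiny_two_class(n_per_class = 9L)
  cfg <- fast_config(epochs = 3L)
  cmp <- compare_entanglers(d$images, d$labels, n_layers = 1L, config = cfg,
                            k = 3L, seed = 8)
  expect_identical(cmp$cnot$folds, cmp$cz$folds)
  expect_equal(nrow(cmp$table), 2L)
  expect_equal(cmp$table$model, c("NNQEv1 (CNOT, L=1)", "NNQEv2 (CZ, L=1)"))
})

test_that("stability probe returns finite dispersions for both entanglers", {
  d <- tiny_two_class(n_per_class = 10L)
  st <- entangler_stability(d$images, d$labels, n_layers = 1L,
                            config = fast_config(epochs = 3L), seeds = 1:3)
  expect_equal(sort(st$entangler), c("CNOT", "CZ"))
  expect_true(all(is.finite(st$sd_val_accuracy)))
  expect_equal(dim(attr(st, "per_seed")), c(3L, 2L))
})
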