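test_that("an exactly divisible class partitions across validation folds", {
  pats <- data.frame(patient_id = sprintf("F%02d", 1:15), class = "FLE")
  pats <- rbind(pats, data.frame(patient_id = sprintf("T%02d", 1:11),
                                 class = "TLE"))
  folds <- make_cv_folds(pats, k = 5, val_per_class = c(FLE = 3, TLE = 3),
                         seed = 2)
  expect_length(folds, 5L)
  fle_val <- unlist(lapply(folds, function(f)
    grep("^F", f$val_patients, value = TRUE)))
  expect_equal(sort(unique(fle_val)), sprintf("F%02d", 1:15))
  expect_equal(length(fle_val), 15L)         # each FLE patient exactly once
  for (f in folds) {
    expect_length(intersect(f$train_patients, f$val_patients), 0L)
    expect_equal(length(grep("^F", f$train_patients)), 12L)
    expect_equal(length(grep("^T", f$train_patients)), 8L)
    expect_equal(unname(as.integer(f$val_counts)), c(3L, 3L))
  }
  # short TLE pool: every patient still validated at least once
  tle_val <- unlist(lapply(folds, function(f)
    grep("^T", f$val_patients, value = TRUE)))
  expect_setequal(unique(tle_val), sprintf("T%02d", 1:11))
  expect_error(make_cv_folds(pats, val_per_class = c(FLE = 3, TLE = 11)),
               "need more")
})

test_that("fold building is seeded and leakage-free for every sample", {
  pats <- data.frame(patient_id = sprintf("P%02d", 1:9),
                     class = rep(c("FLE", "TLE", "Prepost"), each = 3))
  a <- make_cv_folds(pats, k = 4, seed = 7)
  b <- make_cv_folds(pats, k = 4, seed = 7)
  expect_identical(lapply(a, `[[`, "val_patients"),
                   lapply(b, `[[`, "val_patients"))
  for (f in a) {
    expect_setequal(c(f$train_patients, f$val_patients), pats$patient_id)
    expect_length(intersect(f$train_patients, f$val_patients), 0L)
  }
})

test_that("confusion matrices count every (true, predicted) pair", {
  expect_equal(confusion_matrix(c(1, 2, 3), c(1, 2, 3), 3), diag(3),
               ignore_attr = TRUE)
  withr::with_seed(12, {
    yt <- sample(1:4, 100, replace = TRUE)
    yp <- sample(1:4, 100, replace = TRUE)
    cm <- confusion_matrix(yt, yp, 4)
    expect_equal(sum(cm), 100)
    for (i in 1:4) for (j in 1:4)
      expect_equal(cm[i, j], sum(yt == i & yp == j))
  })
  expect_error(confusion_matrix(c(1, 5), c(1, 2), 4), "out of range")
  f <- factor(c("a", "b"), levels = c("a", "b", "c"))
  expect_equal(dim(confusion_matrix(f, f)), c(3L, 3L))
})

test_that("macro metrics match hand computation on the worked example", {
  cm <- matrix(c(8, 2, 3, 7), 2, byrow = TRUE)
  mm <- macro_metrics(cm)
  expect_equal(mm$per_class$f1, c(2 * (8 / 11) * 0.8 / (8 / 11 + 0.8),
                                  2 * (7 / 9) * 0.7 / (7 / 9 + 0.7)),
               tolerance = 1e-10)
  expect_equal(mm$per_class$f1, c(0.7619048, 0.7368421), tolerance = 1e-6)
  expect_equal(mm$macro_f1, 0.7493734, tolerance = 1e-6)
  expect_equal(macro_metrics(diag(5) * 3)$macro_f1, 1)
  ss <- sensitivity_specificity(cm)
  expect_equal(ss$sensitivity, c(0.8, 0.7))
  expect_equal(ss$specificity, c(0.7, 0.8))
})

test_that("degenerate predictions trigger the zero-division convention", {
  # everything predicted as class 1, both classes present
  cm <- matrix(c(10, 0, 5, 0), 2, byrow = TRUE)
  mm <- macro_metrics(cm)
  expect_true(mm$zero_division)
  f1_pred <- mm$per_class$f1[1]
  expect_equal(mm$macro_f1, f1_pred / 2)
  ss <- sensitivity_specificity(matrix(c(0, 0, 2, 3), 2, byrow = TRUE))
  expect_equal(ss$sensitivity[1], 0)         # empty true class
  expect_true(attr(ss, "zero_division"))
  expect_equal(sensitivity_specificity(diag(3))$specificity, rep(1, 3))
})

test_that("macro metrics agree with the counting oracle on random matrices", {
  withr::with_seed(3, {
    for (i in 1:100) {
      C <- sample(2:5, 1)
      cm <- matrix(rpois(C * C, 4), C, C)
      if (sum(cm) == 0) cm[1, 1] <- 1
      want <- counting_metrics(cm)
      mm <- macro_metrics(cm)
      expect_equal(mm$macro_f1, want$macro_f1, tolerance = 1e-12)
      expect_equal(mm$per_class$precision, want$precision)
      ss <- sensitivity_specificity(cm)
      expect_equal(ss$sensitivity, want$sensitivity)
      expect_equal(ss$specificity, want$specificity)
    }
  })
})

test_that("macro-F1 is invariant to uniform duplication of all classes", {
  withr::with_seed(8, {
    cm <- matrix(rpois(9, 5) + 1, 3, 3)
    expect_equal(macro_metrics(cm)$macro_f1, macro_metrics(cm * 7)$macro_f1)
  })
})

test_that("fold summaries report mean and sample standard deviation", {
  fm <- data.frame(macro_f1 = c(0.8, 0.9))
  s <- summarize_folds(fm)
  expect_equal(s["mean", "macro_f1"], 0.85)
  expect_equal(s["sd", "macro_f1"], sd(c(0.8, 0.9)))
  expect_equal(s["sd", "macro_f1"], 0.0707107, tolerance = 1e-6)
  same <- summarize_folds(data.frame(f1 = rep(0.7, 5)))
  expect_equal(same["sd", "f1"], 0)
  one <- summarize_folds(data.frame(f1 = 0.6))
  expect_equal(one["mean", "f1"], 0.6)
  expect_equal(one["sd", "f1"], 0)
  expect_true(attr(one, "single_fold"))
})
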