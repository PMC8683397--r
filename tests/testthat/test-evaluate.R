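# Independent AUROC oracle: trapezoidal integration of the empirical ROC.
trapezoid_auroc <- function(y, s) {
  th <- sort(unique(s), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(s[y == 1] >= t), numeric(1)), 1)
  fpr <- c(0, vapply(th, function(t) mean(s[y == 0] >= t), numeric(1)), 1)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

fake_dataset <- function(seg_counts) {
  n <- sum(seg_counts)
  structure(list(
    segments = matrix(0, n, 4),
    subject_id = rep(names(seg_counts), seg_counts),
    role = "mECG",
    labels = data.frame(subject_id = names(seg_counts),
                        group = "control", pss = 10, pdq = 10,
                        cortisol = 5, fsi = 0)
  ), class = "segment_dataset")
}

test_that("within-subject folds partition each subject into near-equal parts", {
  ds <- fake_dataset(c(A = 10, B = 11, C = 5))
  fs <- make_within_subject_folds(ds, k = 5, seed = 1)

  # exact partition of all segments
  all_test <- sort(unlist(fs$test_indices))
  expect_identical(all_test, seq_len(26))

  sizes_a <- table(fs$fold[ds$subject_id == "A"])
  expect_true(all(sizes_a == 2))
  sizes_b <- sort(as.integer(table(fs$fold[ds$subject_id == "B"])))
  expect_identical(sizes_b, c(2L, 2L, 2L, 2L, 3L))
  sizes_c <- table(fs$fold[ds$subject_id == "C"])
  expect_true(all(sizes_c == 1))

  # deterministic under seed
  fs2 <- make_within_subject_folds(ds, k = 5, seed = 1)
  expect_identical(fs$fold, fs2$fold)

  # subjects with too few segments are dropped with a warning
  ds_small <- fake_dataset(c(A = 10, B = 3))
  expect_warning(fs3 <- make_within_subject_folds(ds_small, k = 5, seed = 2),
                 "dropped")
  expect_true(all(is.na(fs3$fold[ds_small$subject_id == "B"])))
})

test_that("classification metrics follow the confusion matrix and rank AUROC", {
  perfect <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_true(all(unlist(perfect) == 1))

  m <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.1))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 0.5)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$auroc, 1)  # both positives outrank both negatives

  # tie between a positive and a negative contributes 1/2: AUROC 3.5/4
  mt <- classification_metrics(c(1, 1, 0, 0), c(0.9, 0.7, 0.7, 0.1))
  expect_equal(mt$auroc, 0.875)

  anti <- classification_metrics(c(1, 1, 0, 0), c(0.1, 0.2, 0.8, 0.9))
  expect_equal(anti$auroc, 0)

  expect_error(classification_metrics(c(1, 1), c(0.4, 0.6)), "single-class")
})

test_that("rank AUROC equals trapezoidal ROC integration on random score sets", {
  with_seed_test(4, {
    for (rep in 1:200) {
      n <- sample(10:40, 1)
      y <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      s <- round(stats::runif(n), 2)  # rounding forces ties
      expect_lt(abs(classification_metrics(y, s)$auroc - trapezoid_auroc(y, s)),
                1e-12)
    }
  })
})

test_that("regression metrics match their textbook definitions", {
  exact <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unlist(exact), c(r2 = 1, mae = 0, rmse = 0))

  mp <- regression_metrics(c(0, 2), c(1, 1))  # the mean predictor
  expect_equal(unlist(mp), c(r2 = 0, mae = 1, rmse = 1))

  with_seed_test(5, {
    y <- stats::rnorm(50); p <- stats::rnorm(50)
    m <- regression_metrics(y, p)
    expect_lt(abs(m$r2 - (1 - sum((y - p)^2) / sum((y - mean(y))^2))), 1e-12)
    expect_lt(abs(m$mae - mean(abs(y - p))), 1e-12)
    expect_lt(abs(m$rmse - sqrt(mean((y - p)^2))), 1e-12)
    expect_gte(m$rmse, m$mae)
  })

  expect_error(regression_metrics(c(2, 2), c(1, 3)), "constant")
})

test_that("fold comparison uses the exact Mann-Whitney test with Holm criterion", {
  same <- compare_fold_metrics(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(same$p, 1)
  expect_false(same$significant)

  sep <- compare_fold_metrics(1:5, 6:10)
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / 252, tolerance = 1e-12)
  expect_true(sep$significant)
  expect_equal(sep$criterion, 0.025)

  # U = 2: exact two-sided p = 8/252 = 0.0317, significant alone at 0.05
  # but not against the two-comparison Holm first step of 0.025
  u2 <- compare_fold_metrics(c(1, 2, 3, 4, 7), c(5, 6, 8, 9, 10))
  expect_equal(u2$p, 8 / 252, tolerance = 1e-12)
  expect_false(u2$significant)
  expect_true(compare_fold_metrics(c(1, 2, 3, 4, 7), c(5, 6, 8, 9, 10),
                                   n_comparisons = 1)$significant)

  expect_error(compare_fold_metrics(1:2, 3:4), "insufficient")
})
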