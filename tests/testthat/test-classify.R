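test_that("standardize z-scores with training moments", {
  tab <- data.frame(video_id = c("a", "b"), label = c("healthy", "celiac"))
  x <- cbind(c(1, 3), matrix(5, 2, 29))
  colnames(x) <- celiascope:::summary_column_names()
  ds <- celiascope:::new_dataset(x, tab$label, tab$video_id)
  std <- standardize(ds)
  expect_equal(unname(std$dataset$x[, 1]), c(-1, 1))        # population sd
  expect_equal(unname(std$dataset$x[, 2]), c(0, 0))         # zero variance
  expect_equal(unname(colMeans(std$dataset$x)), rep(0, 30))

  # scaler transfers to new data
  ds2 <- celiascope:::dataset_subset(ds, c(1, 2))
  expect_equal(apply_standardization(std$scaler, ds2)$x, std$dataset$x)
})

test_that("split_dataset stratifies, partitions and is reproducible", {
  ds <- toy_dataset(10)
  sp <- split_dataset(ds, 0.5, seed = 42)
  expect_equal(as.integer(table(sp$train$labels)), c(5L, 5L))
  expect_equal(as.integer(table(sp$test$labels)), c(5L, 5L))
  expect_setequal(c(sp$train$ids, sp$test$ids), ds$ids)
  expect_length(intersect(sp$train$ids, sp$test$ids), 0)

  sp2 <- split_dataset(ds, 0.5, seed = 42)
  expect_identical(sp$train$ids, sp2$train$ids)

  tiny <- celiascope:::dataset_subset(ds, c(1, 11, 12))
  expect_error(split_dataset(tiny), "at least 2")
})

test_that("fine and weighted KNN agree with the exhaustive oracle", {
  for (seed in 1:10) {
    withr::with_seed(seed, {
      x <- matrix(rnorm(40), 20, 2)
      y <- sample(c("healthy", "celiac"), 20, replace = TRUE,
                  prob = c(0.5, 0.5))
      q <- matrix(rnorm(10), 5, 2)
    })
    if (length(unique(y)) < 2) next
    ds <- celiascope:::new_dataset(x, y, sprintf("s%02d", 1:20))
    fine <- fit_fine_knn(ds, k = 3)
    wk <- fit_weighted_knn(ds, k = 3)
    for (i in 1:5) {
      expect_identical(predict(fine, q[i, ]),
                       oracle_knn_predict(x, y, q[i, ], 3, weighted = FALSE))
      expect_identical(predict(wk, q[i, ]),
                       oracle_knn_predict(x, y, q[i, ], 3, weighted = TRUE))
    }
  }
})

test_that("KNN handles exact matches, majorities and weighted inversions", {
  x <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  ds <- celiascope:::new_dataset(x, c("healthy", "healthy", "celiac", "celiac"),
                                 c("a", "b", "c", "d"))
  one <- fit_fine_knn(ds, k = 1)
  expect_identical(predict(one, c(5, 5)), "celiac")   # exact match

  three <- fit_fine_knn(ds, k = 3)
  expect_identical(predict(three, c(0.2, 0.2)), "healthy")  # 2-vs-1 majority

  # two near celiac points vs one far healthy point: inverse-distance wins
  x2 <- rbind(c(0.1, 0), c(-0.1, 0), c(3, 0), c(50, 50))
  ds2 <- celiascope:::new_dataset(x2, c("celiac", "celiac", "healthy", "healthy"),
                                  c("a", "b", "c", "d"))
  wk <- fit_weighted_knn(ds2, k = 3)
  expect_identical(predict(wk, c(0, 0)), "celiac")
  expect_identical(predict(wk, c(0.1, 0)), "celiac")  # zero-distance short-circuit

  expect_error(fit_fine_knn(ds, k = 0), "positive integer")
  expect_error(fit_fine_knn(ds, k = 9), "exceed")
})

test_that("linear SVM separates well-separated clusters", {
  ds <- toy_dataset(10, dim = 3, sep = 6, sd = 0.5)
  clf <- fit_linear_svm(ds)
  expect_true(clf$converged)
  expect_length(clf$w, 3)
  expect_identical(unname(predict(clf, ds$x)), ds$labels)

  single <- celiascope:::dataset_subset(ds, 1:10)
  expect_error(fit_linear_svm(single), "both classes")
})

test_that("linear SVM decision values negate under origin mirroring", {
  ds <- toy_dataset(8, dim = 2, sep = 4, sd = 0.8, seed = 5)
  mirrored <- celiascope:::new_dataset(
    -ds$x, ifelse(ds$labels == "celiac", "healthy", "celiac"), ds$ids)
  f1 <- fit_linear_svm(ds)
  f2 <- fit_linear_svm(mirrored)
  q <- withr::with_seed(6, matrix(rnorm(10), 5, 2))
  expect_equal(predict(f2, -q, type = "decision"),
               -predict(f1, q, type = "decision"), tolerance = 1e-8)
})

test_that("evaluate produces consistent confusion counts and metrics", {
  # 1-NN with training points at the test coordinates gives known predictions
  test_x <- matrix(seq_len(20), 10, 2)
  truth <- rep(c("celiac", "healthy"), each = 5)
  pred <- truth
  pred[c(1, 2, 6)] <- c("healthy", "healthy", "celiac")  # fn, fn, fp
  clf <- fit_fine_knn(celiascope:::new_dataset(test_x, pred,
                                               sprintf("t%02d", 1:10)), k = 1)
  rep_ <- evaluate(clf, celiascope:::new_dataset(test_x, truth,
                                                 sprintf("t%02d", 1:10)))
  expect_equal(rep_$tp, 3); expect_equal(rep_$fn, 2)
  expect_equal(rep_$fp, 1); expect_equal(rep_$tn, 4)
  expect_equal(rep_$tp + rep_$fp + rep_$tn + rep_$fn, rep_$n)
  expect_equal(rep_$accuracy, 100 * 7 / 10)
  expect_equal(rep_$precision, 3 / 4)
  expect_equal(rep_$sensibility, 3 / 5)
  expect_equal(rep_$f1, f1_score(3, 1, 2))
  expect_output(print(rep_), "accuracy")
})

test_that("F1 follows the count formula and the harmonic-mean identity", {
  expect_equal(f1_score(48, 3, 0), 48 / 49.5)
  expect_equal(f1_score(0, 0, 0), 0)
  for (seed in 1:10) {
    cnt <- withr::with_seed(seed, sample(1:50, 3))
    tp <- cnt[1]; fp <- cnt[2]; fn <- cnt[3]
    p <- tp / (tp + fp); r <- tp / (tp + fn)
    expect_equal(f1_score(tp, fp, fn), f1_from_pr(p, r), tolerance = 1e-12)
  }
})

test_that("accuracy_from_counts reproduces printed one-decimal accuracies", {
  expect_identical(accuracy_from_counts(51, 3), 94.1)
  expect_identical(accuracy_from_counts(51, 4), 92.2)
  expect_identical(accuracy_from_counts(37, 0), 100)
  expect_error(accuracy_from_counts(0, 0), "positive")
  expect_error(accuracy_from_counts(10, 11), "errors")
})
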