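test_that("euclidean distance matches hand arithmetic", {
  expect_equal(euclidean_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(euclidean_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(euclidean_distance(c(1, 2, 3), c(4, 6, 3)), 5)
  expect_error(euclidean_distance(1:2, 1:3), "equal length")
})

test_that("KNN votes deterministically with the documented tie rules", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("a", "a", "b", "b")
  m1 <- knn_train(x, y, classifier_spec("knn", knn_k = 1L))
  expect_identical(knn_predict(m1, matrix(-1)), "a")
  # two class-a neighbours at distance 1 outvote one nearer class-b neighbour
  x2 <- matrix(c(-1, 1, 0.5, 10), ncol = 1)
  y2 <- c("a", "a", "b", "b")
  m3 <- knn_train(x2, y2, classifier_spec("knn", knn_k = 3L))
  expect_identical(knn_predict(m3, matrix(0)), "a")
  # vote tie breaks toward the class with smaller summed distance
  m2 <- knn_train(x2, y2, classifier_spec("knn", knn_k = 2L))
  expect_identical(knn_predict(m2, matrix(0)), "b")
  expect_error(knn_train(x, rep("a", 4), classifier_spec("knn")),
               "both classes")
  expect_error(knn_train(x, y, classifier_spec("knn", knn_k = 9L)),
               "exceeds")
})

test_that("KNN with k = 1 reproduces its own training labels", {
  set.seed(3)
  x <- matrix(rnorm(60), ncol = 3)
  y <- rep(c("geo_authentic", "non_authentic"), each = 10)
  model <- knn_train(x, y, classifier_spec("knn", knn_k = 1L))
  cc <- confusion(y, knn_predict(model, x))
  expect_equal(compute_metrics(cc)$ACC, 100)
})

test_that("decision trees split pure margins and XOR exactly", {
  x <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c("a", "a", "a", "b", "b", "b")
  m <- dt_train(x, y, classifier_spec("dt"))
  expect_identical(dt_predict(m, x), y)
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  xor_y <- c("a", "b", "b", "a")
  mx <- dt_train(xor_x, xor_y, classifier_spec("dt"))
  expect_identical(dt_predict(mx, xor_x), xor_y)
  expect_error(dt_train(x[0, , drop = FALSE], character(0)), "empty")
})

test_that("the linear SVM recovers the symmetric max-margin separator", {
  x <- matrix(c(-2, -1, 1, 2), ncol = 1)
  y <- c("neg", "neg", "pos", "pos")
  m <- svm_train(x, y, classifier_spec("svm", svm_C = 1e6))
  hp <- svm_hyperplane(m)
  expect_equal(abs(unname(hp$w)), 1, tolerance = 1e-4)
  expect_equal(hp$b, 0, tolerance = 1e-6)
  expect_identical(svm_predict(m, x), y)
  expect_error(svm_train(x, rep("pos", 4)), "both classes")
})

test_that("separable training points satisfy the large-C margin property", {
  set.seed(4)
  x <- rbind(matrix(rnorm(40, -3), ncol = 2), matrix(rnorm(40, 3), ncol = 2))
  y <- rep(c("a", "b"), each = 20)
  m <- svm_train(x, y, classifier_spec("svm", svm_C = 1e6))
  hp <- svm_hyperplane(m)
  pm1 <- ifelse(y == levels(factor(y))[1], 1, -1)  # level 1 gets +1 decision sign
  margins <- pm1 * (drop(x %*% hp$w) + hp$b)
  expect_true(all(margins >= 1 - 1e-6))
  expect_identical(svm_predict(m, x), y)
})

test_that("no linear separator exceeds 3/4 training accuracy on XOR", {
  xor_x <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), ncol = 2)
  xor_y <- c("a", "b", "b", "a")
  m <- svm_train(xor_x, xor_y, classifier_spec("svm", svm_C = 1e6))
  acc <- mean(svm_predict(m, xor_x) == xor_y)
  expect_lte(acc, 0.75)
})

test_that("stratified folds preserve class balance and the 112/28 split", {
  labels <- rep(c("geo_authentic", "non_authentic"), each = 70)
  fa <- stratified_kfold(labels, 5L, seed = 1L)
  sizes <- tabulate(fa$fold, 5L)
  expect_identical(sizes, rep(28L, 5L))
  for (f in 1:5) {
    expect_identical(sum(fa$fold == f & labels == "geo_authentic"), 14L)
    expect_identical(length(labels) - sum(fa$fold == f), 112L)
  }
  expect_identical(sort(unique(fa$fold)), 1:5)
})

test_that("round-robin dealing gives fold sizes 4/3/3 on 10 samples", {
  labels <- rep(c("a", "b"), each = 5)
  fa <- stratified_kfold(labels, 3L, seed = 2L)
  expect_identical(sort(tabulate(fa$fold, 3L), decreasing = TRUE),
                   c(4L, 3L, 3L))
  expect_error(stratified_kfold(labels, 6L), "fewer than k")
})

test_that("per-fold class proportions stay within one sample of balance", {
  for (s in 1:5) {
    set.seed(s)
    labels <- sample(rep(c("a", "b"), times = c(26, 24)))
    fa <- stratified_kfold(labels, 5L, seed = s)
    for (f in 1:5) {
      na <- sum(fa$fold == f & labels == "a")
      nb <- sum(fa$fold == f & labels == "b")
      expect_lte(abs(na - nb), 1L + abs(26 - 24))
    }
  }
})

test_that("confusion counts enumerate TP/FN/TN/FP correctly", {
  cc <- confusion(rep(c("geo_authentic", "non_authentic"), each = 14),
                  rep(c("geo_authentic", "non_authentic"), each = 14))
  expect_identical(unclass(cc)[c("TP", "TN", "FP", "FN")],
                   list(TP = 14L, TN = 14L, FP = 0L, FN = 0L))
  cc2 <- confusion(c("geo_authentic", "geo_authentic", "non_authentic",
                     "non_authentic"),
                   c("geo_authentic", "non_authentic", "geo_authentic",
                     "non_authentic"))
  expect_identical(unclass(cc2)[c("TP", "FN", "FP", "TN")],
                   list(TP = 1L, FN = 1L, FP = 1L, TN = 1L))
  all_pos <- confusion(rep(c("geo_authentic", "non_authentic"), 3),
                       rep("geo_authentic", 6))
  expect_identical(c(all_pos$FN, all_pos$TN), c(0L, 0L))
  expect_error(confusion(c("a", "b", "c"), c("a", "b", "c"),
                         positive = "a"), "two classes")
})

test_that("metrics follow the ACC/SEN/F1 formulas with the 0/0 rule", {
  perfect <- compute_metrics(structure(list(TP = 70L, FN = 0L, TN = 70L,
                                            FP = 0L),
                                       class = "confusion_counts"))
  expect_equal(perfect[c("ACC", "SEN", "F1")], list(ACC = 100, SEN = 100, F1 = 1))
  expect_message(
    degenerate <- compute_metrics(structure(
      list(TP = 0L, FN = 5L, TN = 5L, FP = 0L), class = "confusion_counts")),
    "0/0")
  expect_equal(c(degenerate$SEN, degenerate$F1), c(0, 0))
  near <- compute_metrics(structure(list(TP = 69L, FN = 1L, TN = 67L,
                                         FP = 3L),
                                    class = "confusion_counts"))
  expect_equal(round(near$ACC, 2), 97.14)
  expect_equal(round(near$SEN, 2), 98.57)
})

test_that("accuracy from counts equals mean 0/1 agreement", {
  set.seed(5)
  y_true <- sample(c("geo_authentic", "non_authentic"), 50, replace = TRUE)
  y_pred <- sample(c("geo_authentic", "non_authentic"), 50, replace = TRUE)
  cc <- confusion(y_true, y_pred)
  expect_equal(compute_metrics(cc)$ACC, mean(y_true == y_pred) * 100)
})

test_that("experiment reports pool fold counts consistently", {
  d <- tiny_dataset()
  rep <- run_experiment(d, "exp3_lbp", classifier_spec("knn", knn_k = 3L),
                        k = 4L, seed = 9L, render = tiny_render())
  summed <- Reduce(function(a, b) Map(`+`, a, b),
                   lapply(rep$fold_counts, unclass))
  expect_identical(unclass(rep$pooled_counts), summed)
  total <- with(rep$pooled_counts, TP + FN + TN + FP)
  expect_identical(total, n_samples(d))
  expect_gte(rep$elapsed_seconds, 0)
  row <- summarize_report(rep)
  expect_identical(names(row)[1:5],
                   c("experiment", "classifier", "accuracy", "sensitivity",
                     "f1_score"))
})
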