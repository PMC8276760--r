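test_that("confusion metrics satisfy their defining identities", {
  m <- confusionMetrics(rep(c(1, 0), each = 50), rep(c(1, 0), each = 50))
  expect_equal(m$SN, 1); expect_equal(m$SP, 1)
  expect_equal(m$ACC, 1); expect_equal(m$F_measure, 1)

  # TP=3, FN=1, TN=2, FP=2
  labels <- c(1, 1, 1, 1, 0, 0, 0, 0)
  preds <- c(1, 1, 1, 0, 1, 1, 0, 0)
  m <- confusionMetrics(labels, preds)
  expect_equal(m$SN, 0.75)
  expect_equal(m$SP, 0.5)
  expect_equal(m$ACC, 0.625)
  expect_equal(m$F_measure, 6 / 9)

  m <- confusionMetrics(labels, rep(0, 8))
  expect_equal(m$SN, 0); expect_equal(m$SP, 1)

  expect_error(confusionMetrics(integer(0), integer(0)), "empty")

  set.seed(101)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    labels <- sample(0:1, n, replace = TRUE)
    preds <- sample(0:1, n, replace = TRUE)
    m <- confusionMetrics(labels, preds)
    expect_equal(m$ACC, (m$TP + m$TN) / n)
    expect_equal(m$F_measure, 2 * m$TP / (2 * m$TP + m$FN + m$FP))
    if (m$TP + m$FN > 0) expect_equal(m$SN, m$TP / (m$TP + m$FN))
    if (m$TN + m$FP > 0) expect_equal(m$SP, m$TN / (m$TN + m$FP))
  }
})

test_that("rank-based AUC equals all-pairs counting with half-credit ties", {
  expect_equal(rocAuc(c(0, 0, 1, 1), c(1, 2, 3, 4)), 1)
  expect_equal(rocAuc(c(0, 0, 1, 1), rep(0.5, 4)), 0.5)
  expect_equal(rocAuc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_error(rocAuc(c(1, 1), c(0.1, 0.2)), "both classes")

  set.seed(103)
  for (i in 1:20) {
    n <- sample(4:30, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(rnorm(n), 1)          # coarse scores induce ties
    expect_equal(rocAuc(labels, scores), oracle_auc(labels, scores),
                 tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_equal(rocAuc(labels, exp(2 * scores)), rocAuc(labels, scores))
    expect_equal(rocAuc(labels, rank(scores, ties.method = "average")),
                 rocAuc(labels, scores))
  }
})

test_that("gaussian naive Bayes matches the closed-form Bayes rule", {
  # class 0: values {-1, 1} (mean 0, var 2); class 1: {3, 5} (mean 4, var 2)
  m <- matrix(c(-1, 1, 3, 5), ncol = 1, dimnames = list(NULL, "f"))
  fs <- spotFeatureSet(m, labels = c(0, 0, 1, 1))
  grid <- matrix(c(0, 1.9, 2.1, 6), ncol = 1, dimnames = list(NULL, "f"))
  test <- spotFeatureSet(grid, labels = c(0, 0, 1, 1))
  res <- trainPredict(classifierSpec("gaussian_nb"), fs, test)
  closed <- sapply(grid[, 1], function(x) {
    l0 <- dnorm(x, 0, sqrt(2)) * 0.5
    l1 <- dnorm(x, 4, sqrt(2)) * 0.5
    l1 / (l0 + l1)
  })
  expect_equal(res$scores, unname(closed), tolerance = 1e-12)
  expect_equal(res$predictions, c(0L, 0L, 1L, 1L))

  # agreement with an independent implementation on well-behaved data
  set.seed(105)
  tr <- toy_matrix(n = 40, p = 3, informative = 2, delta = 1.5, seed = 7)
  te <- toy_matrix(n = 20, p = 3, informative = 2, delta = 1.5, seed = 8)
  ours <- trainPredict(classifierSpec("gaussian_nb", var_floor = 0), tr, te)
  df <- as.data.frame(featureValues(tr))
  fit <- e1071::naiveBayes(df, factor(spotLabels(tr), levels = 0:1))
  ref <- predict(fit, as.data.frame(featureValues(te)), type = "raw")[, "1"]
  expect_equal(ours$scores, unname(ref), tolerance = 1e-6)

  # zero-variance feature triggers the floor warning, not a crash
  m <- matrix(c(1, 1, 1, 1, 0, 0, 2, 2), ncol = 2,
              dimnames = list(NULL, c("const", "good")))
  fs <- spotFeatureSet(m, labels = c(0, 0, 1, 1))
  expect_warning(res <- trainPredict(classifierSpec("gaussian_nb"), fs, fs),
                 "floor")
  expect_equal(res$predictions, c(0L, 0L, 1L, 1L))
})

test_that("every classifier solves a linearly separable toy exactly", {
  set.seed(107)
  m <- rbind(matrix(rnorm(20, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(20, mean = 3, sd = 0.3), ncol = 2))
  colnames(m) <- c("f1", "f2")
  fs <- spotFeatureSet(m, labels = rep(0:1, each = 10))
  for (alg in c("svm_linear", "random_forest", "logistic_regression",
                "gaussian_nb", "cart")) {
    res <- suppressWarnings(
      trainPredict(classifierSpec(alg), fs, fs, seed = 3))
    expect_equal(res$predictions, rep(0:1, each = 10), info = alg)
  }
  expect_error(trainPredict(classifierSpec("svm_linear"), fs[, 1:10], fs),
               "single class")
  other <- spotFeatureSet(matrix(rnorm(20), 10, 2,
                                 dimnames = list(NULL, c("g1", "g2"))),
                          labels = rep(0:1, 5))
  expect_error(trainPredict(classifierSpec("svm_linear"), fs, other),
               "identical feature")
})

test_that("cross-validation holds out each sample once, reproducibly", {
  fs <- toy_matrix(n = 10, p = 3, informative = 1, seed = 5)
  cv <- crossValidate(classifierSpec("gaussian_nb"), fs, k = 5, seed = 2)
  expect_equal(sort(unique(cvFolds(cv))), 1:5)
  expect_equal(as.integer(table(cvFolds(cv))), rep(2L, 5))  # folds of size 2
  # stratification: each fold has one sample of each class
  y <- spotLabels(fs)
  for (f in 1:5) expect_equal(sort(y[cvFolds(cv) == f]), c(0L, 1L))

  cv2 <- crossValidate(classifierSpec("gaussian_nb"), fs, k = 5, seed = 2)
  expect_identical(cvFolds(cv), cvFolds(cv2))
  expect_identical(cvMetrics(cv), cvMetrics(cv2))
  cv3 <- crossValidate(classifierSpec("gaussian_nb"), fs, k = 5, seed = 3)
  expect_false(identical(cvFolds(cv), cvFolds(cv3)))

  expect_error(crossValidate(classifierSpec("gaussian_nb"), fs, k = 11), "folds")
})

test_that("null features give chance-level pooled accuracy, planted signal is recovered", {
  # pure-noise features: pooled ACC stays near 0.5 for all five algorithms
  for (alg in c("svm_linear", "random_forest", "logistic_regression",
                "gaussian_nb", "cart")) {
    accs <- vapply(1:3, function(s) {
      fs <- toy_matrix(n = 300, p = 8, informative = 0, seed = 200 + s)
      cv <- suppressWarnings(crossValidate(classifierSpec(alg), fs,
                                           k = 5, seed = s))
      cvMetrics(cv)$ACC
    }, numeric(1))
    expect_gt(mean(accs), 0.42)
    expect_lt(mean(accs), 0.58)
  }

  # strong planted effects: SVM pooled AUC is essentially perfect
  fs <- toy_matrix(n = 200, p = 10, informative = 3, delta = 2.5, seed = 11)
  cvS <- crossValidate(classifierSpec("svm_linear"), fs, k = 5, seed = 4)
  cvR <- crossValidate(classifierSpec("random_forest"), fs, k = 5, seed = 4)
  expect_gte(cvMetrics(cvS)$AUC, 0.9)
  expect_gte(cvMetrics(cvR)$AUC, 0.9)
})

test_that("hold-out splits are stratified, disjoint and seeded", {
  fs <- toy_matrix(n = 100, p = 3, informative = 1, seed = 13)
  sp <- holdoutSplit(fs, trainFraction = 0.7, seed = 5)
  expect_equal(ncol(sp$train), 70L)
  expect_equal(ncol(sp$test), 30L)
  expect_equal(sum(spotLabels(sp$train)), 35L)  # stratified
  ids <- c(colnames(sp$train), colnames(sp$test))
  expect_setequal(ids, colnames(fs))
  expect_length(intersect(colnames(sp$train), colnames(sp$test)), 0L)

  sp2 <- holdoutSplit(fs, trainFraction = 0.7, seed = 5)
  expect_identical(colnames(sp2$train), colnames(sp$train))

  expect_error(holdoutSplit(fs, 1.2), "between 0 and 1")
  tiny <- toy_matrix(n = 4, p = 2, seed = 1)
  expect_error(holdoutSplit(tiny, 0.9), "empty")
})
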