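#' Construct a classifier specification
#'
#' Defaults follow the study design: random forest with `ntree = 130`
#' and `mtry = floor(log2(m))`; linear-kernel SVM with the library
#' defaults otherwise (cost 1, feature scaling on); unregularized
#' logistic regression; Gaussian naive Bayes with a variance floor;
#' CART with Gini splits and complexity parameter 1e-6.
#'
#' @param algorithm One of `"random_forest"`, `"svm_linear"`,
#'   `"logistic_regression"`, `"gaussian_nb"`, `"cart"`.
#' @param ... Overrides of the algorithm's default parameters
#'   (`ntree`, `mtry` for RF; `cost` for SVM; `cp` for CART;
#'   `var_floor` for NB; `maxit` for LR).
#' @return A [ClassifierSpec-class].
#' @examples
#' classifierSpec("svm_linear")
#' @export
classifierSpec <- function(algorithm = c("svm_linear", "random_forest",
                                         "logistic_regression",
                                         "gaussian_nb", "cart"), ...) {
  algorithm <- match.arg(algorithm)
  defaults <- switch(algorithm,
    random_forest = list(ntree = 130L, mtry = NULL),
    svm_linear = list(cost = 1),
    logistic_regression = list(maxit = 100L),
    gaussian_nb = list(var_floor = 1e-9),
    cart = list(cp = 1e-6))
  params <- utils::modifyList(defaults, list(...))
  new("ClassifierSpec", algorithm = algorithm, params = params)
}

setMethod("show", "ClassifierSpec", function(object) {
  p <- object@params[!vapply(object@params, is.null, logical(1))]
  cat(sprintf("ClassifierSpec: %s (%s)\n", object@algorithm,
              paste(names(p), unlist(p), sep = "=", collapse = ", ")))
})

## Gaussian naive Bayes with a per-feature variance floor. Zero-variance
## features (common for rare k-mers after smoothing) would make the
## Gaussian density degenerate; they are floored and a warning is issued.
.nbTrain <- function(x, y, varFloor) {
  classes <- c(0L, 1L)
  prior <- vapply(classes, function(cl) mean(y == cl), numeric(1))
  mu <- lapply(classes, function(cl) colMeans(x[y == cl, , drop = FALSE]))
  s2 <- lapply(classes, function(cl) apply(x[y == cl, , drop = FALSE], 2L,
                                           stats::var))
  nFloored <- sum(vapply(s2, function(v) sum(v < varFloor), numeric(1)))
  if (nFloored > 0)
    warning("naive Bayes: ", nFloored,
            " class-feature variance(s) below the floor; floored",
            call. = FALSE)
  s2 <- lapply(s2, pmax, varFloor)
  list(prior = prior, mu = mu, s2 = s2)
}

.nbPosterior <- function(fit, x) {
  ll <- vapply(1:2, function(ci) {
    mu <- fit$mu[[ci]]; s2 <- fit$s2[[ci]]
    rowSums(sweep(-0.5 * sweep(sweep(x, 2L, mu)^2, 2L, s2, "/"),
                  2L, 0.5 * log(2 * pi * s2), "-")) + log(fit$prior[ci])
  }, numeric(nrow(x)))
  if (nrow(x) == 1L) ll <- matrix(ll, nrow = 1L)
  m <- apply(ll, 1L, max)
  post <- exp(ll - m)
  post[, 2L] / rowSums(post)     # P(hot | x)
}

## data.frame with syntactic column names for formula-based fitters,
## plus the name mapping
.modelFrame <- function(x) {
  safe <- make.names(colnames(x), unique = TRUE)
  df <- as.data.frame(x)
  colnames(df) <- safe
  df
}

#' Train on one set, predict on another
#'
#' Fits the specified classifier on the training samples and returns a
#' hard 0/1 label plus a continuous decision value for every test
#' sample. Decision values are the probability of the hot class for
#' random forest, logistic regression, naive Bayes and CART, and the
#' signed margin (oriented so larger = hot) for the SVM.
#'
#' @param spec A [ClassifierSpec-class].
#' @param train,test [SpotFeatureSet-class] objects sharing identical
#'   feature names; `train` must contain both classes.
#' @param seed Seed for the stochastic fitters (random forest).
#' @return List with `predictions` (integer 0/1) and `scores`
#'   (numeric), one per test sample.
#' @export
trainPredict <- function(spec, train, test, seed = 1L) {
  stopifnot(is(spec, "ClassifierSpec"))
  xtr <- featureValues(train); ytr <- spotLabels(train)
  xte <- featureValues(test)
  if (!identical(colnames(xtr), colnames(xte)))
    stop("train and test must share identical feature names")
  if (length(unique(ytr)) < 2L)
    stop("training set contains a single class")
  p <- spec@params
  scores <- switch(spec@algorithm,
    random_forest = {
      mtry <- if (is.null(p$mtry)) max(1L, floor(log2(ncol(xtr)))) else p$mtry
      fit <- .withSeed(seed, randomForest::randomForest(
        x = xtr, y = factor(ytr, levels = c(0L, 1L)),
        ntree = p$ntree, mtry = mtry))
      stats::predict(fit, xte, type = "prob")[, "1"]
    },
    svm_linear = {
      fit <- suppressWarnings(e1071::svm(
        x = xtr, y = factor(ytr, levels = c(0L, 1L)),
        kernel = "linear", cost = p$cost, scale = TRUE))
      pr <- stats::predict(fit, xte, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      # e1071 orients the margin toward the first class of the colname
      if (startsWith(colnames(dv)[1L], "1")) dv[, 1L] else -dv[, 1L]
    },
    logistic_regression = {
      X <- cbind(`(Intercept)` = 1, xtr)
      fit <- suppressWarnings(stats::glm.fit(
        X, ytr, family = stats::binomial(),
        control = list(maxit = p$maxit)))
      if (!fit$converged)
        warning("logistic regression did not converge (possible ",
                "separation); iteration cap applied", call. = FALSE)
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      as.vector(stats::plogis(cbind(1, xte) %*% beta))
    },
    gaussian_nb = {
      fit <- .nbTrain(xtr, ytr, p$var_floor)
      .nbPosterior(fit, xte)
    },
    cart = {
      df <- .modelFrame(xtr)
      df$.label <- factor(ytr, levels = c(0L, 1L))
      fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                          cp = p$cp)
      nd <- .modelFrame(xte)
      stats::predict(fit, nd, type = "prob")[, "1"]
    })
  scores <- as.numeric(scores)
  threshold <- if (spec@algorithm == "svm_linear") 0 else 0.5
  list(predictions = as.integer(scores > threshold), scores = scores)
}

#' Confusion-matrix metrics
#'
#' Sensitivity `SN = TP/(TP+FN)`, specificity `SP = TN/(TN+FP)`,
#' accuracy `ACC = (TP+TN)/n` and the F-measure
#' `F = 2TP/(2TP+FN+FP)` (harmonic mean of precision and recall), with
#' class 1 (hot) as positive.
#'
#' @param labels True 0/1 labels.
#' @param predictions Predicted 0/1 labels.
#' @return Named list: SN, SP, ACC, F_measure, TP, FP, TN, FN.
#' @export
confusionMetrics <- function(labels, predictions) {
  if (length(labels) == 0L) stop("empty input")
  if (length(labels) != length(predictions)) stop("length mismatch")
  labels <- as.integer(labels); predictions <- as.integer(predictions)
  if (!all(c(labels, predictions) %in% c(0L, 1L)))
    stop("labels and predictions must be binary 0/1")
  TP <- sum(labels == 1L & predictions == 1L)
  FP <- sum(labels == 0L & predictions == 1L)
  TN <- sum(labels == 0L & predictions == 0L)
  FN <- sum(labels == 1L & predictions == 0L)
  list(SN = TP / (TP + FN), SP = TN / (TN + FP),
       ACC = (TP + TN) / (TP + FP + TN + FN),
       F_measure = 2 * TP / (2 * TP + FN + FP),
       TP = TP, FP = FP, TN = TN, FN = FN)
}

#' Rank-based ROC AUC
#'
#' The Mann-Whitney statistic: the probability that a random hot sample
#' scores above a random cold sample, with ties counted one half.
#'
#' @param labels True 0/1 labels (both classes present).
#' @param scores Decision values, larger = more hot-like.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores)) stop("length mismatch")
  nPos <- sum(labels == 1L); nNeg <- sum(labels == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

## stratified fold assignment: within each class, shuffle then deal
## round-robin, so folds differ in size by at most 1 per class
.makeFolds <- function(labels, k, seed) {
  folds <- integer(length(labels))
  .withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      folds[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  })
  folds
}

#' Stratified k-fold cross-validation with pooled decision values
#'
#' Assigns stratified folds, trains on each k-1 fold union, and pools
#' the out-of-fold decision values and predictions so a single ROC
#' curve (and the usual confusion metrics) can be computed over all
#' samples — the "combined decision values" convention.
#'
#' @param spec A [ClassifierSpec-class].
#' @param x A [SpotFeatureSet-class].
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold assignment and stochastic fitters.
#' @return A [CVResult-class].
#' @export
crossValidate <- function(spec, x, k = 5L, seed = 1L) {
  stopifnot(is(x, "SpotFeatureSet"))
  k <- as.integer(k)
  labels <- spotLabels(x)
  n <- length(labels)
  if (k > n) stop("more folds than samples")
  if (k < 2L) stop("need at least 2 folds")
  folds <- .makeFolds(labels, k, seed)
  scores <- numeric(n); preds <- integer(n)
  for (f in seq_len(k)) {
    hold <- folds == f
    res <- trainPredict(spec, x[, !hold], x[, hold],
                        seed = .subSeed(seed, f))
    scores[hold] <- res$scores
    preds[hold] <- res$predictions
  }
  metrics <- confusionMetrics(labels, preds)
  metrics$AUC <- rocAuc(labels, scores)
  new("CVResult", foldAssignments = folds, pooledScores = scores,
      pooledPredictions = preds, labels = labels, metrics = metrics,
      seed = as.integer(seed))
}

#' Metrics of a cross-validation result
#'
#' @param x A [CVResult-class].
#' @return Named list (SN, SP, ACC, F_measure, AUC, confusion counts).
#' @export
cvMetrics <- function(x) { stopifnot(is(x, "CVResult")); x@metrics }

#' @rdname cvMetrics
#' @export
cvScores <- function(x) { stopifnot(is(x, "CVResult")); x@pooledScores }

#' @rdname cvMetrics
#' @export
cvFolds <- function(x) { stopifnot(is(x, "CVResult")); x@foldAssignments }

setMethod("show", "CVResult", function(object) {
  m <- object@metrics
  cat(sprintf(paste0("CVResult (%d folds, seed %d): ACC=%.3f SN=%.3f ",
                     "SP=%.3f F=%.3f AUC=%.3f\n"),
              max(object@foldAssignments), object@seed,
              m$ACC, m$SN, m$SP, m$F_measure, m$AUC))
})

#' Stratified hold-out split
#'
#' Randomly partitions the samples into disjoint train and test sets,
#' stratified by class, with the train size rounded to the nearest
#' integer per class (default 70/30).
#'
#' @param x A [SpotFeatureSet-class].
#' @param trainFraction Fraction assigned to training (0 < f < 1).
#' @param seed Seed for the sampling.
#' @return List with `train` and `test` [SpotFeatureSet-class]s.
#' @export
holdoutSplit <- function(x, trainFraction = 0.7, seed = 1L) {
  stopifnot(is(x, "SpotFeatureSet"))
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie strictly between 0 and 1")
  labels <- spotLabels(x)
  inTrain <- logical(length(labels))
  .withSeed(seed, {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      nTr <- round(length(idx) * trainFraction)
      if (nTr == 0L || nTr == length(idx))
        stop("split leaves a class empty on one side")
      inTrain[sample(idx, nTr)] <- TRUE
    }
  })
  list(train = x[, inTrain], test = x[, !inTrain])
}
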