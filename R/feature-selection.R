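#' ANOVA F-ratio feature ranking
#'
#' Scores every feature by the ratio of between-group to within-group
#' variance across the two classes (the two-group ANOVA F statistic)
#' and sorts in decreasing order. Features with zero within-group
#' variance receive an infinite score and are ranked first; ties are
#' broken by feature name for reproducibility.
#'
#' @param x A [SpotFeatureSet-class] with both classes present and at
#'   least two samples per class.
#' @return `data.frame` with columns `feature` and `score`, decreasing.
#' @export
anovaRank <- function(x) {
  stopifnot(is(x, "SpotFeatureSet"))
  m <- featureValues(x); y <- spotLabels(x)
  if (length(unique(y)) < 2L) stop("both classes required")
  if (min(table(y)) < 2L) stop("need >= 2 samples per class")
  n <- nrow(m); g <- 2L
  grand <- colMeans(m)
  idx0 <- y == 0L; idx1 <- y == 1L
  m0 <- colMeans(m[idx0, , drop = FALSE])
  m1 <- colMeans(m[idx1, , drop = FALSE])
  ssb <- sum(idx0) * (m0 - grand)^2 + sum(idx1) * (m1 - grand)^2
  ssw <- colSums(sweep(m[idx0, , drop = FALSE], 2L, m0)^2) +
    colSums(sweep(m[idx1, , drop = FALSE], 2L, m1)^2)
  score <- (ssb / (g - 1)) / (ssw / (n - g))
  # constant features carry no information: ratio 0, ranked last
  score[ssb == 0 & ssw == 0] <- 0
  zeroW <- ssw == 0 & ssb > 0
  if (any(zeroW)) {
    message(sum(zeroW), " feature(s) with zero within-group variance; ",
            "ranked first")
    score[zeroW] <- Inf
  }
  ord <- order(-score, colnames(m))
  data.frame(feature = colnames(m)[ord], score = score[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Gini-importance feature ranking
#'
#' Mean decrease in Gini impurity from a random forest (130 trees,
#' `floor(log2(m))` candidate features per split) trained on the whole
#' matrix, sorted decreasing; ties broken by feature name.
#'
#' @param x A [SpotFeatureSet-class].
#' @param seed Seed for the forest.
#' @return `data.frame` with columns `feature` and `score`, decreasing.
#' @export
giniRank <- function(x, seed = 1L) {
  stopifnot(is(x, "SpotFeatureSet"))
  m <- featureValues(x); y <- spotLabels(x)
  if (length(unique(y)) < 2L) stop("both classes required")
  fit <- .withSeed(seed, randomForest::randomForest(
    x = m, y = factor(y, levels = c(0L, 1L)), ntree = 130L,
    mtry = max(1L, floor(log2(ncol(m)))), importance = FALSE))
  imp <- randomForest::importance(fit, type = 2L)[, 1L]
  ord <- order(-imp, names(imp))
  data.frame(feature = names(imp)[ord], score = unname(imp[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

## pooled CV accuracy of a feature subset under a frozen fold assignment
.cvAccuracyFixedFolds <- function(spec, x, featNames, folds, seed) {
  sub <- x[featNames, ]
  labels <- spotLabels(sub)
  preds <- integer(length(labels))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    res <- trainPredict(spec, sub[, !hold], sub[, hold],
                        seed = .subSeed(seed, f))
    preds[hold] <- res$predictions
  }
  mean(preds == labels)
}

#' Incremental feature selection (IFS)
#'
#' Walks the ranking from most to least important, tentatively adding
#' each feature to the retained set and recomputing the k-fold
#' cross-validated accuracy under a fold assignment frozen once from
#' the seed (so every step sees the same folds). A feature is kept only
#' if accuracy strictly increases over the current retained accuracy;
#' the top-ranked feature seeds the set. The trace records every
#' examined feature with the tentative accuracy observed.
#'
#' @param x A [SpotFeatureSet-class].
#' @param ranking A ranking `data.frame` from [anovaRank()] or
#'   [giniRank()] (or any data.frame with a `feature` column covering
#'   the matrix features to consider).
#' @param spec A [ClassifierSpec-class] (the study uses the linear
#'   SVM).
#' @param k Number of CV folds.
#' @param seed Seed freezing the folds.
#' @return A [SelectionTrace-class].
#' @export
incrementalFeatureSelection <- function(x, ranking,
                                        spec = classifierSpec("svm_linear"),
                                        k = 5L, seed = 1L) {
  stopifnot(is(x, "SpotFeatureSet"))
  feats <- ranking$feature
  if (length(feats) == 0L) stop("empty ranking")
  if (!all(feats %in% rownames(x)))
    stop("ranking refers to features absent from the matrix")
  folds <- .makeFolds(spotLabels(x), k, seed)
  kept <- character(0)
  best <- -Inf
  steps <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    cand <- c(kept, feats[i])
    acc <- .cvAccuracyFixedFolds(spec, x, cand, folds, seed)
    if (acc > best) {
      kept <- cand
      best <- acc
      action <- "kept"
    } else {
      action <- "removed"
    }
    steps[[i]] <- data.frame(feature = feats[i], action = action,
                             cv_accuracy_after = acc,
                             stringsAsFactors = FALSE)
  }
  new("SelectionTrace", steps = do.call(rbind, steps), finalSet = kept,
      classifier = spec, seed = as.integer(seed))
}

#' Recursive correlated-feature pruning
#'
#' Repeatedly finds the most correlated remaining pair (by absolute
#' Pearson correlation) and removes the member with the lower
#' univariate cross-validated accuracy (same classifier, same frozen
#' folds), recording the full-set CV accuracy after each removal, until
#' a single feature remains. The caller inspects the trace for the
#' "no new accuracy peak" pattern that justifies keeping the original
#' set. A constant feature has undefined correlations and is treated as
#' uncorrelated (r = 0) with everything.
#'
#' @param x A [SpotFeatureSet-class].
#' @param featureSet Character vector of >= 2 feature names to prune.
#' @param spec A [ClassifierSpec-class].
#' @param k Number of CV folds.
#' @param seed Seed freezing the folds.
#' @return A [SelectionTrace-class]; `finalSet` is the single survivor,
#'   `steps` has one `"removed"` row per excluded feature.
#' @export
correlationPrune <- function(x, featureSet,
                             spec = classifierSpec("svm_linear"),
                             k = 5L, seed = 1L) {
  stopifnot(is(x, "SpotFeatureSet"))
  if (length(featureSet) < 2L) stop("featureSet must contain >= 2 features")
  if (!all(featureSet %in% rownames(x)))
    stop("featureSet refers to features absent from the matrix")
  folds <- .makeFolds(spotLabels(x), k, seed)
  uniAcc <- vapply(featureSet, function(f)
    .cvAccuracyFixedFolds(spec, x, f, folds, seed), numeric(1))
  m <- featureValues(x)[, featureSet, drop = FALSE]
  cm <- suppressWarnings(abs(stats::cor(m)))
  if (anyNA(cm)) {
    message("constant feature(s) present; correlations treated as 0")
    cm[is.na(cm)] <- 0
  }
  diag(cm) <- -Inf
  current <- featureSet
  steps <- list()
  while (length(current) > 1L) {
    sub <- cm[current, current, drop = FALSE]
    top <- which(sub == max(sub), arr.ind = TRUE)[1L, ]
    pair <- c(current[top[["row"]]], current[top[["col"]]])
    pair <- pair[order(uniAcc[pair], pair)]      # worse univariate first
    drop <- pair[1L]
    current <- setdiff(current, drop)
    acc <- .cvAccuracyFixedFolds(spec, x, current, folds, seed)
    steps[[length(steps) + 1L]] <-
      data.frame(feature = drop, action = "removed",
                 cv_accuracy_after = acc, stringsAsFactors = FALSE)
  }
  new("SelectionTrace", steps = do.call(rbind, steps),
      finalSet = current, classifier = spec, seed = as.integer(seed))
}

#' Steps and final set of a selection trace
#'
#' @param x A [SelectionTrace-class].
#' @return `selectionSteps()`: the per-step `data.frame`;
#'   `selectedFeatures()`: the retained feature names.
#' @export
selectionSteps <- function(x) { stopifnot(is(x, "SelectionTrace")); x@steps }

#' @rdname selectionSteps
#' @export
selectedFeatures <- function(x) { stopifnot(is(x, "SelectionTrace")); x@finalSet }

setMethod("show", "SelectionTrace", function(object) {
  st <- object@steps
  cat(sprintf(paste0("SelectionTrace: %d steps (%d kept, %d removed), ",
                     "final set of %d feature(s)\n"),
              nrow(st), sum(st$action == "kept"),
              sum(st$action == "removed"), length(object@finalSet)))
})
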