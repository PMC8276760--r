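#' @import methods
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats var rnorm runif rgamma sd cor predict glm.fit
#'   binomial plogis quantile
#' @importFrom utils read.delim write.table head
NULL

#' Per-base signal over a set of chromosomes
#'
#' A `SignalTrack` holds one dense numeric vector per chromosome, one value
#' per base. It is the carrier for Spo11-oligo signal and for epigenetic
#' marks (histone modifications, MNase-seq, Top2 binding). Positions not
#' covered by the source file are 0 by the package-wide policy, which is
#' what makes the coldspot rule ("no signal, value exactly zero")
#' well-defined.
#'
#' @slot values Named list, one finite numeric vector per chromosome.
#' @export
setClass("SignalTrack", representation(values = "list"))

setValidity("SignalTrack", function(object) {
  v <- object@values
  if (length(v) == 0L) return("track has no chromosomes")
  if (is.null(names(v)) || anyDuplicated(names(v)) || any(names(v) == ""))
    return("chromosome names must be unique and non-empty")
  for (nm in names(v)) {
    if (!is.numeric(v[[nm]])) return(sprintf("values for %s are not numeric", nm))
    if (!all(is.finite(v[[nm]]))) return(sprintf("non-finite values on %s", nm))
  }
  TRUE
})

#' Lookup table mapping k-mers to structural or physical properties
#'
#' Carrier for dinucleotide thermodynamics, base-pair-step equilibrium
#' parameters and force constants, rigidity, and pentamer DNA-shape
#' tables. Each of the 4^k k-mers must be present, with one finite value
#' per property.
#'
#' @slot name Short table identifier used as a feature-name prefix.
#' @slot k Word length (2 for dinucleotide properties, 5 for pentamer shape).
#' @slot properties Character vector of property names.
#' @slot values Numeric matrix, 4^k rows (k-mers, lexicographic) by
#'   properties.
#' @slot resolution `"per-step"` or `"per-base"`; metadata describing
#'   whether a property is defined on the base-pair step or the base pair
#'   itself. It does not change the lookup arithmetic.
#' @export
setClass("ParameterTable", representation(
  name = "character", k = "integer", properties = "character",
  values = "matrix", resolution = "character"))

setValidity("ParameterTable", function(object) {
  if (length(object@k) != 1L || object@k < 1L) return("k must be a single positive integer")
  n <- 4L^object@k
  if (nrow(object@values) != n)
    return(sprintf("table must have %d rows (one per %d-mer), has %d",
                   n, object@k, nrow(object@values)))
  if (!identical(rownames(object@values), allKmers(object@k)))
    return("row names must be the complete lexicographic k-mer set")
  if (anyDuplicated(object@properties)) return("duplicate property names")
  if (ncol(object@values) != length(object@properties))
    return("one column per property required")
  if (!all(is.finite(object@values))) return("all parameter values must be finite")
  if (!object@resolution %in% c("per-step", "per-base"))
    return("resolution must be 'per-step' or 'per-base'")
  TRUE
})

#' Positional profile of a statistic along a sequence
#'
#' One value per sliding-window placement (or per base-pair step), with
#' each value assigned to the bp offset of its window center relative to
#' the sequence center. Missing values (`NA`, e.g. steps containing N)
#' are allowed and propagate through smoothing.
#'
#' @slot values Numeric vector (may contain `NA`).
#' @slot positions Center offsets in bp relative to the sequence center;
#'   strictly increasing.
#' @slot windowSize Window (or word) width in bp.
#' @slot step Step size in bp between placements.
#' @export
setClass("Profile", representation(
  values = "numeric", positions = "numeric",
  windowSize = "numeric", step = "numeric"))

setValidity("Profile", function(object) {
  if (length(object@values) != length(object@positions))
    return("values and positions differ in length")
  if (any(is.infinite(object@values))) return("values must be finite or NA")
  if (length(object@positions) > 1L && any(diff(object@positions) <= 0))
    return("positions must be strictly increasing")
  TRUE
})

#' Labeled fixed-width benchmark windows
#'
#' The benchmark object: hot and cold spots recentered into fixed-width
#' windows, each fully inside its chromosome, each carrying a
#' `label` metadata column (`"hot"` or `"cold"`).
#'
#' @slot windows `GRanges` with an mcols `label` column.
#' @slot width Common window width in bp.
#' @slot source Free-text provenance string.
#' @export
setClass("SpotSet", representation(
  windows = "GRanges", width = "integer", source = "character"))

setValidity("SpotSet", function(object) {
  w <- object@windows
  if (length(w) > 0L) {
    if (is.null(w$label) || !all(w$label %in% c("hot", "cold")))
      return("every window needs a label of 'hot' or 'cold'")
    if (!all(GenomicRanges::width(w) == object@width))
      return("all windows must share the declared width")
  }
  TRUE
})

#' Samples-by-features matrix with binary hot/cold labels
#'
#' The interchange object between feature extraction, classification and
#' feature selection: a [SummarizedExperiment::SummarizedExperiment]
#' whose single assay holds features in rows and spots (samples) in
#' columns, with the binary label (1 = hot, 0 = cold) in `colData`.
#'
#' @export
setClass("SpotFeatureSet", contains = "SummarizedExperiment")

setValidity("SpotFeatureSet", function(object) {
  if (length(SummarizedExperiment::assays(object)) != 1L)
    return("exactly one assay expected")
  a <- SummarizedExperiment::assay(object)
  if (nrow(a) > 0L && (is.null(rownames(a)) || anyDuplicated(rownames(a))))
    return("feature names must be present and unique")
  if (length(a) > 0L && !all(is.finite(a)))
    return("all feature values must be finite")
  lab <- SummarizedExperiment::colData(object)$label
  if (ncol(a) > 0L && (is.null(lab) || anyNA(lab) || !all(lab %in% c(0L, 1L))))
    return("every sample needs a label in {0, 1}")
  TRUE
})

#' Classifier configuration
#'
#' Names one of the five supported algorithms together with its settings.
#' Defaults follow the study design: random forest with 130 trees and
#' `floor(log2(m))` candidate features per split, linear-kernel SVM,
#' unregularized logistic regression, Gaussian naive Bayes with a
#' variance floor, and CART with complexity parameter 1e-6.
#'
#' @slot algorithm One of `"random_forest"`, `"svm_linear"`,
#'   `"logistic_regression"`, `"gaussian_nb"`, `"cart"`.
#' @slot params Named list of algorithm-specific settings.
#' @export
setClass("ClassifierSpec", representation(algorithm = "character", params = "list"))

setValidity("ClassifierSpec", function(object) {
  algs <- c("random_forest", "svm_linear", "logistic_regression",
            "gaussian_nb", "cart")
  if (length(object@algorithm) != 1L || !object@algorithm %in% algs)
    return(paste("algorithm must be one of:", paste(algs, collapse = ", ")))
  TRUE
})

#' Cross-validation result with pooled decision values
#'
#' Records the fold assignment, the out-of-fold decision value and hard
#' prediction for every sample, and the evaluation metrics computed on
#' the pooled set (including the AUC of the pooled decision values).
#'
#' @slot foldAssignments Integer fold index (1..k) per sample.
#' @slot pooledScores Out-of-fold decision value per sample.
#' @slot pooledPredictions Out-of-fold hard label (0/1) per sample.
#' @slot labels True labels (0/1).
#' @slot metrics Named list: SN, SP, ACC, F_measure, AUC and the
#'   confusion counts.
#' @slot seed Seed used for the fold assignment.
#' @export
setClass("CVResult", representation(
  foldAssignments = "integer", pooledScores = "numeric",
  pooledPredictions = "integer", labels = "integer",
  metrics = "list", seed = "integer"))

#' Ordered record of feature-selection steps
#'
#' Output of incremental feature selection and of recursive correlated-
#' feature pruning: one row per examined feature with the action taken
#' and the cross-validated accuracy observed at that step, plus the
#' final retained set.
#'
#' @slot steps `data.frame` with columns `feature`, `action`
#'   (`"kept"`/`"removed"`), `cv_accuracy_after`.
#' @slot finalSet Character vector of retained feature names.
#' @slot classifier The [ClassifierSpec-class] used throughout.
#' @slot seed Seed fixing the fold assignment for every step.
#' @export
setClass("SelectionTrace", representation(
  steps = "data.frame", finalSet = "character",
  classifier = "ClassifierSpec", seed = "integer"))

setValidity("SelectionTrace", function(object) {
  st <- object@steps
  need <- c("feature", "action", "cv_accuracy_after")
  if (!all(need %in% names(st))) return("steps must have feature/action/cv_accuracy_after")
  if (!all(st$action %in% c("kept", "removed"))) return("action must be kept/removed")
  if (any(st$cv_accuracy_after < 0 | st$cv_accuracy_after > 1))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' Configuration of the synthetic benchmark generator
#'
#' Defines a small multi-chromosome genome, the number of planted hot and
#' cold spots, and the effect sizes that distinguish hot windows from the
#' background: an anti-symmetric G/C bias flipping sign at the spot
#' center (mimicking the reversed GC-skew of real hotspots), excess A/T
#' probability in the central 100 bp, an alternating-dinucleotide bias at
#' the center (creating a mutual-information peak), and per-mark
#' fold-changes of epigenetic signal over hot windows (MNase modeled as a
#' dip, fold < 1).
#'
#' @slot nChromosomes,chromLength Genome geometry.
#' @slot nHot,nCold Numbers of planted spots per class.
#' @slot window Spot window width in bp.
#' @slot backgroundBaseProbs Length-4 probability vector (A, C, G, T).
#' @slot skewAmplitude,centerAtEnrichment,dinucleotideBias Compositional
#'   effect sizes in [0, 1].
#' @slot markEnrichment Named numeric vector of per-mark fold-changes.
#' @slot markNoiseSd Gaussian noise SD of the mark tracks.
#' @slot seed Root seed; all streams are derived from it.
#' @export
setClass("SynthConfig", representation(
  nChromosomes = "integer", chromLength = "integer",
  nHot = "integer", nCold = "integer", window = "integer",
  backgroundBaseProbs = "numeric",
  skewAmplitude = "numeric", centerAtEnrichment = "numeric",
  dinucleotideBias = "numeric",
  markEnrichment = "numeric", markNoiseSd = "numeric",
  seed = "integer"))

setValidity("SynthConfig", function(object) {
  if (object@nHot < 1L || object@nCold < 1L) return("need at least one spot per class")
  p <- object@backgroundBaseProbs
  if (length(p) != 4L || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    return("backgroundBaseProbs must be a length-4 probability vector")
  for (s in c("skewAmplitude", "centerAtEnrichment", "dinucleotideBias")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) return(sprintf("%s must lie in [0, 1]", s))
  }
  if (any(object@markEnrichment < 0)) return("mark fold-changes must be >= 0")
  if (object@markNoiseSd < 0) return("markNoiseSd must be >= 0")
  TRUE
})
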