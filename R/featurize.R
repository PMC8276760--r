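#' Extract the full feature matrix for a benchmark
#'
#' Runs the three feature families over every window of a
#' [SpotSet-class]:
#'
#' * compositional: mean and variance of sliding GC-content, GC-skew
#'   and mutual-information profiles over the central span, plus the
#'   Laplace-smoothed k-mer composition of the central span
#'   (`6 + 4^k` features);
#' * structural: mean and variance of the smoothed lookup profile of
#'   every property of every parameter table (two features per
#'   property; 84 with the full default inventory);
#' * epigenomic: the mean signal of each track over the central span
#'   (one feature per track).
#'
#' With the full default configuration (all tables, six tracks, k = 4)
#' this emits 96 non-k-mer features plus 256 k-mer features per spot.
#'
#' @param spotSet A [SpotSet-class].
#' @param genome The `DNAStringSet` the windows were built against.
#' @param tables List of [ParameterTable-class] objects; `list()`
#'   disables the structural family.
#' @param tracks Named list of [SignalTrack-class] objects; `NULL`
#'   disables the epigenomic family.
#' @param k k-mer size (1..6), or `NULL` to skip k-mer features.
#' @param central Central span in bp for block summaries, k-mer region
#'   and signal averaging.
#' @param composition Include the GC/skew/MI block?
#' @param windows Sliding-window widths for the compositional profiles.
#' @param smooth Moving-average width for structural profiles.
#' @return A [SpotFeatureSet-class] (features x spots).
#' @export
extractFeatures <- function(spotSet, genome,
                            tables = defaultParameterTables(),
                            tracks = NULL, k = 4L, central = 300L,
                            composition = TRUE,
                            windows = c(gc_content = 100L,
                                        gc_skew = 100L,
                                        mutual_information = 200L),
                            smooth = 10L) {
  stopifnot(is(spotSet, "SpotSet"))
  w <- spotWindows(spotSet)
  if (length(w) == 0L) stop("empty SpotSet")
  seqs <- as.character(extractSequence(genome, w))
  rows <- vector("list", length(w))
  for (i in seq_along(w)) {
    feats <- numeric(0)
    if (composition || !is.null(k)) {
      sf <- sequenceFeatureBlock(seqs[[i]],
                                 k = if (is.null(k)) 1L else k,
                                 central = central, windows = windows)
      if (!composition)
        sf <- sf[grepl("^kmer", names(sf))]
      if (is.null(k))
        sf <- sf[!grepl("^kmer", names(sf))]
      feats <- c(feats, sf)
    }
    if (length(tables) > 0L)
      feats <- c(feats, structuralBlock(seqs[[i]], tables = tables,
                                        span = central, smooth = smooth))
    if (!is.null(tracks) && length(tracks) > 0L)
      feats <- c(feats, signalMeanBlock(tracks, w[i], span = central))
    rows[[i]] <- feats
  }
  nm <- names(rows[[1L]])
  if (anyDuplicated(nm)) stop("duplicate feature names")
  m <- do.call(rbind, rows)
  rownames(m) <- paste0("spot", seq_len(nrow(m)))
  spotFeatureSet(m, labels = as.integer(w$label == "hot"))
}
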