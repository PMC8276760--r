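#' Per-step structural profile of a sequence
#'
#' Maps a k-mer parameter table along the sequence: value i is the
#' table entry for the word starting at position i, assigned to the
#' word's center offset. Words containing N yield a missing value
#' (`NA`), which downstream smoothing propagates and block summaries
#' exclude.
#'
#' @param seq A DNA string of length >= k.
#' @param table A [ParameterTable-class].
#' @param property Property name; defaults to the table's only
#'   property.
#' @return A [Profile-class] with `L - k + 1` values.
#' @export
stepProfile <- function(seq, table, property = NULL) {
  stopifnot(is(table, "ParameterTable"))
  if (is.null(property)) {
    if (length(table@properties) != 1L)
      stop("table has several properties; name one")
    property <- table@properties
  }
  if (!property %in% table@properties)
    stop("no property '", property, "' in table '", table@name, "'")
  codes <- .baseCodes(seq)
  k <- table@k
  if (length(codes) < k) stop("sequence shorter than table k-mer length")
  idx <- .kmerIndex(codes, k)
  vals <- table@values[, property][idx]
  L <- length(codes)
  pos <- (seq_along(idx) - 1) + (k - 1) / 2 - (L - 1) / 2
  .newProfile(vals, pos, windowSize = k)
}

#' Moving-average smoothing of a profile
#'
#' Centered moving average in valid mode: only positions where the full
#' width is available are returned, so the output is `width - 1` values
#' shorter. Missing values propagate (any window touching an `NA` is
#' `NA`).
#'
#' @param profile A [Profile-class].
#' @param width Averaging width in profile steps (default 10, the
#'   standard smoothing for structural profiles).
#' @return A [Profile-class].
#' @export
smoothProfile <- function(profile, width = 10L) {
  stopifnot(is(profile, "Profile"))
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("width must be a positive integer")
  if (width > length(profile@values))
    stop("width exceeds profile length")
  vals <- .movingAverage(profile@values, width)
  pos <- .movingAverage(profile@positions, width)
  .newProfile(vals, pos, windowSize = profile@windowSize + width - 1,
              step = profile@step)
}

#' Structural feature block of a spot sequence
#'
#' For every property of every table: look up the per-step profile,
#' smooth it with a `smooth`-bp moving average, and summarize the
#' central `span` bp as mean and sample variance. Emits exactly two
#' named features per property (`<table>.<property>.mean` and `.var`);
#' with the full default table set that is 84 structural features.
#' N-containing steps are missing values, excluded from the summaries.
#'
#' @param seq A DNA string; must cover the span plus smoothing margins.
#' @param tables List of [ParameterTable-class] objects (default: the
#'   full inventory from [defaultParameterTables()]).
#' @param span Central span in bp (default 300).
#' @param smooth Moving-average width (default 10).
#' @return Named numeric vector, two values per property.
#' @export
structuralBlock <- function(seq, tables = defaultParameterTables(),
                            span = 300L, smooth = 10L) {
  if (is(tables, "ParameterTable")) tables <- list(tables)
  codes <- .baseCodes(seq)
  L <- length(codes)
  # per-k lookup index and smoothed central-span selector, computed once
  ks <- unique(vapply(tables, function(t) t@k, integer(1L)))
  cache <- lapply(ks, function(k) {
    idx <- .kmerIndex(codes, k)
    pos <- (seq_along(idx) - 1) + (k - 1) / 2 - (L - 1) / 2
    smPos <- .movingAverage(pos, smooth)
    list(idx = idx, sel = abs(smPos) <= span / 2 + 1e-9)
  })
  names(cache) <- as.character(ks)
  out <- numeric(2L * sum(vapply(tables, function(t)
    length(t@properties), integer(1L))))
  nm <- character(length(out))
  j <- 0L
  for (tab in tables) {
    stopifnot(is(tab, "ParameterTable"))
    cc <- cache[[as.character(tab@k)]]
    if (smooth > length(cc$idx)) stop("smoothing width exceeds profile length")
    for (prop in tab@properties) {
      vals <- .movingAverage(tab@values[, prop][cc$idx], smooth)[cc$sel]
      vals <- vals[!is.na(vals)]
      if (length(vals) < 2L)
        stop("fewer than 2 profile values inside the central span")
      nm[j + 1:2] <- paste0(tab@name, ".", prop, c(".mean", ".var"))
      out[j + 1:2] <- c(mean(vals), stats::var(vals))
      j <- j + 2L
    }
  }
  stats::setNames(out, nm)
}
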