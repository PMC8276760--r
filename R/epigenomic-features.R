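#' Mean epigenetic signal features for one spot
#'
#' One feature per track: the arithmetic mean of the per-base signal
#' over a `span`-bp window centered on the spot center. No variance is
#' emitted for signal features. With the six study tracks this
#' contributes 6 of the 96 non-k-mer features; the "clear" set (the two
#' redundant tracks removed) contributes 4.
#'
#' @param tracks Named list of [SignalTrack-class] objects; names become
#'   feature names.
#' @param spot A single-interval `GRanges`.
#' @param span Averaging span in bp, centered on the spot center
#'   (default 300; 150 is the alternative setting).
#' @return Named numeric vector, one value per track.
#' @export
signalMeanBlock <- function(tracks, spot, span = 300L) {
  if (length(spot) != 1L) stop("signalMeanBlock() takes a single spot")
  if (length(tracks) == 0L) return(numeric(0))
  if (is.null(names(tracks)) || anyDuplicated(names(tracks)))
    stop("tracks must be uniquely named")
  win <- centerWindow(spot, span)
  chrom <- as.character(GenomeInfoDb::seqnames(win))
  s <- BiocGenerics::start(win); e <- BiocGenerics::end(win)
  vapply(names(tracks), function(nm) {
    tr <- tracks[[nm]]
    stopifnot(is(tr, "SignalTrack"))
    if (!chrom %in% names(tr@values))
      stop("track '", nm, "' has no coverage for chromosome ", chrom)
    v <- tr@values[[chrom]]
    if (s < 1L || e > length(v))
      stop("span window out of chromosome bounds for track '", nm, "'")
    mean(v[s:e])
  }, numeric(1L))
}
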