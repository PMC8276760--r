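#' Call recombination coldspots from a Spo11-oligo track
#'
#' Coldspots are the maximal runs of consecutive positions with signal
#' exactly 0 whose length is at least `minLen` bp (default 500). A
#' 1,200-bp zero run yields one 1,200-bp coldspot, never tiled pieces.
#' Runs are reported per chromosome, sorted and pairwise disjoint.
#'
#' @param track A [SignalTrack-class], dense over the genome.
#' @param minLen Minimum run length in bp.
#' @return `GRanges` of coldspots with `label = "cold"`.
#' @export
callColdspots <- function(track, minLen = 500L) {
  stopifnot(is(track, "SignalTrack"))
  minLen <- as.integer(minLen)
  if (length(minLen) != 1L || is.na(minLen) || minLen < 1L)
    stop("minLen must be a positive integer")
  pieces <- lapply(names(track@values), function(chrom) {
    r <- S4Vectors::Rle(track@values[[chrom]] == 0)
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) & S4Vectors::runLength(r) >= minLen
    if (!any(keep)) return(GenomicRanges::GRanges())
    GenomicRanges::GRanges(chrom,
                           IRanges::IRanges(starts[keep], ends[keep]))
  })
  out <- suppressWarnings(do.call(c, pieces))
  if (length(out) > 0L) out$label <- "cold"
  out
}

#' Center a fixed-width window on a spot
#'
#' The window is centered at the floor midpoint of the spot and spans
#' exactly `width` bp. In 0-based half-open terms the center is
#' `c = floor((start + end) / 2)` and the window is
#' `[c - floor(width/2), c - floor(width/2) + width)`. No bounds check
#' is applied here; out-of-bounds windows are handled downstream.
#'
#' @param spots `GRanges` of spots.
#' @param width Window width in bp.
#' @return `GRanges` of windows, metadata columns preserved.
#' @export
centerWindow <- function(spots, width) {
  width <- as.integer(width)
  if (length(width) != 1L || is.na(width) || width < 1L)
    stop("width must be a positive integer")
  start0 <- BiocGenerics::start(spots) - 1L
  end0 <- BiocGenerics::end(spots)
  c0 <- (start0 + end0) %/% 2L
  newStart0 <- c0 - width %/% 2L
  out <- spots
  IRanges::ranges(out) <- IRanges::IRanges(start = newStart0 + 1L,
                                           width = width)
  out
}

#' Assemble the labeled hot/cold benchmark
#'
#' Centers a fixed-width window on every hot and cold spot, drops any
#' window that would run past a chromosome boundary (reported via a
#' message), and attaches labels. Windows are never clipped, so every
#' sample has identical width as the fixed-window feature arithmetic
#' assumes; overlapping hot and cold windows are both kept.
#'
#' @param hot,cold `GRanges` of hot and cold spots.
#' @param genome A `DNAStringSet` (bounds reference).
#' @param width Window width in bp (default 1000, the retrieval width
#'   used throughout).
#' @param source Provenance string recorded in the result.
#' @return A [SpotSet-class].
#' @export
buildBenchmark <- function(hot, cold, genome, width = 1000L,
                           source = "buildBenchmark") {
  width <- as.integer(width)
  lens <- .genomeLengths(genome)
  prep <- function(gr, lab) {
    chroms <- as.character(GenomeInfoDb::seqnames(gr))
    if (!all(chroms %in% names(lens)))
      stop("spot on a chromosome absent from the genome")
    w <- centerWindow(gr, width)
    ok <- BiocGenerics::start(w) >= 1L &
      BiocGenerics::end(w) <= lens[chroms]
    if (any(!ok))
      message(sum(!ok), " ", lab, " spot(s) dropped: window exceeds ",
              "chromosome bounds")
    w <- w[ok]
    S4Vectors::mcols(w) <- S4Vectors::DataFrame(label = rep(lab, length(w)))
    w
  }
  h <- prep(hot, "hot")
  c_ <- prep(cold, "cold")
  if (length(h) == 0L || length(c_) == 0L)
    stop("benchmark needs at least one window of each class after ",
         "bounds filtering")
  new("SpotSet", windows = suppressWarnings(c(h, c_)), width = width,
      source = source)
}

#' Windows of a SpotSet
#'
#' @param x A [SpotSet-class].
#' @return `GRanges` with the `label` metadata column.
#' @export
spotWindows <- function(x) {
  stopifnot(is(x, "SpotSet"))
  x@windows
}

setMethod("show", "SpotSet", function(object) {
  lab <- object@windows$label
  cat(sprintf("SpotSet: %d windows of %d bp (%d hot, %d cold) [%s]\n",
              length(object@windows), object@width,
              sum(lab == "hot"), sum(lab == "cold"), object@source))
})
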