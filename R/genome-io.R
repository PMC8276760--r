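#' Read a reference genome from FASTA
#'
#' Reads a multi-record FASTA into a [Biostrings::DNAStringSet], keeping
#' the first whitespace-delimited token of each header as the chromosome
#' name. Sequences are uppercased; only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one entry per chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrI", "acgtacgt"), fa)
#' genome <- readGenome(fa)
#' width(genome)
#' @export
readGenome <- function(path) {
  .assertSingleString(path, "path")
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e) stop("malformed FASTA: ",
                                              conditionMessage(e)))
  if (length(genome) == 0L) stop("empty FASTA file: ", path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in FASTA")
  genome <- Biostrings::DNAStringSet(toupper(genome))
  freq <- Biostrings::alphabetFrequency(genome)
  extra <- colSums(freq[, !colnames(freq) %in% c("A", "C", "G", "T", "N"),
                        drop = FALSE])
  if (sum(extra) > 0)
    stop("genome contains letters outside {A,C,G,T,N}")
  genome
}

## named chromosome lengths of a DNAStringSet genome
.genomeLengths <- function(genome) {
  stats::setNames(BiocGenerics::width(genome), names(genome))
}

#' Read hot/cold spot intervals from BED
#'
#' Reads a BED3+ file into a `GRanges` (1-based closed internally, the
#' usual Bioconductor convention; the 0-based half-open BED coordinates
#' are converted at this boundary). A 4th column, when present, is kept
#' as the `label` metadata column.
#'
#' @param path Path to a BED file.
#' @return `GRanges` in file order, with an optional `label` column.
#' @export
readSpots <- function(path) {
  .assertSingleString(path, "path")
  if (!file.exists(path)) stop("BED file not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) stop("malformed BED: ",
                                          conditionMessage(e)))
  if (any(BiocGenerics::start(gr) < 1L))
    stop("negative coordinate in BED file")
  if (any(BiocGenerics::width(gr) < 1L))
    stop("empty interval (start >= end) in BED file")
  if (!is.null(gr$name)) {
    gr$label <- gr$name
    gr$name <- NULL
  }
  gr
}

#' Write labeled intervals to BED
#'
#' @param gr `GRanges`, optionally with a `label` metadata column
#'   (written as the BED name field).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSpots <- function(gr, path) {
  if (!is.null(gr$label)) gr$name <- gr$label
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a per-base signal track
#'
#' Reads a bedGraph or fixed-step wiggle file and expands it to dense
#' per-base vectors over every chromosome of `genome`. Positions not
#' covered by the file are set to 0 (the declared policy: absence of
#' Spo11-oligo signal is a zero value). Overlapping bedGraph intervals
#' are rejected, as are intervals running past a chromosome end.
#'
#' @param path Path to a bedGraph (`.bedgraph`/`.bg`) or wiggle
#'   (`.wig`) file.
#' @param genome A `DNAStringSet` supplying chromosome names and lengths.
#' @param format `"auto"` (from the file extension), `"bedGraph"` or
#'   `"wig"`.
#' @return A [SignalTrack-class].
#' @export
readSignalTrack <- function(path, genome, format = c("auto", "bedGraph", "wig")) {
  .assertSingleString(path, "path")
  format <- match.arg(format)
  if (!file.exists(path)) stop("signal file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.wig(\\.gz)?$", path, ignore.case = TRUE))
      "wig" else "bedGraph"
  }
  lens <- .genomeLengths(genome)
  vals <- lapply(lens, numeric)
  nonEmpty <- any(nzchar(trimws(readLines(path, n = 50L))))
  if (nonEmpty) {
    gr <- rtracklayer::import(path, format = format)
    if (length(gr) > 0L) {
      bad <- setdiff(as.character(GenomeInfoDb::seqnames(gr)), names(lens))
      if (length(bad))
        stop("track refers to chromosomes absent from the genome: ",
             paste(unique(bad), collapse = ", "))
      ends <- BiocGenerics::end(gr)
      if (any(ends > lens[as.character(GenomeInfoDb::seqnames(gr))]))
        stop("track interval extends beyond chromosome end")
      self <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                          drop.redundant = TRUE)
      if (length(self) > 0L)
        stop("overlapping intervals in signal file (dialect not supported)")
      df <- data.frame(chrom = as.character(GenomeInfoDb::seqnames(gr)),
                       start = BiocGenerics::start(gr),
                       end = ends, score = gr$score)
      for (i in seq_len(nrow(df))) {
        vals[[df$chrom[i]]][df$start[i]:df$end[i]] <- df$score[i]
      }
    }
  }
  new("SignalTrack", values = vals)
}

#' @describeIn SignalTrack-class Construct a track from a named list of
#'   per-chromosome numeric vectors.
#' @param values Named list of finite numeric vectors.
#' @export
SignalTrack <- function(values) new("SignalTrack", values = values)

#' Per-chromosome values of a signal track
#'
#' @param x A [SignalTrack-class].
#' @param chrom Optional chromosome name; when given, returns that
#'   chromosome's numeric vector instead of the full list.
#' @return Named list of numeric vectors, or one vector.
#' @export
trackValues <- function(x, chrom = NULL) {
  stopifnot(is(x, "SignalTrack"))
  if (is.null(chrom)) return(x@values)
  if (!chrom %in% names(x@values)) stop("no such chromosome in track: ", chrom)
  x@values[[chrom]]
}

setMethod("show", "SignalTrack", function(object) {
  cat(sprintf("SignalTrack over %d chromosome(s), %s bases total\n",
              length(object@values),
              format(sum(lengths(object@values)), big.mark = ",")))
})

#' Extract interval sequences from a genome
#'
#' Returns the forward-strand genome substring of each interval. Never
#' clips: an interval outside its chromosome is an error (callers decide
#' whether to drop such intervals beforehand).
#'
#' @param genome A `DNAStringSet`.
#' @param intervals A `GRanges`.
#' @return A `DNAStringSet`, one sequence per interval, same order.
#' @export
extractSequence <- function(genome, intervals) {
  lens <- .genomeLengths(genome)
  chroms <- as.character(GenomeInfoDb::seqnames(intervals))
  if (!all(chroms %in% names(lens)))
    stop("interval on a chromosome absent from the genome")
  if (any(BiocGenerics::start(intervals) < 1L) ||
      any(BiocGenerics::end(intervals) > lens[chroms]))
    stop("interval out of chromosome bounds")
  out <- vector("list", length(intervals))
  for (i in seq_along(intervals)) {
    out[[i]] <- Biostrings::subseq(genome[[chroms[i]]],
                                   BiocGenerics::start(intervals)[i],
                                   BiocGenerics::end(intervals)[i])
  }
  ans <- Biostrings::DNAStringSet(out)
  names(ans) <- names(intervals)
  ans
}

#' Write a signal track as bedGraph
#'
#' Run-length-compresses each chromosome and writes one bedGraph line
#' per nonzero run (uncovered-equals-zero policy, mirroring
#' [readSignalTrack()]).
#'
#' @param track A [SignalTrack-class].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeSignalTrack <- function(track, path) {
  stopifnot(is(track, "SignalTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track@values)) {
    r <- S4Vectors::Rle(track@values[[chrom]])
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- ends - S4Vectors::runLength(r) + 1L
    keep <- S4Vectors::runValue(r) != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, starts[keep] - 1L,
                       ends[keep],
                       format(S4Vectors::runValue(r)[keep], digits = 10L,
                              trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}

#' Construct a SpotFeatureSet
#'
#' @param values Numeric samples-by-features matrix (feature names as
#'   column names).
#' @param labels Per-sample label, 1 = hot, 0 = cold.
#' @param sampleIds Optional sample identifiers (default: rownames of
#'   `values`, else `spot1..spotN`).
#' @return A [SpotFeatureSet-class].
#' @export
spotFeatureSet <- function(values, labels, sampleIds = NULL) {
  values <- as.matrix(values)
  if (is.null(sampleIds)) sampleIds <- rownames(values)
  if (is.null(sampleIds) && nrow(values) > 0L)
    sampleIds <- paste0("spot", seq_len(nrow(values)))
  labels <- as.integer(labels)
  if (length(labels) != nrow(values))
    stop("one label per sample required")
  assay <- t(values)
  colnames(assay) <- sampleIds
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = assay),
    colData = S4Vectors::DataFrame(label = labels, row.names = sampleIds))
  new("SpotFeatureSet", se)
}

#' Feature values as a samples-by-features matrix
#'
#' @param x A [SpotFeatureSet-class].
#' @return Numeric matrix, samples in rows.
#' @export
featureValues <- function(x) {
  stopifnot(is(x, "SpotFeatureSet"))
  t(SummarizedExperiment::assay(x))
}

#' Binary spot labels (1 = hot, 0 = cold)
#'
#' @param x A [SpotFeatureSet-class] or [SpotSet-class].
#' @return Integer vector.
#' @export
spotLabels <- function(x) {
  if (is(x, "SpotFeatureSet"))
    return(as.integer(SummarizedExperiment::colData(x)$label))
  if (is(x, "SpotSet"))
    return(as.integer(x@windows$label == "hot"))
  stop("spotLabels() needs a SpotFeatureSet or SpotSet")
}

#' Write / read a feature matrix as TSV
#'
#' The on-disk format is a plain TSV: a header row, the sample id in the
#' first column, one column per feature, and the binary label in the
#' last column. The round trip is lossless to at least 12 significant
#' digits.
#'
#' @param x A [SpotFeatureSet-class].
#' @param path Output (input) path.
#' @return `writeFeatureMatrix` invisibly returns `path`;
#'   `readFeatureMatrix` returns a [SpotFeatureSet-class].
#' @export
writeFeatureMatrix <- function(x, path) {
  stopifnot(is(x, "SpotFeatureSet"))
  m <- featureValues(x)
  if (length(m) > 0L && !all(is.finite(m)))
    stop("feature matrix contains non-finite values; refusing to write")
  if (nrow(m) == 0L) {
    df <- data.frame(sample_id = character(),
                     stats::setNames(rep(list(character()), ncol(m)),
                                     colnames(m)),
                     label = integer(), check.names = FALSE)
  } else {
    # write.table renders doubles at 15 significant digits
    df <- data.frame(sample_id = colnames(SummarizedExperiment::assay(x)),
                     as.data.frame(m), label = spotLabels(x),
                     check.names = FALSE, stringsAsFactors = FALSE)
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFeatureMatrix
#' @export
readFeatureMatrix <- function(path) {
  .assertSingleString(path, "path")
  if (!file.exists(path)) stop("feature matrix file not found: ", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "sample_id" ||
      names(df)[ncol(df)] != "label")
    stop("feature TSV must have sample_id first and label last")
  featNames <- names(df)[-c(1L, ncol(df))]
  if (anyDuplicated(featNames)) stop("duplicate feature names in file")
  m <- as.matrix(df[, featNames, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample_id
  spotFeatureSet(m, labels = df$label, sampleIds = df$sample_id)
}

setMethod("show", "SpotFeatureSet", function(object) {
  lab <- spotLabels(object)
  cat(sprintf("SpotFeatureSet: %d features x %d spots (%d hot, %d cold)\n",
              nrow(object), ncol(object), sum(lab == 1L), sum(lab == 0L)))
})
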