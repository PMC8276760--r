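#' GC content of a sequence
#'
#' `(N_G + N_C) / (N_A + N_T + N_G + N_C)`. N bases are excluded from
#' both numerator and denominator.
#'
#' @param seq A DNA string (character or `DNAString`).
#' @return Value in `[0, 1]`.
#' @examples
#' gcContent("ATGC")
#' @export
gcContent <- function(seq) {
  codes <- .baseCodes(seq)
  if (length(codes) < 1L) stop("empty sequence")
  n <- tabulate(codes + 1L, nbins = 4L)
  if (sum(n) == 0L) stop("GC content undefined: no A/C/G/T in sequence")
  (n[2L] + n[3L]) / sum(n)
}

#' GC skew of a sequence
#'
#' `(N_G - N_C) / (N_G + N_C)`, the strand-asymmetric compositional
#' statistic. Computed on the forward strand as given.
#'
#' @param seq A DNA string.
#' @return Value in `[-1, 1]`.
#' @examples
#' gcSkew("GCCC")
#' @export
gcSkew <- function(seq) {
  codes <- .baseCodes(seq)
  n <- tabulate(codes + 1L, nbins = 4L)
  if (n[2L] + n[3L] == 0L) stop("GC skew undefined: no G or C in sequence")
  (n[3L] - n[2L]) / (n[3L] + n[2L])
}

#' Dinucleotide mutual information
#'
#' Overall deviation of observed overlapping-dinucleotide frequencies
#' from the product of mononucleotide frequencies,
#' `MI = sum_ij p_ij log2(p_ij / (p_i p_j))`, in bits. Dinucleotides are
#' counted with overlap at step 1; terms with `p_ij = 0` contribute 0;
#' pairs containing N are skipped.
#'
#' @param seq A DNA string of length >= 2.
#' @return MI in bits (>= 0 up to floating point).
#' @examples
#' mutualInformation("ATATATAT")
#' @export
mutualInformation <- function(seq) {
  codes <- .baseCodes(seq)
  L <- length(codes)
  if (L < 2L) stop("mutual information needs a sequence of length >= 2")
  mono <- tabulate(codes + 1L, nbins = 4L)
  if (sum(mono) == 0L) stop("mutual information undefined: all-N sequence")
  p <- mono / sum(mono)
  a <- codes[-L]; b <- codes[-1L]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) stop("mutual information undefined: no valid dinucleotide")
  di <- tabulate(a[ok] * 4L + b[ok] + 1L, nbins = 16L)
  pij <- di / sum(di)
  expec <- as.vector(t(outer(p, p)))  # p_i * p_j, first base varying slowest
  pos <- pij > 0
  sum(pij[pos] * log2(pij[pos] / expec[pos]))
}

#' k-mer composition with Laplace smoothing
#'
#' Occurrence probabilities of all 4^k k-mers counted at step 1 along
#' the sequence (k-mers containing N are skipped). For `k <= 2` the raw
#' fractions `N_t / sum(N)` are returned; for `k >= 3` an add-one
#' (Laplace) correction is applied, `(N_t + 1) / (sum(N) + 4^k)`, so
#' that short sequences never yield zero probabilities. The result sums
#' to 1, in fixed lexicographic k-mer order.
#'
#' @param seq A DNA string of length >= k.
#' @param k Word length, 1..6.
#' @return Named numeric vector of length 4^k.
#' @examples
#' kmerComposition("AAAAA", k = 3)[c("AAA", "AAC")]
#' @export
kmerComposition <- function(seq, k = 4L) {
  k <- as.integer(k)
  if (length(k) != 1L || is.na(k) || k < 1L || k > 6L)
    stop("k must lie in 1..6")
  x <- Biostrings::DNAString(toupper(as.character(seq)))
  if (length(x) < k) stop("sequence shorter than k")
  counts <- Biostrings::oligonucleotideFrequency(x, width = k, step = 1L)
  counts <- counts[allKmers(k)]
  tot <- sum(counts)
  if (k <= 2L) {
    if (tot == 0L) stop("no valid k-mer in sequence")
    p <- counts / tot
  } else {
    p <- (counts + 1) / (tot + 4L^k)
  }
  p
}

.newProfile <- function(values, positions, windowSize, step = 1) {
  new("Profile", values = as.numeric(values),
      positions = as.numeric(positions),
      windowSize = as.numeric(windowSize), step = as.numeric(step))
}

#' Values and positions of a Profile
#'
#' @param x A [Profile-class].
#' @return Numeric vector.
#' @export
profileValues <- function(x) { stopifnot(is(x, "Profile")); x@values }

#' @rdname profileValues
#' @export
profilePositions <- function(x) { stopifnot(is(x, "Profile")); x@positions }

setMethod("show", "Profile", function(object) {
  cat(sprintf("Profile: %d values, window %g bp, step %g bp, offsets [%g, %g]\n",
              length(object@values), object@windowSize, object@step,
              min(object@positions), max(object@positions)))
})

## sliding-window column sums of an indicator matrix via one flat
## cumsum; within-column differences cancel the cross-column carry
.windowColSums <- function(ind, window) {
  L <- nrow(ind)
  n <- L - window + 1L
  cs <- matrix(cumsum(as.numeric(ind)), nrow = L)
  row0 <- c(0, cs[L, -ncol(ind)])
  csA <- rbind(row0, cs)
  i <- seq_len(n)
  cs[i + window - 1L, , drop = FALSE] - csA[i, , drop = FALSE]
}

## per-window base counts (windows x 4)
.windowBaseCounts <- function(codes, window) {
  L <- length(codes)
  ind <- matrix(0L, nrow = L, ncol = 4L)
  ok <- !is.na(codes)
  ind[cbind(which(ok), codes[ok] + 1L)] <- 1L
  .windowColSums(ind, window)
}

#' Sliding-window profile of a compositional statistic
#'
#' Computes GC content, GC skew or dinucleotide mutual information in
#' every fully contained window placement at step 1 bp, assigning each
#' value to the window's center offset relative to the sequence center.
#' Windows in which GC skew is undefined (no G or C) emit 0 with a
#' warning so the profile length stays deterministic.
#'
#' @param seq A DNA string.
#' @param window Window width in bp (study defaults: 100 bp for GC
#'   content and GC skew, 200 bp for MI).
#' @param stat One of `"gc_content"`, `"gc_skew"`,
#'   `"mutual_information"`.
#' @return A [Profile-class] with `L - window + 1` values.
#' @export
slidingProfile <- function(seq, window,
                           stat = c("gc_content", "gc_skew",
                                    "mutual_information")) {
  stat <- match.arg(stat)
  codes <- .baseCodes(seq)
  L <- length(codes)
  window <- as.integer(window)
  if (length(window) != 1L || is.na(window) || window < 1L)
    stop("window must be a positive integer")
  if (window > L) stop("window exceeds sequence length")
  if (stat == "mutual_information" && window < 2L)
    stop("mutual information needs window >= 2")
  n <- L - window + 1L
  cnt <- .windowBaseCounts(codes, window)
  if (stat == "gc_content") {
    denom <- rowSums(cnt)
    vals <- (cnt[, 2L] + cnt[, 3L]) / denom
    if (any(denom == 0)) {
      warning(sum(denom == 0), " all-N window(s): GC content emitted as NA")
      vals[denom == 0] <- NA_real_
    }
  } else if (stat == "gc_skew") {
    denom <- cnt[, 2L] + cnt[, 3L]
    vals <- ifelse(denom > 0, (cnt[, 3L] - cnt[, 2L]) / denom, 0)
    if (any(denom == 0))
      warning(sum(denom == 0),
              " window(s) without G or C: GC skew emitted as 0")
  } else {
    a <- codes[-L]; b <- codes[-1L]
    okPair <- !is.na(a) & !is.na(b)
    di <- matrix(0L, nrow = L - 1L, ncol = 16L)
    di[cbind(which(okPair), a[okPair] * 4L + b[okPair] + 1L)] <- 1L
    dc <- .windowColSums(di, window - 1L)
    dtot <- rowSums(dc)
    mtot <- rowSums(cnt)
    P <- dc / dtot                              # windows x 16, p_ij
    pm <- cnt / mtot                            # windows x 4, p_i
    Q <- pm[, rep(1:4, each = 4L), drop = FALSE] *
      pm[, rep(1:4, times = 4L), drop = FALSE]  # p_i * p_j, ij order
    term <- P * log2(P / Q)
    term[!is.finite(term)] <- 0
    vals <- rowSums(term)
    bad <- dtot == 0 | mtot == 0
    if (any(bad)) {
      warning(sum(bad), " window(s) with no valid dinucleotide: MI NA")
      vals[bad] <- NA_real_
    }
  }
  pos <- (seq_len(n) - 1) + (window - 1) / 2 - (L - 1) / 2
  .newProfile(vals, pos, windowSize = window)
}

#' Mean and variance of a profile over the central span
#'
#' Summarizes the profile values whose center offset lies within
#' `span/2` bp of the sequence center as a mean and a sample variance
#' (n - 1 denominator). A span larger than the profile extent
#' summarizes all values. `NA` profile values (e.g. N-containing steps)
#' are excluded.
#'
#' @param profile A [Profile-class].
#' @param span Central span in bp (default 300).
#' @return List with `mean`, `variance`, `span`, `n`.
#' @export
blockSummary <- function(profile, span = 300L) {
  stopifnot(is(profile, "Profile"))
  if (span <= 0) stop("span must be positive")
  sel <- abs(profile@positions) <= span / 2 + 1e-9
  vals <- profile@values[sel]
  vals <- vals[!is.na(vals)]
  if (length(vals) < 2L)
    stop("fewer than 2 profile values inside the central span")
  list(mean = mean(vals), variance = stats::var(vals),
       span = span, n = length(vals))
}

## central `span` bp of a sequence, matching the centered-window geometry
.centralSubsequence <- function(seq, span) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  if (span > L) stop("central span exceeds sequence length")
  start0 <- (L - span) %/% 2L
  substr(s, start0 + 1L, start0 + span)
}

#' Compositional feature block of a spot sequence
#'
#' Emits the DNA-composition features of one fixed-width spot window:
#' mean and variance of the sliding GC-content, GC-skew and
#' mutual-information profiles over the central span, plus the
#' Laplace-smoothed k-mer composition of the central span — exactly
#' `6 + 4^k` named values.
#'
#' Feature names follow the grammar `gc_content.mean`, `gc_skew.var`,
#' `mi.mean`, `kmer4.ACGT`, ...
#'
#' @param seq A DNA string (typically the 1000-bp retrieved window).
#' @param k k-mer size (default 4, the best-performing size).
#' @param central Central span in bp for the block summaries and the
#'   k-mer region (default 300; 150 and 500 are the sensitivity
#'   settings).
#' @param windows Named sliding-window widths for the three profile
#'   statistics.
#' @return Named numeric vector of length `6 + 4^k`.
#' @export
sequenceFeatureBlock <- function(seq, k = 4L, central = 300L,
                                 windows = c(gc_content = 100L,
                                             gc_skew = 100L,
                                             mutual_information = 200L)) {
  out <- numeric(0)
  for (stat in c("gc_content", "gc_skew", "mutual_information")) {
    prof <- slidingProfile(seq, windows[[stat]], stat)
    bs <- blockSummary(prof, span = central)
    nm <- if (stat == "mutual_information") "mi" else stat
    out <- c(out, stats::setNames(c(bs$mean, bs$variance),
                                  paste0(nm, c(".mean", ".var"))))
  }
  km <- kmerComposition(.centralSubsequence(seq, central), k = k)
  names(km) <- paste0("kmer", k, ".", names(km))
  c(out, km)
}
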