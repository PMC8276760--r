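## Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

#' All k-mers over {A,C,G,T} in lexicographic order
#'
#' @param k Word length.
#' @return Character vector of length 4^k.
#' @examples
#' allKmers(1)
#' @export
allKmers <- function(k) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, k >= 1L)
  out <- BASES
  if (k > 1L) for (i in seq_len(k - 1L)) {
    out <- as.vector(t(outer(out, BASES, paste0)))
  }
  out
}

## sequence -> integer codes A=0 C=1 G=2 T=3, NA for anything else (N)
.baseCodes <- function(seq) {
  ch <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1]]
  m <- match(ch, BASES) - 1L
  m
}

## rolling base-4 k-mer index (1-based into allKmers(k)); NA where the
## word contains a non-ACGT letter
.kmerIndex <- function(codes, k) {
  L <- length(codes)
  if (L < k) stop("sequence shorter than k")
  n <- L - k + 1L
  idx <- rep(0, n)
  ok <- rep(TRUE, n)
  for (j in seq_len(k)) {
    cj <- codes[j:(j + n - 1L)]
    ok <- ok & !is.na(cj)
    cj[is.na(cj)] <- 0L
    idx <- idx * 4 + cj
  }
  idx <- idx + 1
  idx[!ok] <- NA
  as.integer(idx)
}

## run `expr` under a fixed RNG seed without disturbing the caller's
## RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

## derive a substream seed from a root seed; keeps results < 2^31
.subSeed <- function(seed, stream) {
  (as.double(seed) * 48271 + 7919 * as.double(stream)) %% 2147483629
}

## centered moving average, valid mode, via cumulative sums; NA propagates
.movingAverage <- function(x, width) {
  n <- length(x)
  if (width > n) stop("width exceeds profile length")
  if (width == 1L) return(x)
  cs <- cumsum(ifelse(is.na(x), 0, x))
  bad <- cumsum(is.na(x))
  i <- seq_len(n - width + 1L)
  tot <- cs[i + width - 1L] - c(0, cs)[i]
  nbad <- bad[i + width - 1L] - c(0, bad)[i]
  out <- tot / width
  out[nbad > 0L] <- NA_real_
  out
}

.assertSingleString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop(sprintf("%s must be a single string", what))
}
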