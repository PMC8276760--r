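# Brute-force reference implementations, kept deliberately naive and
# independent of the package's vectorized code paths.

width <- BiocGenerics::width

oracle_chars <- function(s) strsplit(toupper(s), "", fixed = TRUE)[[1]]

oracle_gc_content <- function(s) {
  ch <- oracle_chars(s)
  ch <- ch[ch %in% c("A", "C", "G", "T")]
  sum(ch %in% c("G", "C")) / length(ch)
}

oracle_gc_skew <- function(s) {
  ch <- oracle_chars(s)
  (sum(ch == "G") - sum(ch == "C")) / (sum(ch == "G") + sum(ch == "C"))
}

# double sum over the full 4x4 dinucleotide table
oracle_mi <- function(s) {
  ch <- oracle_chars(s)
  bases <- c("A", "C", "G", "T")
  valid <- ch %in% bases
  p <- sapply(bases, function(b) sum(ch == b)) / sum(valid)
  L <- length(ch)
  di <- paste0(ch[-L], ch[-1L])
  di <- di[valid[-L] & valid[-1L]]
  mi <- 0
  for (i in bases) for (j in bases) {
    pij <- sum(di == paste0(i, j)) / length(di)
    if (pij > 0) mi <- mi + pij * log2(pij / (p[[i]] * p[[j]]))
  }
  mi
}

oracle_kmer <- function(s, k) {
  ch <- oracle_chars(s)
  words <- vapply(seq_len(length(ch) - k + 1L),
                  function(i) paste(ch[i:(i + k - 1L)], collapse = ""),
                  character(1))
  kmers <- recspots::allKmers(k)
  counts <- sapply(kmers, function(w) sum(words == w))
  if (k <= 2L) counts / sum(counts)
  else (counts + 1) / (sum(counts) + 4^k)
}

# all-pairs Mann-Whitney with half credit for ties
oracle_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (n in neg)
    wins <- wins + if (p > n) 1 else if (p == n) 0.5 else 0
  wins / (length(pos) * length(neg))
}

# two-group ANOVA F via explicit sums of squares
oracle_anova_f <- function(x, y) {
  g0 <- x[y == 0]; g1 <- x[y == 1]
  grand <- mean(x)
  ssb <- length(g0) * (mean(g0) - grand)^2 + length(g1) * (mean(g1) - grand)^2
  ssw <- sum((g0 - mean(g0))^2) + sum((g1 - mean(g1))^2)
  (ssb / 1) / (ssw / (length(x) - 2))
}

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(oracle_chars(s)), collapse = ""))
}

# Gaussian feature matrix with labels; first `informative` features get a
# class-mean shift of `delta`
toy_matrix <- function(n = 60, p = 5, informative = 0, delta = 2,
                       seed = 1, prefix = "f") {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  m <- matrix(rnorm(n * p), nrow = n,
              dimnames = list(NULL, paste0(prefix, seq_len(p))))
  if (informative > 0)
    m[y == 1L, seq_len(informative)] <-
      m[y == 1L, seq_len(informative)] + delta
  spotFeatureSet(m, labels = y)
}

tiny_genome <- function(...) {
  seqs <- toupper(c(...))
  Biostrings::DNAStringSet(setNames(seqs, names(seqs)))
}
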