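#' Configure the synthetic benchmark generator
#'
#' Returns a [SynthConfig-class] describing a small multi-chromosome
#' genome with planted hot and cold spots. Defaults define the standard
#' study conditions used throughout the package's tests: 300 hot + 300
#' cold 1000-bp windows on a 4 x 400-kb genome with uniform background
#' composition, an anti-symmetric GC-skew of amplitude 0.3, 0.15 excess
#' A/T in the central 100 bp, a 0.2 alternating-dinucleotide bias at
#' the center, and six epigenetic marks with fold-changes
#' (H3K4me3 x2: 3, H3K56ac x2: 2, MNase: 0.5 — a nucleosome-depletion
#' dip — and Top2: 2) over Gaussian noise of SD 0.2.
#'
#' @param nChromosomes,chromLength Genome geometry.
#' @param nHot,nCold Planted spots per class.
#' @param window Spot window width in bp.
#' @param backgroundBaseProbs Length-4 base probabilities (A, C, G, T).
#' @param skewAmplitude,centerAtEnrichment,dinucleotideBias
#'   Compositional effect sizes in `[0, 1]`; 0 disables an effect.
#' @param markEnrichment Named per-mark fold-changes (1 = null).
#' @param markNoiseSd Gaussian noise SD of mark tracks.
#' @param seed Root seed; all generator streams derive from it.
#' @return A [SynthConfig-class].
#' @export
synthConfig <- function(nChromosomes = 4L, chromLength = 400000L,
                        nHot = 300L, nCold = 300L, window = 1000L,
                        backgroundBaseProbs = rep(0.25, 4L),
                        skewAmplitude = 0.3,
                        centerAtEnrichment = 0.15,
                        dinucleotideBias = 0.2,
                        markEnrichment = c(H3K4me3_A = 3, H3K56ac_A = 2,
                                           H3K4me3_B = 3, H3K56ac_B = 2,
                                           MNase = 0.5, Top2 = 2),
                        markNoiseSd = 0.2, seed = 1L) {
  new("SynthConfig", nChromosomes = as.integer(nChromosomes),
      chromLength = as.integer(chromLength), nHot = as.integer(nHot),
      nCold = as.integer(nCold), window = as.integer(window),
      backgroundBaseProbs = backgroundBaseProbs,
      skewAmplitude = skewAmplitude,
      centerAtEnrichment = centerAtEnrichment,
      dinucleotideBias = dinucleotideBias,
      markEnrichment = markEnrichment, markNoiseSd = markNoiseSd,
      seed = as.integer(seed))
}

#' Null-effect variant of a configuration
#'
#' Convenience: the same geometry with every compositional effect at 0
#' and every mark fold-change at 1, so hot and cold windows are drawn
#' from identical distributions.
#'
#' @param config A [SynthConfig-class].
#' @return A [SynthConfig-class].
#' @export
nullEffects <- function(config) {
  config@skewAmplitude <- 0
  config@centerAtEnrichment <- 0
  config@dinucleotideBias <- 0
  config@markEnrichment[] <- 1
  config
}

## sample one hot-window sequence under the configured compositional
## effects; assumes the RNG state is already positioned
.sampleHotWindow <- function(config) {
  W <- config@window
  p0 <- config@backgroundBaseProbs            # A C G T
  P <- matrix(p0, nrow = 4L, ncol = W)
  a <- config@skewAmplitude
  if (a > 0) {
    left <- seq_len(W %/% 2L)
    P[3L, left] <- P[3L, left] * (1 + a)      # G up, C down left of center
    P[2L, left] <- P[2L, left] * (1 - a)
    right <- setdiff(seq_len(W), left)
    P[3L, right] <- P[3L, right] * (1 - a)
    P[2L, right] <- P[2L, right] * (1 + a)
  }
  center <- W %/% 2L
  central <- max(1L, center - 49L):min(W, center + 50L)
  e <- config@centerAtEnrichment
  if (e > 0)                                   # mix toward pure A/T
    P[, central] <- (1 - e) * P[, central] + e * c(0.5, 0, 0, 0.5)
  P <- sweep(P, 2L, colSums(P), "/")
  u <- stats::runif(W)
  cp <- apply(P, 2L, cumsum)
  base <- 1L + colSums(cp < rep(u, each = 4L))
  seq <- BASES[base]
  d <- config@dinucleotideBias
  if (d > 0) {                                 # planted AT alternation
    hit <- central[stats::runif(length(central)) < d]
    seq[hit] <- ifelse(hit %% 2L == 0L, "A", "T")
  }
  paste(seq, collapse = "")
}

#' Generate the synthetic genome and planted spots
#'
#' Background sequence is i.i.d. from the configured base
#' probabilities. Hot windows carry the compositional effects
#' (anti-symmetric G/C bias, central A/T excess, central
#' alternating-dinucleotide bias); cold windows are pure background.
#' Window placements are non-overlapping and at least one window width
#' apart. Deterministic given the seed.
#'
#' @param config A [SynthConfig-class].
#' @return List with `genome` (`DNAStringSet`), `hot` and `cold`
#'   (`GRanges` of window-width spots with labels).
#' @export
synthGenomeAndSpots <- function(config) {
  stopifnot(is(config, "SynthConfig"))
  W <- config@window
  slotW <- 2L * W
  slotsPerChrom <- config@chromLength %/% slotW
  totalSlots <- slotsPerChrom * config@nChromosomes
  nSpots <- config@nHot + config@nCold
  if (nSpots > totalSlots)
    stop("spot footprint exceeds genome capacity (", nSpots, " spots, ",
         totalSlots, " slots); enlarge the genome")
  chromNames <- paste0("chr", seq_len(config@nChromosomes))
  .withSeed(.subSeed(config@seed, 1L), {
    chromSeqs <- lapply(chromNames, function(cn)
      sample(BASES, config@chromLength, replace = TRUE,
             prob = config@backgroundBaseProbs))
    names(chromSeqs) <- chromNames
    slots <- sort(sample.int(totalSlots, nSpots))
    isHot <- logical(nSpots)
    isHot[sample.int(nSpots, config@nHot)] <- TRUE
    chromIdx <- (slots - 1L) %/% slotsPerChrom + 1L
    slotInChrom <- (slots - 1L) %% slotsPerChrom
    start <- slotInChrom * slotW + W %/% 2L + 1L   # 1-based window start
    for (i in which(isHot)) {
      hotSeq <- strsplit(.sampleHotWindow(config), "", fixed = TRUE)[[1]]
      chromSeqs[[chromIdx[i]]][start[i]:(start[i] + W - 1L)] <- hotSeq
    }
    genome <- Biostrings::DNAStringSet(
      vapply(chromSeqs, paste, character(1L), collapse = ""))
    gr <- GenomicRanges::GRanges(chromNames[chromIdx],
                                 IRanges::IRanges(start, width = W))
    gr$label <- ifelse(isHot, "hot", "cold")
    list(genome = genome, hot = gr[isHot], cold = gr[!isHot])
  })
}

#' Generate a Spo11-oligo-like signal track
#'
#' Strictly positive noisy background everywhere, elevated signal over
#' hot windows, and exact zeros across every cold window — so coldspot
#' calling recovers the planted cold intervals exactly.
#'
#' @param genome The synthetic `DNAStringSet`.
#' @param hot,cold Planted spot `GRanges`.
#' @param config The [SynthConfig-class] used to generate them.
#' @return A [SignalTrack-class].
#' @export
synthSpo11Track <- function(genome, hot, cold, config) {
  lens <- .genomeLengths(genome)
  .withSeed(.subSeed(config@seed, 2L), {
    vals <- lapply(lens, function(L) stats::runif(L, 0.05, 2))
    for (i in seq_along(hot)) {
      cn <- as.character(GenomeInfoDb::seqnames(hot))[i]
      s <- BiocGenerics::start(hot)[i]; e <- BiocGenerics::end(hot)[i]
      vals[[cn]][s:e] <- vals[[cn]][s:e] +
        stats::rgamma(e - s + 1L, shape = 4, rate = 0.8)
    }
    for (i in seq_along(cold)) {
      cn <- as.character(GenomeInfoDb::seqnames(cold))[i]
      vals[[cn]][BiocGenerics::start(cold)[i]:BiocGenerics::end(cold)[i]] <- 0
    }
    SignalTrack(vals)
  })
}

#' Generate epigenetic mark tracks
#'
#' One track per entry of the configured mark set: Gaussian noise
#' around a baseline of 1, with the mean multiplied by the mark's
#' fold-change across hot windows (folds below 1 model a depletion dip,
#' e.g. MNase). Negative draws are clipped at 0 (reported via a
#' message). Deterministic given the seed.
#'
#' @inheritParams synthSpo11Track
#' @return Named list of [SignalTrack-class] objects.
#' @export
synthMarkTracks <- function(genome, hot, cold, config) {
  lens <- .genomeLengths(genome)
  marks <- config@markEnrichment
  out <- vector("list", length(marks))
  names(out) <- names(marks)
  nClipped <- 0L
  for (j in seq_along(marks)) {
    out[[j]] <- .withSeed(.subSeed(config@seed, 10L + j), {
      vals <- lapply(lens, function(L) {
        stats::rnorm(L, mean = 1, sd = config@markNoiseSd)
      })
      for (i in seq_along(hot)) {
        cn <- as.character(GenomeInfoDb::seqnames(hot))[i]
        s <- BiocGenerics::start(hot)[i]; e <- BiocGenerics::end(hot)[i]
        vals[[cn]][s:e] <- stats::rnorm(e - s + 1L, mean = marks[[j]],
                                        sd = config@markNoiseSd)
      }
      clip <- vapply(vals, function(v) sum(v < 0), numeric(1))
      nClipped <<- nClipped + sum(clip)
      SignalTrack(lapply(vals, pmax, 0))
    })
  }
  if (nClipped > 0L)
    message(nClipped, " negative mark value(s) clipped at 0")
  out
}

#' Generate a complete synthetic benchmark
#'
#' Convenience wrapper chaining genome/spot generation, the Spo11-like
#' track, the mark tracks, benchmark assembly and feature extraction.
#'
#' @param config A [SynthConfig-class].
#' @param tables Parameter tables for the structural family (default:
#'   full inventory; `list()` disables).
#' @param k k-mer size, or `NULL` to skip k-mer features.
#' @param central Central span in bp.
#' @param marks Include the epigenetic tracks and their features?
#' @return List with `genome`, `hot`, `cold`, `spotSet`, `spo11`,
#'   `marks`, `features` (a [SpotFeatureSet-class]) and `config`.
#' @export
synthBenchmark <- function(config = synthConfig(),
                           tables = defaultParameterTables(),
                           k = 4L, central = 300L, marks = TRUE) {
  gs <- synthGenomeAndSpots(config)
  spo11 <- synthSpo11Track(gs$genome, gs$hot, gs$cold, config)
  markTracks <- if (marks)
    synthMarkTracks(gs$genome, gs$hot, gs$cold, config) else NULL
  spotSet <- buildBenchmark(gs$hot, gs$cold, gs$genome,
                            width = config@window, source = "synthetic")
  features <- extractFeatures(spotSet, gs$genome, tables = tables,
                              tracks = markTracks, k = k,
                              central = central)
  list(genome = gs$genome, hot = gs$hot, cold = gs$cold,
       spotSet = spotSet, spo11 = spo11, marks = markTracks,
       features = features, config = config)
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(paste0("SynthConfig: %d x %s bp genome, %d hot + %d cold ",
                     "%d-bp windows, seed %d\n",
                     "  effects: skew %.2f, central A/T %.2f, dinucleotide ",
                     "%.2f; marks: %s\n"),
              object@nChromosomes, format(object@chromLength, big.mark = ","),
              object@nHot, object@nCold, object@window, object@seed,
              object@skewAmplitude, object@centerAtEnrichment,
              object@dinucleotideBias,
              paste(names(object@markEnrichment), object@markEnrichment,
                    sep = "=", collapse = ", ")))
})
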