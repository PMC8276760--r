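test_that("GC content and GC skew match direct counts", {
  expect_equal(gcContent("ATGC"), 0.5)
  expect_equal(gcContent("AAAA"), 0)
  expect_equal(gcContent("GGCCGGTA"), 0.75)
  expect_equal(gcContent("ANGN"), 0.5)   # N excluded from both sides
  expect_error(gcContent("NNN"), "undefined")
  expect_error(gcContent(""), "empty")

  expect_equal(gcSkew("GGCC"), 0)
  expect_equal(gcSkew("GGGG"), 1)
  expect_equal(gcSkew("GCCC"), -0.5)
  expect_error(gcSkew("ATAT"), "undefined")
})

test_that("mutual information equals the brute-force double sum", {
  expect_equal(mutualInformation("AAAAAAAA"), 0)
  expect_equal(mutualInformation("ATATATAT"), oracle_mi("ATATATAT"))
  expect_equal(mutualInformation("ATATATAT"), 1.0148, tolerance = 1e-4)
  expect_error(mutualInformation("A"), "length >= 2")

  set.seed(31)
  for (i in 1:25) {
    s <- rand_dna(sample(2:50, 1),
                  alphabet = c("A", "C", "G", "T",
                               if (i %% 5 == 0) "N"))
    if (substr(s, 1, 2) == "NN") next
    expect_equal(mutualInformation(s), oracle_mi(s), tolerance = 1e-12,
                 info = s)
    expect_gte(mutualInformation(s), -1e-12)
  }

  # MI is invariant under the consistent relabeling A<->T, C<->G
  set.seed(32)
  for (i in 1:10) {
    s <- rand_dna(30)
    expect_equal(mutualInformation(chartr("ACGT", "TGCA", s)),
                 mutualInformation(s), tolerance = 1e-12)
  }

  # independence limit: long i.i.d. sequence has near-zero MI
  set.seed(33)
  expect_lt(mutualInformation(rand_dna(50000)), 1e-3)
})

test_that("k-mer composition applies add-one smoothing only for k > 2", {
  p <- kmerComposition("AACC", k = 1)
  expect_equal(unname(p), c(0.5, 0.5, 0, 0))
  expect_equal(names(p), c("A", "C", "G", "T"))

  p <- kmerComposition("AAAA", k = 2)
  expect_equal(p[["AA"]], 1)
  expect_equal(sum(p == 0), 15L)

  p <- kmerComposition("AAAAA", k = 3)
  expect_equal(p[["AAA"]], 4 / 67)
  expect_equal(unname(p[names(p) != "AAA"]), rep(1 / 67, 63))

  expect_error(kmerComposition("ACGT", k = 0), "1..6")
  expect_error(kmerComposition("ACGT", k = 7), "1..6")
  expect_error(kmerComposition("AC", k = 3), "shorter")

  set.seed(41)
  for (i in 1:12) {
    k <- sample(1:6, 1)
    s <- rand_dna(sample(max(k, 10):50, 1),
                  alphabet = c("A", "C", "G", "T", if (i %% 4 == 0) "N"))
    p <- kmerComposition(s, k)
    expect_equal(sum(p), 1, tolerance = 1e-12)            # sums to 1
    expect_equal(unname(p), unname(oracle_kmer(s, k)), tolerance = 1e-12)
  }
})

test_that("sliding profiles scan every placement at step 1", {
  p <- slidingProfile("GGGGCCCC", 4, "gc_skew")
  expect_equal(profileValues(p), c(1, 0.5, 0, -0.5, -1))
  expect_equal(profilePositions(p), c(-2, -1, 0, 1, 2))

  # constant sequence -> constant profile; L - w + 1 values
  set.seed(51)
  s <- rand_dna(1000)
  expect_length(profileValues(slidingProfile(s, 100, "gc_content")), 901L)
  p <- slidingProfile(strrep("ACGT", 50), 8, "gc_content")
  expect_true(all(profileValues(p) == 0.5))

  expect_error(slidingProfile("ACGT", 10, "gc_content"), "exceeds")

  # undefined skew windows emit 0 with a warning, keeping length fixed
  expect_warning(p <- slidingProfile("ATATGATA", 4, "gc_skew"), "without G or C")
  expect_length(profileValues(p), 5L)
  expect_equal(profileValues(p)[1], 0)

  # profile values agree with the scalar statistics window by window
  for (stat in c("gc_content", "gc_skew", "mutual_information")) {
    w <- 20L
    p <- slidingProfile(s, w, stat)
    f <- switch(stat, gc_content = gcContent, gc_skew = gcSkew,
                mutual_information = mutualInformation)
    idx <- c(1, 250, 500, 981)
    expect_equal(profileValues(p)[idx],
                 vapply(idx, function(i) f(substr(s, i, i + w - 1)),
                        numeric(1)),
                 tolerance = 1e-12, info = stat)
  }
})

test_that("gc skew is antisymmetric under reverse complement", {
  set.seed(61)
  for (i in 1:10) {
    s <- rand_dna(40)
    if (gcContent(s) == 0) next
    expect_equal(gcSkew(revcomp(s)), -gcSkew(s), tolerance = 1e-12)
  }
})

test_that("block summaries take mean and n-1 variance over the central span", {
  # constant profile -> zero variance
  p <- slidingProfile(strrep("AC", 200), 50, "gc_content")
  bs <- blockSummary(p, 300)
  expect_equal(bs$variance, 0)
  expect_equal(bs$mean, 0.5)

  # hand-built profile with values {0, 1} inside the span
  prof <- new("Profile", values = c(9, 0, 1, 9), positions = c(-200, -10, 10, 200),
              windowSize = 1, step = 1)
  bs <- blockSummary(prof, 300)
  expect_equal(bs$mean, 0.5)
  expect_equal(bs$variance, 0.5)

  # span beyond the profile extent summarizes everything
  bs <- blockSummary(prof, 1e6)
  expect_equal(bs$n, 4L)
  expect_equal(bs$mean, mean(c(9, 0, 1, 9)))

  tiny <- new("Profile", values = c(1, 2), positions = c(-300, 300),
              windowSize = 1, step = 1)
  expect_error(blockSummary(tiny, 10), "fewer than 2")
})

test_that("the compositional block emits 6 + 4^k stably named features", {
  set.seed(71)
  s <- rand_dna(1000)
  for (k in c(2L, 4L)) {
    f <- sequenceFeatureBlock(s, k = k)
    expect_length(f, 6L + 4L^k)
    expect_equal(names(f)[1:6],
                 c("gc_content.mean", "gc_content.var", "gc_skew.mean",
                   "gc_skew.var", "mi.mean", "mi.var"))
    expect_equal(sum(grepl(paste0("^kmer", k, "\\."), names(f))), 4L^k)
    expect_false(anyDuplicated(names(f)) > 0)
    expect_true(all(is.finite(f)))
  }
  # k-mer block equals the composition of the central 300 bp
  f <- sequenceFeatureBlock(s, k = 3)
  expect_equal(unname(f[paste0("kmer3.", allKmers(3))]),
               unname(kmerComposition(substr(s, 351, 650), 3)))
})
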