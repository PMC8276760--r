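test_that("parameter tables validate completeness and round-trip via TSV", {
  tab <- nearestNeighborThermoTable()
  expect_s4_class(tab, "ParameterTable")
  expect_equal(tab@k, 2L)
  expect_equal(tab@properties, c("dG", "dH", "dS"))
  # reverse-complement symmetry of nearest-neighbor stacks
  expect_equal(tab@values["AC", "dG"], tab@values["GT", "dG"])
  expect_equal(tab@values["CG", "dH"], -10.6)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeParameterTable(tab, tsv)
  back <- loadParameterTable(tsv, name = "thermo")
  expect_equal(back@values, tab@values)

  # 15-row dinucleotide table -> completeness error
  df <- data.frame(kmer = allKmers(2)[-1], x = 1:15)
  writeLines(c("kmer\tx", paste(df$kmer, df$x, sep = "\t")), tsv)
  expect_error(loadParameterTable(tsv), "incomplete")

  writeLines(c("kmer\tx", paste(allKmers(2), c("oops", 2:16), sep = "\t")),
             tsv)
  expect_error(loadParameterTable(tsv), "non-numeric")

  # 1024-row pentamer table with several properties is valid
  shape <- syntheticShapeTable()
  expect_equal(shape@k, 5L)
  expect_equal(nrow(shape@values), 1024L)
  expect_length(shape@properties, 13L)
  # synthetic tables are deterministic across calls
  expect_identical(shape@values, syntheticShapeTable()@values)
})

test_that("step profiles are direct table lookups at word centers", {
  tab <- parameterTable("toy", matrix(1:16, ncol = 1,
                                      dimnames = list(allKmers(2), "p")))
  p <- stepProfile("ACGT", tab, "p")
  expect_equal(profileValues(p),
               unname(tab@values[c("AC", "CG", "GT"), "p"]))
  expect_equal(profilePositions(p), c(-1, 0, 1))

  p <- stepProfile(strrep("A", 20), tab, "p")
  expect_true(all(profileValues(p) == tab@values["AA", "p"]))

  expect_error(stepProfile("A", tab, "p"), "shorter")
  expect_error(stepProfile("ACGT", tab, "nope"), "no property")

  # N-containing steps are missing values
  p <- stepProfile("ACNGT", tab, "p")
  expect_equal(is.na(profileValues(p)), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("profile smoothing is a valid-mode centered moving average", {
  impulse <- new("Profile", values = c(rep(0, 12), 1, rep(0, 12)),
                 positions = seq(-12, 12), windowSize = 1, step = 1)
  sm <- smoothProfile(impulse, 10)
  expect_length(profileValues(sm), 16L)
  expect_equal(sum(profileValues(sm) == 0.1), 10L)
  expect_equal(sum(profileValues(sm)), 1)  # mass conserved

  const <- new("Profile", values = rep(3, 25), positions = seq_len(25),
               windowSize = 1, step = 1)
  sm <- smoothProfile(const, 7)
  expect_true(all(profileValues(sm) == 3))
  expect_length(profileValues(sm), 19L)

  expect_identical(profileValues(smoothProfile(const, 1)),
                   profileValues(const))
  expect_error(smoothProfile(const, 26), "exceeds")

  # NA propagates through any window touching it
  gap <- new("Profile", values = c(1, 2, NA, 4, 5, 6), positions = 1:6,
             windowSize = 1, step = 1)
  expect_equal(is.na(profileValues(smoothProfile(gap, 2))),
               c(FALSE, TRUE, TRUE, FALSE, FALSE))

  # mean preserved when the length is an exact multiple of the width
  set.seed(81)
  v <- rnorm(40)
  pr <- new("Profile", values = v, positions = seq_along(v),
            windowSize = 1, step = 1)
  sm <- profileValues(smoothProfile(pr, 5))
  expect_equal(mean(sm[seq(1, 36, by = 5)]), mean(v), tolerance = 1e-12)
})

test_that("strand-symmetric tables give mirror-image reverse profiles", {
  set.seed(83)
  vals <- rnorm(16)
  names(vals) <- allKmers(2)
  for (d in allKmers(2)) {
    rc <- revcomp(d)
    vals[d] <- vals[rc] <- (vals[d] + vals[rc]) / 2  # symmetrize
  }
  tab <- parameterTable("sym", matrix(vals, ncol = 1,
                                      dimnames = list(names(vals), "p")))
  for (i in 1:5) {
    s <- rand_dna(30)
    fwd <- profileValues(stepProfile(s, tab, "p"))
    rev <- profileValues(stepProfile(revcomp(s), tab, "p"))
    expect_equal(rev, base::rev(fwd), tolerance = 1e-12)
  }
})

test_that("the structural block emits two features per property", {
  set.seed(85)
  s <- rand_dna(1000)

  # homopolymer -> constant profiles, variances zero up to float rounding
  f <- structuralBlock(strrep("A", 1000))
  expect_lt(max(f[grepl("\\.var$", names(f))]), 1e-20)

  # two small tables with 1 + 2 properties -> 6 features
  t1 <- parameterTable("one", matrix(rnorm(16), ncol = 1,
                                     dimnames = list(allKmers(2), "a")))
  t2 <- parameterTable("two", matrix(rnorm(32), ncol = 2,
                                     dimnames = list(allKmers(2),
                                                     c("b", "c"))))
  f <- structuralBlock(s, list(t1, t2))
  expect_equal(names(f), c("one.a.mean", "one.a.var", "two.b.mean",
                           "two.b.var", "two.c.mean", "two.c.var"))

  # full default inventory: 84 structural features
  f <- structuralBlock(s)
  expect_length(f, 84L)
  expect_true(all(is.finite(f)))

  # block equals the hand-computed smooth-then-summarize chain
  sm <- smoothProfile(stepProfile(s, t1, "a"), 10)
  keep <- abs(profilePositions(sm)) <= 150 + 1e-9
  ref <- profileValues(sm)[keep]
  f <- structuralBlock(s, list(t1))
  expect_equal(unname(f["one.a.mean"]), mean(ref), tolerance = 1e-12)
  expect_equal(unname(f["one.a.var"]), var(ref), tolerance = 1e-12)

  # tiny end-to-end arithmetic check on an 8-bp toy, smoothing width 2:
  # steps AC CG GT TA AC CG GT -> lookups averaged pairwise
  toy <- parameterTable("toy", matrix(seq(10, 160, by = 10), ncol = 1,
                                      dimnames = list(allKmers(2), "p")))
  look <- toy@values[c("AC", "CG", "GT", "TA", "AC", "CG", "GT"), "p"]
  smoothed <- (look[-7] + look[-1]) / 2
  f <- structuralBlock("ACGTACGT", list(toy), span = 1000, smooth = 2)
  expect_equal(unname(f["toy.p.mean"]), mean(smoothed), tolerance = 1e-12)
  expect_equal(unname(f["toy.p.var"]), var(smoothed), tolerance = 1e-12)
})
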