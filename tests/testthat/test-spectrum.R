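test_that("mutation contexts read off the reference with strand collapse", {
  expect_equal(mutationContext(c(chr1 = "ATCAG"),
                               data.frame(sample = "s", chrom = "chr1",
                                          pos = 3, ref = "C", alt = "T")),
               "T[C>T]A")
  ## purine reference base: reverse-complemented to the pyrimidine strand
  expect_equal(mutationContext(c(chr1 = "CTGAT"),
                               data.frame(sample = "s", chrom = "chr1",
                                          pos = 3, ref = "G", alt = "A")),
               "T[C>T]A")
  expect_error(mutationContext(c(chr1 = "ATCAG"),
                               data.frame(sample = "s", chrom = "chr1",
                                          pos = 1, ref = "A", alt = "C")),
               "context")
  expect_error(mutationContext(c(chr1 = "ATCAG"),
                               data.frame(sample = "s1", chrom = "chr1",
                                          pos = 3, ref = "G", alt = "A")),
               "mismatch.*s1")
})

test_that("strand collapse is an involution on the reverse complement", {
  withr::with_seed(31, {
    ref <- as.character(simulateReference(500, 0.5, rng_seed = 31))
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ref)))
    L <- nchar(ref)
    for (k in 1:50) {
      pos <- sample(2:(L - 1), 1)
      refBase <- substring(ref, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), refBase), 1)
      fwd <- mutationContext(c(c1 = ref),
                             data.frame(sample = "s", chrom = "c1", pos = pos,
                                        ref = refBase, alt = alt))
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      rev <- mutationContext(c(c1 = rc),
                             data.frame(sample = "s", chrom = "c1",
                                        pos = L - pos + 1,
                                        ref = comp[[refBase]],
                                        alt = comp[[alt]]))
      expect_identical(fwd, rev)
    }
  })
})

test_that("spectra partition counts into proportions", {
  ref <- c(chr1 = "AATCATTCGAGCCAA")
  muts <- data.frame(sample = "s", chrom = "chr1", pos = c(4, 8, 11, 13),
                     ref = c("C", "C", "G", "C"),
                     alt = c("T", "G", "A", "A"))
  sp <- buildSpectrum(muts, ref)
  expect_equal(nMutations(sp), 4L)
  expect_equal(sum(channelCounts(sp)), 4)
  expect_equal(sort(unname(channelProportions(sp)[channelCounts(sp) > 0])),
               rep(0.25, 4))
  ## duplicating one mutation increments exactly its channel
  sp2 <- buildSpectrum(rbind(muts, muts[1, ]), ref)
  expect_equal(channelCounts(sp2)[["T[C>T]A"]],
               channelCounts(sp)[["T[C>T]A"]] + 1)
  empty <- buildSpectrum(muts[0, ], ref)
  expect_equal(nMutations(empty), 0L)
  expect_true(all(is.na(channelProportions(empty))))
})

test_that("a pure APOBEC cohort concentrates on TCW channels", {
  ref <- simulateReference(30000, 0.5, rng_seed = 41)
  cfg <- cohortConfig(
    n_patients = 3, muts_per_patient = 80,
    signature_weights = list(
      early_clonal = c(apobec = 1, smoking = 0, ageing = 0, other = 0),
      late_clonal  = c(apobec = 1, smoking = 0, ageing = 0, other = 0),
      subclonal    = c(apobec = 1, smoking = 0, ageing = 0, other = 0)),
    rng_seed = 42)
  co <- simulateCohort(cfg, ref)
  sp <- buildSpectrum(co$mutations, ref)
  tcw <- c("T[C>T]A", "T[C>T]T", "T[C>G]A", "T[C>G]T")
  expect_equal(sum(channelProportions(sp)[tcw]), 1)
})

test_that("reference motif frequencies enumerate windows over length - 2", {
  lit <- referenceMotifFrequencies("ATCAGT", mode = "literal")
  expect_equal(lit$denominator, 4)
  expect_equal(unname(lit$frequencies[c("ATC", "TCA", "CAG", "AGT")]),
               rep(0.25, 4))
  expect_equal(sum(lit$frequencies), 1)

  homo <- referenceMotifFrequencies("AAAA", mode = "literal")
  expect_equal(unname(homo$frequencies[["AAA"]]), 1)

  big <- referenceMotifFrequencies(simulateReference(1e5, 0.5, rng_seed = 2))
  expect_lt(abs(sum(big$frequencies) - 1), 1e-9)
  expect_equal(length(big$frequencies), 32L)
  expect_error(referenceMotifFrequencies("AT"), "length")

  ## collapsed mode merges each window with its reverse complement
  col <- referenceMotifFrequencies("ATCAGT", mode = "collapsed")
  ## windows: ATC, TCA, CAG (-> CTG), AGT (-> ACT)
  expect_equal(unname(col$frequencies[c("ATC", "TCA", "CTG", "ACT")]),
               rep(0.25, 4))
})

test_that("motif-abundance weighting follows the adjusted-count formula", {
  ref <- c(chr1 = "GTCAGACAG")  # windows include TCA and ACA
  muts <- data.frame(sample = "s", chrom = "chr1", pos = c(3, 3, 7, 7),
                     ref = "C", alt = "T")
  sp <- buildSpectrum(muts, ref)
  w <- weightedFrequencies(
    weightedSpectrum(sp, c(TCA = 0.1, ACA = 0.4)))
  expect_equal(unname(w[["T[C>T]A"]]), 0.8)
  expect_equal(unname(w[["A[C>T]A"]]), 0.2)

  ## uniform motif frequencies leave proportions unchanged
  uni <- setNames(rep(1 / 32, 32),
                  unique(sub("^(.)\\[(.)>.\\](.)$", "\\1\\2\\3",
                             trinucChannels())))
  wu <- weightedFrequencies(weightedSpectrum(sp, uni))
  expect_equal(unname(wu[channelCounts(sp) > 0]),
               unname(channelProportions(sp)[channelCounts(sp) > 0]))

  ## single nonzero channel is weighted to 1 regardless of frequency
  one <- buildSpectrum(muts[1:2, ], ref)
  w1 <- weightedFrequencies(weightedSpectrum(one, c(TCA = 0.015)))
  expect_equal(unname(w1[["T[C>T]A"]]), 1)

  expect_error(weightedSpectrum(sp, c(TCA = 0, ACA = 0.4)), "zero")
})

test_that("5x rarer motifs gain 5x weight at equal counts", {
  ## TCG windows 5x rarer than TCA; equal C>T counts in both
  ref <- c(chr1 = paste(c(rep("TCAG", 50), rep("TCGG", 10)), collapse = ""))
  freq <- referenceMotifFrequencies(ref, mode = "literal")
  muts <- data.frame(sample = "s", chrom = "chr1",
                     pos = c(2, 2 + 4 * 50), ref = "C", alt = "T")
  sp <- buildSpectrum(muts, ref)
  w <- weightedFrequencies(weightedSpectrum(sp, freq))
  expect_equal(unname(w[["T[C>T]G"]] / w[["T[C>T]A"]]), 5)
})

test_that("signature categories implement the motif definitions", {
  expect_equal(as.character(classifyCategory("T[C>T]A")), "APOBEC")
  expect_equal(as.character(classifyCategory("T[C>T]T")), "APOBEC")
  expect_equal(as.character(classifyCategory("C[C>A]G")), "smoking")
  expect_equal(as.character(classifyCategory("A[C>T]G")), "ageing")
  expect_true(is.na(classifyCategory("T[C>G]A")))  # C>G excluded by default
  expect_equal(as.character(classifyCategory("T[C>G]A", mode = "extended")),
               "APOBEC")
  expect_true(is.na(classifyCategory("A[T>G]C")))
  ## TCW excludes 3' G, so the categories cannot overlap
  ch <- trinucChannels()
  for (mode in c("ct-only", "extended")) {
    cats <- classifyCategory(ch, mode = mode)
    apo <- ch[!is.na(cats) & cats == "APOBEC"]
    expect_false(any(grepl("\\]G$", apo)))
  }
  expect_error(classifyCategory("C>T"), "invalid channel")
})

test_that("patient-timing cells obey the minimum-count inclusion rule", {
  ref <- c(chr1 = paste(rep("ATCAG", 40), collapse = ""))
  mkMuts <- function(sample, n) {
    data.frame(sample = sample, chrom = "chr1",
               pos = 5 * (seq_len(n) - 1) + 3, ref = "C",
               alt = rep(c("T", "T", "A", "G"), length.out = n))
  }
  ## 3 mutations: excluded; 4: retained; 10 with 4 APOBEC: proportion 0.4
  m3 <- mkMuts("p3", 3); m4 <- mkMuts("p4", 4)
  m10 <- mkMuts("p10", 10)
  m10$alt <- c(rep("T", 4), rep("A", 6))  # 4 APOBEC (TCA C>T), 6 smoking
  muts <- rbind(m3, m4, m10)
  props <- categoryProportions(muts, ref, min_count = 4)
  expect_false("p3" %in% props$sample)
  expect_true("p4" %in% props$sample)
  excl <- attr(props, "excluded")
  expect_equal(excl$sample, "p3")
  expect_equal(excl$n_mutations, 3L)
  p10 <- props[props$sample == "p10", ]
  expect_equal(p10$proportion[p10$category == "APOBEC"], 0.4)
  expect_equal(p10$proportion[p10$category == "smoking"], 0.6)
  expect_true(all(p10$n_mutations == 10L))
})

test_that("Welch comparison matches its contract", {
  same <- compareGroups(rep(c(0.2, 0.2), 5), rep(c(TRUE, FALSE), 5))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  expect_error(compareGroups(c(1, 2, 3), c(TRUE, FALSE, FALSE)),
               "insufficient group size")

  ## strong separation: means 0.3 vs 0.1, sd 0.05, n = 20 each
  withr::with_seed(8, {
    x <- c(rnorm(20, 0.3, 0.05), rnorm(20, 0.1, 0.05))
    g <- rep(c("a", "b"), each = 20)
    res <- compareGroups(x, g)
    expect_lt(res$p.value, 0.001)
    expect_equal(unname(res$n), c(20L, 20L))
  })

  ## type-I error at alpha = 0.05 under the null
  withr::with_seed(9, {
    rej <- mean(replicate(1000, {
      compareGroups(rnorm(20), rep(c("a", "b"), 10))$p.value < 0.05
    }))
    expect_lt(abs(rej - 0.05), 0.02)
  })
})

test_that("Fisher enrichment gives exact two-sided probabilities", {
  diag10 <- fisherEnrichment(matrix(c(10, 0, 0, 10), 2))
  expect_equal(diag10$p.value, 2 / 184756)
  expect_true(diag10$continuity_corrected)
  expect_equal(fisherEnrichment(matrix(c(5, 5, 5, 5), 2))$p.value, 1)
  cross <- fisherEnrichment(matrix(c(2, 8, 8, 2), 2))
  expect_equal(cross$p.value, oracleFisherP(2, 8, 8, 2), tolerance = 1e-12)
  expect_error(fisherEnrichment(matrix(c(0, 0, 3, 4), 2)), "margin")
  expect_error(fisherEnrichment(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})
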