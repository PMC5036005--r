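mkSeg <- function(mean, sample = "s1") {
  data.frame(sample = sample, chrom = "chr22", start = 37680000L,
             end = 37720000L, num_probes = 10L, segment_mean = mean)
}
a3bInt <- list(chrom = "chr22", start = 37683965L, end = 37713498L)

test_that("A3B zygosity follows the segment-mean and coverage-ratio rules", {
  cov <- data.frame(exon = 1:6,
                    normalized_depth = c(1, 1, 0.02, 0.02, 1, 1),
                    in_deletion = c(FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  z <- callA3BZygosity(mkSeg(-1.8), "s1", a3bInt, exon_coverage = cov)
  expect_equal(z$call, "null")
  expect_equal(z$min_segment_mean, -1.8)
  expect_equal(z$coverage_ratio, 0.02)

  covOk <- data.frame(exon = 1:4, normalized_depth = c(1, 1, 1, 1),
                      in_deletion = c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(callA3BZygosity(mkSeg(0.1), "s1", a3bInt,
                               exon_coverage = covOk)$call, "intact")
  ## -1.0 falls between the null (-1.5) and intact (-0.5) thresholds
  expect_equal(callA3BZygosity(mkSeg(-1.0), "s1", a3bInt)$call,
               "indeterminate")
  ## the boundary value itself is null ("-1.5 or less")
  expect_equal(callA3BZygosity(mkSeg(-1.5), "s1", a3bInt)$call, "null")
  noEv <- callA3BZygosity(mkSeg(-1.8, sample = "other"), "s1", a3bInt)
  expect_equal(noEv$call, "indeterminate")
  expect_equal(noEv$reason, "no evidence")
})

test_that("planted A3B nulls are never called intact", {
  segs <- do.call(rbind, lapply(1:20, function(i)
    mkSeg(-2, sample = paste0("n", i))))
  calls <- vapply(paste0("n", 1:20), function(id)
    callA3BZygosity(segs, id, a3bInt)$call, character(1))
  expect_false(any(calls == "intact"))
  expect_true(all(calls == "null"))
})

siteRow <- function(site, counts, coverage = sum(counts), q = 35,
                    sample = "s1") {
  data.frame(sample = sample, site = site, A = counts[1], C = counts[2],
              G = counts[3], T = counts[4], mean_quality = q,
              coverage = coverage)
}

test_that("A3H carrier status follows G105 copy number", {
  ## two G105 copies, clean homozygous calls at every defining site
  sc <- rbind(siteRow("c15", c(28, 0, 0, 0)), siteRow("c105", c(0, 0, 28, 0)),
              siteRow("c121", c(28, 0, 0, 0)), siteRow("c178", c(28, 0, 0, 0)))
  g <- callA3HDiplotype(sc)
  expect_true(g$carrier_status)
  expect_equal(g$g105_copies, 2L)
  expect_equal(g$haplotype_pair, c("I", "I"))

  ## one copy: heterozygous G/C at codon 105
  het <- rbind(siteRow("c15", c(29, 0, 0, 0)),
               siteRow("c105", c(0, 15, 14, 0)),
               siteRow("c121", c(14, 0, 15, 0)),
               siteRow("c178", c(15, 0, 0, 14)))
  g <- callA3HDiplotype(het)
  expect_true(g$carrier_status)
  expect_equal(g$g105_copies, 1L)
  expect_equal(g$haplotype_pair, c("I", "II"))

  ## zero copies
  non <- rbind(siteRow("c15", c(30, 0, 0, 0)),
               siteRow("c105", c(0, 30, 0, 0)),
               siteRow("c121", c(0, 0, 30, 0)),
               siteRow("c178", c(0, 0, 0, 30)))
  g <- callA3HDiplotype(non)
  expect_false(g$carrier_status)
  expect_equal(g$haplotype_pair, c("II", "II"))
})

test_that("low coverage and contradictory patterns yield unknown, not crashes", {
  low <- rbind(siteRow("c15", c(3, 0, 0, 0), coverage = 3),
               siteRow("c105", c(0, 0, 3, 0), coverage = 3),
               siteRow("c121", c(3, 0, 0, 0), coverage = 3),
               siteRow("c178", c(3, 0, 0, 0), coverage = 3))
  g <- callA3HDiplotype(low, min_coverage = 8)
  expect_equal(g$haplotype_pair, c("unknown", "unknown"))
  expect_true(is.na(g$carrier_status))

  ## genotype pattern matching no haplotype pair: hom T at codon 105
  contra <- rbind(siteRow("c15", c(30, 0, 0, 0)),
                  siteRow("c105", c(0, 0, 0, 30)),
                  siteRow("c121", c(30, 0, 0, 0)),
                  siteRow("c178", c(30, 0, 0, 0)))
  g <- callA3HDiplotype(contra)
  expect_equal(g$haplotype_pair, c("unknown", "unknown"))
  expect_false(g$carrier_status)  # zero G105 copies were called
})

test_that("diplotype calling recovers planted truth", {
  table <- a3hHaplotypeTable()
  haps <- unique(table$haplotype)
  pairs <- list()
  for (i in seq_along(haps)) for (j in i:length(haps))
    pairs[[length(pairs) + 1L]] <- c(haps[i], haps[j])
  ## noise-free calls at ample depth recover carrier status and G105 copies
  ## for every diplotype, and the pair itself up to table ambiguity
  for (p in pairs) {
    sc <- simulateSiteCalls(p, depth = 30, error_rate = 0,
                            rng_seed = 99, sample_id = "x")
    g <- callA3HDiplotype(sc)
    expect_equal(g$g105_copies, sum(p == "I"))
    if (!g$ambiguous) expect_equal(g$haplotype_pair, sort(p))
  }
})

test_that("allele frequency estimation counts haplotypes per population", {
  h <- matrix(c(rep(1, 8), rep(0, 12)), ncol = 1)
  panel <- HaplotypePanel(h, snpId = "rs1", position = 1L, chrom = "chr22",
                          sampleId = paste0("s", 1:10))
  fr <- alleleFrequencies(panel, "rs1")
  expect_equal(unname(fr$by_population[["ALL"]]), 0.4)
  expect_equal(fr$overall, 0.4)

  panel0 <- HaplotypePanel(matrix(0L, 20, 1), snpId = "rs1", position = 1L,
                           chrom = "chr22", sampleId = paste0("s", 1:10))
  expect_equal(alleleFrequencies(panel0, "rs1")$overall, 0)

  h2 <- matrix(c(rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 2),
                 rep(c(1, 1, 1, 1, 1, 1, 1, 0, 0, 0), 2)), ncol = 1)
  panel2 <- HaplotypePanel(h2, snpId = "rs1", position = 1L, chrom = "chr22",
                           sampleId = paste0("s", 1:20),
                           population = rep(c("A", "B"), each = 10))
  fr2 <- alleleFrequencies(panel2, "rs1")
  expect_equal(unname(fr2$by_population[["A"]]), 0.1)
  expect_equal(unname(fr2$by_population[["B"]]), 0.7)
  expect_equal(fr2$overall, 0.4)  # equal sample counts: pooled mean

  expect_error(alleleFrequencies(panel, "nope"), "unknown SNP")
})

test_that("population correlation behaves at the boundaries and under the null", {
  dec <- populationCorrelation(1:8, 8:1)
  expect_equal(dec$rho, -1)
  same <- populationCorrelation(c(1, 3, 2, 5), c(1, 3, 2, 5))
  expect_equal(same$rho, 1)
  cst <- populationCorrelation(rep(0.5, 5), 1:5)
  expect_true(is.na(cst$rho))
  expect_match(cst$reason, "constant")
  withr::with_seed(7, {
    x <- runif(1000); y <- runif(1000)
    null <- populationCorrelation(x, y)
    expect_lt(abs(null$rho), 0.08)
  })
})
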