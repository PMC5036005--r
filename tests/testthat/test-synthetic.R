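test_that("simulated references respect length, composition and seed", {
  expect_error(simulateReference(2), "length")
  one <- simulateReference(3, rng_seed = 1)
  expect_equal(length(one), 3L)
  gcOnly <- as.character(simulateReference(200, gc_fraction = 1, rng_seed = 2))
  expect_true(all(strsplit(gcOnly, "")[[1]] %in% c("G", "C")))
  big <- as.character(simulateReference(1e5, gc_fraction = 0.5, rng_seed = 3))
  gc <- mean(strsplit(big, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 1e5))
  expect_identical(as.character(simulateReference(500, 0.4, rng_seed = 9)),
                   as.character(simulateReference(500, 0.4, rng_seed = 9)))
})

test_that("planted mutations sit in their process motifs", {
  ref <- simulateReference(20000, 0.5, rng_seed = 4)
  cfg <- cohortConfig(
    n_patients = 4, muts_per_patient = 60,
    signature_weights = list(
      early_clonal = c(apobec = 0, smoking = 0, ageing = 1, other = 0),
      late_clonal  = c(apobec = 0, smoking = 0, ageing = 1, other = 0),
      subclonal    = c(apobec = 0, smoking = 0, ageing = 1, other = 0)),
    rng_seed = 5)
  co <- simulateCohort(cfg, ref)
  s <- as.character(ref)
  ## every ageing event lies in a CG dinucleotide on the pyrimidine strand
  fwd <- co$mutations$ref == "C"
  expect_true(all(substring(s, co$mutations$pos[fwd] + 1,
                            co$mutations$pos[fwd] + 1) == "G"))
  expect_true(all(substring(s, co$mutations$pos[!fwd] - 1,
                            co$mutations$pos[!fwd] - 1) == "C"))
  expect_true(all(co$truth$process == "ageing"))
})

test_that("APOBEC events require TCW sites in the reference", {
  noTcw <- c(chr1 = paste(rep("C", 200), collapse = ""))
  cfg <- cohortConfig(n_patients = 1, muts_per_patient = 5, rng_seed = 1)
  expect_error(simulateCohort(cfg, noTcw), "TCW")
})

test_that("read counts follow the purity/copy-number allele-fraction algebra", {
  ref <- simulateReference(50000, 0.5, rng_seed = 6)
  cfg <- cohortConfig(
    n_patients = 1, muts_per_patient = 200,
    timing_fractions = c(early_clonal = 0, late_clonal = 1, subclonal = 0),
    purity_range = c(1, 1), depth = 10000L,
    cn_probs = c(`1` = 0, `2` = 1, `3` = 0), rng_seed = 7)
  co <- simulateCohort(cfg, ref)
  ## m = 1, CN = 2, purity 1: expected AF is 0.5 for every mutation
  expect_true(all(co$truth$expected_af == 0.5))
  af <- co$mutations$alt_count /
        (co$mutations$alt_count + co$mutations$ref_count)
  n <- nrow(co$mutations) * 10000
  expect_lt(abs(mean(af) - 0.5), 3 * sqrt(0.25 / n))
})

test_that("cohort generation is deterministic and truth-conserving", {
  ref <- simulateReference(30000, 0.45, rng_seed = 8)
  cfg <- cohortConfig(n_patients = 5, muts_per_patient = 40, rng_seed = 11)
  a <- simulateCohort(cfg, ref)
  b <- simulateCohort(cfg, ref)
  expect_identical(a, b)
  expect_equal(nrow(a$mutations), nrow(a$truth))
  expect_identical(a$mutations$pos, a$truth$pos)
})

test_that("planted process mixture matches the configured weights", {
  ref <- simulateReference(2e5, 0.45, rng_seed = 12)
  w <- c(apobec = 0.3, smoking = 0.25, ageing = 0.25, other = 0.2)
  cfg <- cohortConfig(n_patients = 100, muts_per_patient = 100,
                      signature_weights = list(early_clonal = w,
                                               late_clonal = w,
                                               subclonal = w),
                      rng_seed = 13)
  co <- simulateCohort(cfg, ref)
  expect_gt(nrow(co$truth), 9000)
  obs <- table(factor(co$truth$process, levels = names(w)))
  chi <- suppressWarnings(stats::chisq.test(obs, p = w))
  expect_gt(chi$p.value, 0.001)
})

test_that("haplotype panels honour block LD targets and independence", {
  expect_error(simulateHaplotypePanel(1, blocks = list()), "n_samples")
  expect_error(simulateHaplotypePanel(
    10, blocks = list(list(n_snps = 2, r2 = 1.4, maf = 0.5))), "r2")

  perfect <- simulateHaplotypePanel(
    100, blocks = list(list(n_snps = 4, r2 = 1, maf = 0.5)), rng_seed = 3)
  m <- ldMatrix(perfect)
  expect_equal(as.numeric(m), rep(1, 16))

  two <- simulateHaplotypePanel(
    5000, blocks = list(list(n_snps = 3, r2 = 1, maf = 0.5),
                        list(n_snps = 3, r2 = 1, maf = 0.5)), rng_seed = 4)
  m <- ldMatrix(two)
  cross <- m[1:3, 4:6]
  expect_lt(mean(cross), 0.01)
})

test_that("per-population allele frequencies match generating values", {
  pops <- rep(c("AFR", "EAS"), each = 1500)
  panel <- simulateHaplotypePanel(
    3000, blocks = list(list(n_snps = 1, r2 = 1,
                             maf = c(AFR = 0.05, EAS = 0.65))),
    populations = pops, rng_seed = 5)
  fr <- alleleFrequencies(panel, "b1_s1")$by_population
  expect_lt(abs(fr[["AFR"]] - 0.05), 3 * sqrt(0.05 * 0.95 / 3000))
  expect_lt(abs(fr[["EAS"]] - 0.65), 3 * sqrt(0.65 * 0.35 / 3000))
})

test_that("site-call summaries count reads faithfully", {
  sc <- simulateSiteCalls(c("I", "I"), depth = 30, error_rate = 0,
                          rng_seed = 1, sample_id = "s")
  c105 <- sc[sc$site == "c105", ]
  expect_equal(c105$G, 30L)
  expect_equal(c105$coverage, 30L)
  expect_true(all(rowSums(sc[, c("A", "C", "G", "T")]) == sc$coverage))

  empty <- simulateSiteCalls(c("I", "II"), depth = 0, rng_seed = 1)
  expect_true(all(empty$coverage == 0L))
  expect_true(all(empty$note == "no coverage"))

  expect_error(simulateSiteCalls(c("I", "II"), depth = 10, error_rate = 0.5),
               "error_rate")
})

test_that("amplicon simulation plants context-specific deaminations", {
  ref <- simulateReference(400, 0.5, rng_seed = 21)
  none <- simulateAmplicons(ref, rates = c(TC = 0, CC = 0, GC = 0, AC = 0),
                            n_sequences = 5, rng_seed = 1)
  expect_true(all(as.character(none$sequences) == as.character(ref)))
  expect_equal(sum(none$context_totals), 0L)

  ## many TC sites at rate 0.01: planted count within 3 binomial SDs
  tcRef <- paste(rep("TCA", 4000), collapse = "")
  am <- simulateAmplicons(tcRef, rates = c(TC = 0.01, CC = 0, GC = 0, AC = 0),
                          n_sequences = 1, rng_seed = 2)
  nTC <- 4000 - 1  # first C lacks a 5' base only if at pos 1; here pos 2 has T
  expect_lt(abs(sum(am$context_totals) - 0.01 * 4000),
            3 * sqrt(4000 * 0.01 * 0.99) + 1)
  expect_equal(unname(am$context_totals[c("CC", "GC", "AC")]), rep(0L, 3))
  expect_equal(nrow(am$truth), sum(am$context_totals))
})
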