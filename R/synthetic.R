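## Synthetic-cohort generator. Every analysis stage in the package can be
## exercised against data with a recoverable ground truth: per-patient
## mutation catalogs drawn from mixed mutational processes with a clonal
## architecture and binomial read counts, copy-number/purity tables, phased
## haplotype panels with block LD structure, per-site base-call summaries at
## haplotype-defining positions, and deaminated amplicon sequences.

#' Simulate a random reference sequence
#'
#' @param length sequence length (>= 3, so at least one trinucleotide exists).
#' @param gc_fraction target G+C fraction in [0, 1].
#' @param rng_seed integer seed; the same seed yields the identical sequence.
#' @return A \code{DNAString}.
#' @examples
#' simulateReference(30, gc_fraction = 0.5, rng_seed = 1)
#' @export
simulateReference <- function(length, gc_fraction = 0.41, rng_seed = 1L) {
  if (length < 3) stop("reference length must be >= 3 (no trinucleotide exists)")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction must lie in [0, 1]")
  p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
         G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  withSeed(rng_seed, {
    Biostrings::DNAString(paste(sample(DNA_BASES, length, replace = TRUE,
                                       prob = p), collapse = ""))
  })
}

#' Cohort simulation configuration
#'
#' Bundles the generating parameters for \code{\link{simulateCohort}}. The
#' defaults define the reference study conditions used throughout the test
#' suite: mixed APOBEC/smoking/ageing/background processes, a clonal
#' architecture with early-clonal mutations on all copies of their segment,
#' late-clonal single-copy mutations and subclonal mutations at
#' cancer-cell fractions in (0.1, 0.5), purity uniform on [0.6, 1] and a
#' constant sequencing depth of 120.
#'
#' @param n_patients number of patients.
#' @param muts_per_patient mean somatic mutation count per patient (Poisson).
#' @param timing_fractions named fractions (early_clonal, late_clonal,
#'   subclonal) summing to 1.
#' @param signature_weights list with one named weight vector
#'   (apobec, smoking, ageing, other; non-negative, summing to 1) per timing
#'   class.
#' @param purity_range range of the per-patient uniform purity draw, in (0,1].
#' @param depth constant per-mutation sequencing depth (>= 1).
#' @param n_segments copy-number segments per patient.
#' @param cn_probs named probabilities of total copy number 1/2/3 per segment.
#' @param subclonal_ccf_range range of the uniform subclonal cancer-cell
#'   fraction draw, within (0, 1).
#' @param apobec_ct_fraction fraction of APOBEC-process events that are C>T
#'   (the remainder are C>G), both restricted to TCW sites.
#' @param sample_prefix prefix for generated patient identifiers.
#' @param rng_seed integer seed.
#' @return A list of class \code{cohort_config}.
#' @export
cohortConfig <- function(n_patients = 60L,
                         muts_per_patient = 100,
                         timing_fractions = c(early_clonal = 0.3,
                                              late_clonal = 0.4,
                                              subclonal = 0.3),
                         signature_weights = list(
                           early_clonal = c(apobec = 0.3, smoking = 0.25,
                                            ageing = 0.25, other = 0.2),
                           late_clonal  = c(apobec = 0.3, smoking = 0.25,
                                            ageing = 0.25, other = 0.2),
                           subclonal    = c(apobec = 0.3, smoking = 0.25,
                                            ageing = 0.25, other = 0.2)),
                         purity_range = c(0.6, 1),
                         depth = 120L,
                         n_segments = 12L,
                         cn_probs = c(`1` = 0.05, `2` = 0.75, `3` = 0.2),
                         subclonal_ccf_range = c(0.1, 0.5),
                         apobec_ct_fraction = 0.65,
                         sample_prefix = "P",
                         rng_seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              muts_per_patient = muts_per_patient,
              timing_fractions = timing_fractions,
              signature_weights = signature_weights,
              purity_range = purity_range, depth = as.integer(depth),
              n_segments = as.integer(n_segments), cn_probs = cn_probs,
              subclonal_ccf_range = subclonal_ccf_range,
              apobec_ct_fraction = apobec_ct_fraction,
              sample_prefix = sample_prefix, rng_seed = as.integer(rng_seed))
  if (abs(sum(timing_fractions) - 1) > 1e-9)
    stop("timing_fractions must sum to 1")
  for (w in signature_weights) {
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      stop("signature weights must be non-negative and sum to 1")
    if (!all(c("apobec", "smoking", "ageing", "other") %in% names(w)))
      stop("signature weights must name apobec, smoking, ageing, other")
  }
  if (any(subclonal_ccf_range <= 0) || any(subclonal_ccf_range >= 1))
    stop("subclonal cancer-cell fractions must lie in (0, 1)")
  if (cfg$depth < 1) stop("depth must be >= 1")
  class(cfg) <- "cohort_config"
  cfg
}

## per-process candidate mutation sites on a reference (both strands; the
## "reverse" entries are purine-strand positions whose pyrimidine-strand
## context matches the process motif)
processSitePools <- function(s) {
  L <- nchar(s)
  cen <- substring(s, 2:(L - 1), 2:(L - 1))
  five <- substring(s, 1:(L - 2), 1:(L - 2))
  three <- substring(s, 3:L, 3:L)
  pos <- 2:(L - 1)
  fwdC <- cen == "C"
  revG <- cen == "G"
  list(
    apobec = list(
      fwd = pos[fwdC & five == "T" & three %in% c("A", "T")],
      rev = pos[revG & three == "A" & five %in% c("A", "T")]),
    smoking = list(fwd = pos[fwdC], rev = pos[revG]),
    ageing  = list(fwd = pos[fwdC & three == "G"],
                   rev = pos[revG & five == "C"]),
    other   = list(fwd = pos, rev = integer())
  )
}

## alt alleles for a vector of planted events (pyrimidine-strand logic,
## complemented for purine-strand sites)
plantedAlts <- function(process, strand, refBase, ctFraction) {
  k <- length(process)
  pyr <- character(k)
  isApo <- process == "apobec"
  pyr[isApo] <- ifelse(runif(sum(isApo)) < ctFraction, "T", "G")
  pyr[process == "smoking"] <- "A"
  pyr[process == "ageing"] <- "T"
  oth <- which(process == "other")
  if (length(oth)) {
    pyrRef <- ifelse(strand[oth] == "fwd", refBase[oth],
                     unname(COMP[refBase[oth]]))
    pyr[oth] <- vapply(pyrRef, function(b)
      sample(setdiff(DNA_BASES, b), 1), character(1), USE.NAMES = FALSE)
  }
  ifelse(strand == "fwd", pyr, unname(COMP[pyr]))
}

#' Simulate a tumour cohort with known ground truth
#'
#' Generates per-patient somatic mutation catalogs, copy-number segments and
#' purities under the clonal architecture and mutational-process mixture of a
#' \code{\link{cohortConfig}}. Each mutation's expected variant allele
#' fraction follows \code{ccf * m * purity / (CN * purity + 2 * (1 - purity))}
#' (m = multiplicity, CN = total copy number) and its alternate read count is
#' binomial at that fraction. APOBEC-process events are planted only at TCW
#' sites (pyrimidine strand) as C>T or C>G, smoking events as C>A at any
#' cytosine, ageing events as C>T at CG sites.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @param reference reference sequence (\code{DNAString} or character).
#' @param chrom chromosome name recorded for all simulated records.
#' @return A list with data.frames \code{mutations}, \code{segments},
#'   \code{purity} and \code{truth} (per-mutation process, timing class,
#'   multiplicity and cancer-cell fraction, row-aligned with
#'   \code{mutations}).
#' @export
simulateCohort <- function(config, reference, chrom = "chr1") {
  stopifnot(inherits(config, "cohort_config"))
  s <- unname(refAsCharacter(reference)[1])
  L <- nchar(s)
  pools <- processSitePools(s)
  wantsApobec <- any(vapply(config$signature_weights,
                            function(w) w[["apobec"]] > 0, logical(1)))
  if (wantsApobec &&
      length(pools$apobec$fwd) + length(pools$apobec$rev) == 0L)
    stop("APOBEC mutations requested but the reference contains no TCW site")
  classes <- names(config$timing_fractions)
  withSeed(config$rng_seed, {
    ids <- sprintf("%s%03d", config$sample_prefix, seq_len(config$n_patients))
    purity <- data.frame(sample = ids,
                         purity = runif(config$n_patients,
                                        config$purity_range[1],
                                        config$purity_range[2]),
                         population = NA_character_)
    mutL <- vector("list", config$n_patients)
    truthL <- vector("list", config$n_patients)
    segL <- vector("list", config$n_patients)
    for (i in seq_len(config$n_patients)) {
      ## copy-number segmentation of the reference
      k <- config$n_segments
      bks <- sort(sample(2:(L - 1), k - 1))
      starts <- c(1L, bks)
      ends <- c(bks - 1L, L)
      cn <- sample(as.integer(names(config$cn_probs)), k, replace = TRUE,
                   prob = config$cn_probs)
      if (all(cn < 2)) cn[sample.int(k, 1)] <- 2L
      segL[[i]] <- data.frame(sample = ids[i], chrom = chrom, start = starts,
                              end = ends, num_probes = pmax(1L, (ends - starts) %/% 50L),
                              segment_mean = log2(cn / 2), total_cn = cn)
      cnAt <- function(p) cn[findInterval(p, starts)]
      n_i <- rpois(1, config$muts_per_patient)
      if (n_i == 0) next
      cls <- sample(classes, n_i, replace = TRUE,
                    prob = config$timing_fractions)
      proc <- character(n_i)
      for (cl in classes) {
        sel <- cls == cl
        if (any(sel))
          proc[sel] <- sample(names(config$signature_weights[[cl]]), sum(sel),
                              replace = TRUE,
                              prob = config$signature_weights[[cl]])
      }
      ## draw one site per event, without replacement within the patient;
      ## early-clonal events are restricted to CN >= 2 segments so their
      ## multiplicity (= all copies) is well defined
      usedMask <- logical(L)
      pos <- integer(n_i); strand <- character(n_i)
      early <- cls == "early_clonal"
      for (p in unique(proc)) for (e in unique(early[proc == p])) {
        grp <- which(proc == p & early == e)
        pool <- pools[[p]]
        cand <- c(pool$fwd, pool$rev)
        cstr <- rep(c("fwd", "rev"), c(length(pool$fwd), length(pool$rev)))
        keep <- !usedMask[cand]
        if (e) keep <- keep & cnAt(cand) >= 2L
        cand <- cand[keep]; cstr <- cstr[keep]
        if (length(cand) < length(grp))
          stop("reference exhausted: no unused site available for process '",
               p, "'")
        pick <- sample.int(length(cand), length(grp))
        pos[grp] <- cand[pick]; strand[grp] <- cstr[pick]
        usedMask[cand[pick]] <- TRUE
      }
      refBase <- substring(s, pos, pos)
      alt <- plantedAlts(proc, strand, refBase, config$apobec_ct_fraction)
      cnv <- cnAt(pos)
      m <- ifelse(cls == "early_clonal", cnv, 1L)
      ccf <- ifelse(cls == "subclonal",
                    runif(n_i, config$subclonal_ccf_range[1],
                          config$subclonal_ccf_range[2]), 1)
      rho <- purity$purity[i]
      eaf <- ccf * m * rho / (cnv * rho + 2 * (1 - rho))
      altCt <- rbinom(n_i, config$depth, eaf)
      mutL[[i]] <- data.frame(sample = ids[i], chrom = chrom, pos = pos,
                              ref = refBase, alt = alt,
                              ref_count = config$depth - altCt,
                              alt_count = altCt)
      truthL[[i]] <- data.frame(sample = ids[i], chrom = chrom, pos = pos,
                                process = proc, timing_class = cls,
                                multiplicity = m, cancer_cell_fraction = ccf,
                                expected_af = eaf, strand = strand)
    }
    mutations <- do.call(rbind, mutL)
    truth <- do.call(rbind, truthL)
    rownames(mutations) <- rownames(truth) <- NULL
    validateMutations(mutations)
    stopifnot(nrow(mutations) == nrow(truth))
    list(mutations = mutations, segments = do.call(rbind, segL),
         purity = purity, truth = truth)
  })
}

#' Simulate a phased haplotype panel with block LD structure
#'
#' SNPs are organised into independent blocks. Within a block every SNP is a
#' noisy copy of an unobserved block founder allele: a SNP copies the founder
#' with probability \code{1 - f} and otherwise draws a fresh allele at the
#' founder frequency, with \code{f} set so that the expected pairwise
#' r-squared between any two SNPs of the block equals the block target
#' (\code{r2 = (1-f)^4}). Marginal allele frequencies are preserved exactly.
#' Blocks are generated independently, so cross-block LD is null.
#'
#' @param n_samples number of diploid samples (>= 2); the panel holds
#'   \code{2 * n_samples} haplotypes.
#' @param blocks list of block specifications, each a list with \code{n_snps},
#'   \code{r2} (target pairwise r-squared in [0, 1]) and \code{maf} (founder
#'   alternate-allele frequency; either a scalar or a named per-population
#'   vector).
#' @param populations optional per-sample population labels (length
#'   \code{n_samples}).
#' @param chrom chromosome name recorded for the SNPs.
#' @param rng_seed integer seed.
#' @return A \linkS4class{HaplotypePanel}.
#' @examples
#' simulateHaplotypePanel(50, blocks = list(list(n_snps = 3, r2 = 0.8,
#'                                               maf = 0.3)), rng_seed = 7)
#' @export
simulateHaplotypePanel <- function(n_samples, blocks,
                                   populations = NULL, chrom = "chr22",
                                   rng_seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2")
  if (is.null(populations)) populations <- rep(NA_character_, n_samples)
  if (length(populations) != n_samples)
    stop("populations must have one label per sample")
  for (b in blocks)
    if (b$r2 < 0 || b$r2 > 1) stop("target r2 must lie in [0, 1]")
  nh <- 2L * n_samples
  popPerHap <- rep(populations, each = 2L)
  withSeed(rng_seed, {
    cols <- list(); ids <- character(); poss <- integer()
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      p <- b$maf
      pHap <- if (length(p) > 1L) {
        if (is.null(names(p))) stop("per-population maf must be named")
        unname(p[popPerHap])
      } else rep(p, nh)
      if (anyNA(pHap)) stop("maf missing for some population label")
      f <- 1 - b$r2^(1 / 4)
      founder <- rbinom(nh, 1L, pHap)
      for (j in seq_len(b$n_snps)) {
        copy <- runif(nh) < (1 - f)
        fresh <- rbinom(nh, 1L, pHap)
        cols[[length(cols) + 1L]] <- ifelse(copy, founder, fresh)
        ids <- c(ids, sprintf("b%d_s%d", bi, j))
        poss <- c(poss, 100000L * bi + 10L * j)
      }
    }
    HaplotypePanel(do.call(cbind, cols), snpId = ids, position = poss,
                   chrom = rep(chrom, length(ids)),
                   sampleId = sprintf("S%05d", seq_len(n_samples)),
                   population = populations)
  })
}

#' Simulate per-site base-call summaries for an A3H diplotype
#'
#' Emulates extraction of base calls, qualities and coverage from exome
#' alignments at the haplotype-defining APOBEC3H sites: each read draws one
#' of the two haplotype alleles with equal probability and is then corrupted
#' to a uniformly random other base with probability \code{error_rate}.
#'
#' @param diplotype character vector of two haplotype labels (e.g.
#'   \code{c("I", "II")}) drawn from the haplotype table.
#' @param depth read coverage per site; \code{0} yields an empty summary
#'   flagged "no coverage".
#' @param error_rate per-read error probability in [0, 0.25].
#' @param rng_seed integer seed.
#' @param haplotype_table defining-site allele table
#'   (\code{\link{a3hHaplotypeTable}}).
#' @param sample_id sample identifier recorded in the output.
#' @return data.frame with one row per defining site: sample, site, base
#'   counts A/C/G/T, mean_quality, coverage, note.
#' @export
simulateSiteCalls <- function(diplotype, depth, error_rate = 0,
                              rng_seed = 1L,
                              haplotype_table = a3hHaplotypeTable(),
                              sample_id = "sample") {
  if (length(diplotype) != 2L) stop("diplotype must name exactly 2 haplotypes")
  if (error_rate < 0 || error_rate > 0.25)
    stop("error_rate must lie in [0, 0.25]")
  sites <- unique(haplotype_table$site)
  withSeed(rng_seed, {
    rows <- lapply(sites, function(st) {
      al <- vapply(diplotype, function(hp)
        haplotype_table$base[haplotype_table$site == st &
                             haplotype_table$haplotype == hp], character(1))
      if (any(is.na(al)) || length(al) != 2L)
        stop("haplotype table lacks an allele for a requested haplotype")
      counts <- setNames(integer(4), DNA_BASES)
      if (depth > 0) {
        reads <- al[sample.int(2L, depth, replace = TRUE)]
        err <- runif(depth) < error_rate
        if (any(err))
          reads[err] <- vapply(reads[err], function(b)
            sample(setdiff(DNA_BASES, b), 1), character(1))
        tab <- table(factor(reads, levels = DNA_BASES))
        counts[] <- as.integer(tab)
      }
      data.frame(sample = sample_id, site = st,
                 A = counts[["A"]], C = counts[["C"]], G = counts[["G"]],
                 T = counts[["T"]],
                 mean_quality = if (depth > 0) round(runif(1, 32, 38), 1) else 0,
                 coverage = as.integer(depth),
                 note = if (depth > 0) "" else "no coverage")
    })
    do.call(rbind, rows)
  })
}

#' Simulate APOBEC-deaminated amplicon sequences
#'
#' Plants C>T deamination events on copies of a reference amplicon with
#' per-context probabilities keyed by the 5' dinucleotide of each cytosine
#' (TC/CC/GC/AC). The planted events are returned as ground truth for the
#' counting stage.
#'
#' @param reference amplicon reference (\code{DNAString} or character).
#' @param rates named per-site deamination probabilities for contexts
#'   TC, CC, GC, AC.
#' @param n_sequences number of amplicon copies.
#' @param rng_seed integer seed.
#' @return list with \code{sequences} (\code{DNAStringSet}), \code{truth}
#'   (data.frame of planted events: sequence, pos, context) and
#'   \code{context_totals} (named planted counts per context).
#' @export
simulateAmplicons <- function(reference,
                              rates = c(TC = 0.02, CC = 0.005, GC = 0.002,
                                        AC = 0.002),
                              n_sequences = 32L, rng_seed = 1L) {
  s <- unname(refAsCharacter(reference)[1])
  L <- nchar(s)
  if (!all(c("TC", "CC", "GC", "AC") %in% names(rates)))
    stop("rates must be keyed by 5' dinucleotide: TC, CC, GC, AC")
  if (any(rates < 0) || any(rates > 1)) stop("rates must be probabilities")
  cpos <- which(strsplit(s, "")[[1]] == "C")
  cpos <- cpos[cpos >= 2L]  # a 5' context base must exist
  ctx <- paste0(substring(s, cpos - 1L, cpos - 1L), "C")
  withSeed(rng_seed, {
    seqs <- character(n_sequences)
    ev <- list()
    for (i in seq_len(n_sequences)) {
      hit <- runif(length(cpos)) < rates[ctx]
      x <- strsplit(s, "")[[1]]
      if (any(hit)) {
        x[cpos[hit]] <- "T"
        ev[[length(ev) + 1L]] <- data.frame(sequence = sprintf("amp%03d", i),
                                            pos = cpos[hit],
                                            context = ctx[hit])
      }
      seqs[i] <- paste(x, collapse = "")
    }
    truth <- if (length(ev)) do.call(rbind, ev)
             else data.frame(sequence = character(), pos = integer(),
                             context = character())
    totals <- setNames(integer(4), c("TC", "CC", "GC", "AC"))
    if (nrow(truth)) {
      tab <- table(factor(truth$context, levels = names(totals)))
      totals[] <- as.integer(tab)
    }
    list(sequences = setNames(Biostrings::DNAStringSet(seqs),
                              sprintf("amp%03d", seq_len(n_sequences))),
         truth = truth, context_totals = totals)
  })
}

#' Simulate a genotype-association study cohort
#'
#' Builds a two-arm cohort for the end-to-end pipeline: carrier patients
#' (at least one copy of the A3H-I / Gly105 allele) receive an additive
#' increment to their early-clonal APOBEC signature weight, non-carriers the
#' base mixture. Per-patient base-call summaries at the haplotype-defining
#' sites are simulated so genotypes must be recovered, not read off.
#'
#' @param n_carrier,n_noncarrier arm sizes.
#' @param carrier_effect additive increment to the carrier arm's early-clonal
#'   APOBEC weight (other early-clonal weights are rescaled to keep the sum
#'   at 1); \code{0} gives a null study.
#' @param reference reference sequence shared by both arms.
#' @param base_config \code{\link{cohortConfig}} for the non-carrier arm.
#' @param site_depth,site_error_rate base-call simulation parameters.
#' @param rng_seed integer seed.
#' @return list with \code{mutations}, \code{segments}, \code{purity},
#'   \code{site_calls}, \code{truth} and \code{carrier_truth} (data.frame of
#'   sample, diplotype, is_carrier).
#' @export
simulateAssociationStudy <- function(n_carrier = 60L, n_noncarrier = 60L,
                                     carrier_effect = 0.15,
                                     reference,
                                     base_config = cohortConfig(),
                                     site_depth = 40L,
                                     site_error_rate = 0.005,
                                     rng_seed = 1L) {
  wEarly <- base_config$signature_weights$early_clonal
  wCar <- wEarly
  wCar[["apobec"]] <- wEarly[["apobec"]] + carrier_effect
  if (wCar[["apobec"]] > 1) stop("carrier_effect pushes the APOBEC weight above 1")
  others <- setdiff(names(wEarly), "apobec")
  wCar[others] <- wEarly[others] * (1 - wCar[["apobec"]]) / (1 - wEarly[["apobec"]])
  carCfg <- base_config
  carCfg$signature_weights$early_clonal <- wCar
  carCfg$n_patients <- as.integer(n_carrier)
  carCfg$sample_prefix <- "CAR"
  carCfg$rng_seed <- mixSeed(rng_seed, "carrier-arm")
  nonCfg <- base_config
  nonCfg$n_patients <- as.integer(n_noncarrier)
  nonCfg$sample_prefix <- "NON"
  nonCfg$rng_seed <- mixSeed(rng_seed, "noncarrier-arm")
  car <- simulateCohort(carCfg, reference)
  non <- simulateCohort(nonCfg, reference)
  carDips <- list(c("I", "I"), c("I", "II"))
  nonDips <- list(c("II", "II"), c("II", "V"), c("III", "IV"))
  allIds <- c(car$purity$sample, non$purity$sample)
  dips <- withSeed(mixSeed(rng_seed, "diplotypes"), {
    c(lapply(seq_len(n_carrier), function(i)
        carDips[[sample.int(length(carDips), 1)]]),
      lapply(seq_len(n_noncarrier), function(i)
        nonDips[[sample.int(length(nonDips), 1)]]))
  })
  siteCalls <- do.call(rbind, lapply(seq_along(allIds), function(i)
    simulateSiteCalls(dips[[i]], depth = site_depth,
                      error_rate = site_error_rate,
                      rng_seed = mixSeed(rng_seed, "sites", allIds[i]),
                      sample_id = allIds[i])))
  list(mutations = rbind(car$mutations, non$mutations),
       segments = rbind(car$segments, non$segments),
       purity = rbind(car$purity, non$purity),
       site_calls = siteCalls,
       truth = rbind(car$truth, non$truth),
       carrier_truth = data.frame(
         sample = allIds,
         diplotype = vapply(dips, paste, character(1), collapse = "/"),
         is_carrier = vapply(dips, function(d) "I" %in% d, logical(1))))
}
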