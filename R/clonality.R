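## Clonality timing: purity/copy-number-adjusted mutation multiplicity,
## half-coverage bootstrap confidence intervals, and the early/late/subclonal
## classification rules.

#' Purity- and copy-number-adjusted mutation multiplicity
#'
#' Converts a variant allele fraction into the estimated number of tumour
#' chromosomal copies carrying the mutation:
#' \deqn{\hat m = VAF (\rho CN + 2(1-\rho)) / \rho}
#' where \eqn{\rho} is tumour purity and CN the total copy number at the
#' locus. At purity 1 this reproduces the diploid anchor (VAF 0.50 is 1 of 2
#' copies) and the amplified anchor (VAF 0.667 is 2 of 3 copies). The
#' adjusted allele fraction is \eqn{\hat m / CN}.
#'
#' @param vaf variant allele fraction in [0, 1].
#' @param purity tumour purity in (0, 1].
#' @param total_cn total copy number (integer >= 1).
#' @return list with \code{multiplicity} and \code{adjusted_af}; both
#'   vectorized over the inputs.
#' @examples
#' adjustedMultiplicity(0.667, purity = 1, total_cn = 3)$multiplicity  # 2.001
#' adjustedMultiplicity(0.5, purity = 1, total_cn = 2)$multiplicity   # 1
#' @export
adjustedMultiplicity <- function(vaf, purity, total_cn) {
  if (any(purity <= 0)) stop("purity must be > 0")
  if (any(purity > 1)) stop("purity must be <= 1")
  if (any(vaf < 0 | vaf > 1)) stop("vaf must lie in [0, 1]")
  if (any(total_cn < 1)) stop("total_cn must be >= 1")
  m <- vaf * (purity * total_cn + 2 * (1 - purity)) / purity
  list(multiplicity = m, adjusted_af = m / total_cn)
}

#' Bootstrap confidence interval for mutation multiplicity
#'
#' Resamples the reads supporting the reference and alternate alleles at
#' half of the observed coverage: each of \code{n_boot} replicates draws an
#' alternate count from Binomial(ceiling(coverage/2), alt/coverage), maps
#' the replicate VAF through \code{\link{adjustedMultiplicity}}, and the CI
#' is the percentile interval of the replicate multiplicities.
#'
#' @param ref_count,alt_count observed supporting reads (sum >= 2).
#' @param purity,total_cn as in \code{\link{adjustedMultiplicity}}.
#' @param n_boot number of bootstrap replicates (default 10,000).
#' @param level confidence level (default 0.95).
#' @param rng_seed integer seed; the interval is deterministic given the
#'   seed.
#' @return list with \code{ci_lower}, \code{ci_upper} (copy scale),
#'   \code{multiplicity_hat} (point estimate from the observed VAF),
#'   \code{half_coverage}, \code{n_boot}.
#' @export
bootstrapMultiplicityCI <- function(ref_count, alt_count, purity, total_cn,
                                    n_boot = 10000L, level = 0.95,
                                    rng_seed = 1L) {
  withSeed(rng_seed,
           bootCICore(ref_count, alt_count, purity, total_cn, n_boot, level))
}

## bootstrap core; assumes the RNG has already been seeded by the caller
bootCICore <- function(ref_count, alt_count, purity, total_cn, n_boot,
                       level) {
  cov <- ref_count + alt_count
  if (cov < 2) stop("coverage < 2: multiplicity is unevaluable")
  h <- as.integer(ceiling(cov / 2))
  p <- alt_count / cov
  mhat <- adjustedMultiplicity(p, purity, total_cn)$multiplicity
  reps <- rbinom(n_boot, h, p) / h
  mrep <- adjustedMultiplicity(reps, purity, total_cn)$multiplicity
  alpha <- (1 - level) / 2
  ci <- unname(quantile(mrep, c(alpha, 1 - alpha)))
  list(ci_lower = ci[1], ci_upper = ci[2], multiplicity_hat = mhat,
       half_coverage = h, n_boot = as.integer(n_boot))
}

#' Classify mutation timing from a copy-scale confidence interval
#'
#' Timing classes relative to one mutated copy: early-clonal when the lower
#' 95% bound exceeds 1 copy in diploid regions, or reaches 2 copies in
#' amplified (CN >= 3) regions; subclonal when the upper bound falls below
#' 1 copy; late-clonal otherwise (the interval overlaps 1 copy, or sits
#' between 1 and the amplified-clonal threshold). Mutations in CN < 2
#' segments are unevaluable by default; set \code{allow_low_cn} to apply the
#' interval-versus-one-copy rules there as well.
#'
#' @param ci_lower,ci_upper confidence bounds on the copy scale.
#' @param total_cn total copy number at the locus.
#' @param allow_low_cn apply the diploid rules in CN < 2 segments.
#' @return one of "early_clonal", "late_clonal", "subclonal", "unevaluable";
#'   vectorized over the inputs.
#' @examples
#' classifyClonality(1.22, 1.60, 2)  # early_clonal
#' classifyClonality(0.80, 1.20, 2)  # late_clonal
#' classifyClonality(0.30, 0.90, 2)  # subclonal
#' @export
classifyClonality <- function(ci_lower, ci_upper, total_cn,
                              allow_low_cn = FALSE) {
  n <- max(length(ci_lower), length(ci_upper), length(total_cn))
  ci_lower <- rep_len(ci_lower, n); ci_upper <- rep_len(ci_upper, n)
  total_cn <- rep_len(total_cn, n)
  early <- ifelse(total_cn >= 3, ci_lower >= 2, ci_lower > 1)
  out <- ifelse(early, "early_clonal",
                ifelse(ci_upper < 1, "subclonal", "late_clonal"))
  if (!allow_low_cn) out[total_cn < 2] <- "unevaluable"
  out
}

#' Time every mutation of a cohort
#'
#' Joins mutations to their copy-number segment and sample purity, computes
#' the half-coverage bootstrap CI of the adjusted multiplicity, and
#' classifies each mutation as early-clonal, late-clonal or subclonal.
#' Mutations without read counts, an overlapping segment, a purity value, or
#' with coverage below 2 are returned as unevaluable with a reason. The
#' bootstrap RNG stream of each mutation is derived from the global seed and
#' the mutation's (sample, chrom, pos), so results do not depend on record
#' order.
#'
#' @param mutations mutation data.frame with ref_count/alt_count columns.
#' @param segments segment data.frame with a \code{total_cn} column.
#' @param purity purity data.frame (sample, purity).
#' @param n_boot,level bootstrap parameters (defaults 10,000 and 0.95).
#' @param allow_low_cn see \code{\link{classifyClonality}}.
#' @param rng_seed global integer seed.
#' @return \code{S4Vectors::DataFrame} with one row per mutation: sample,
#'   chrom, pos, vaf, total_cn, purity, multiplicity_hat, ci_lower,
#'   ci_upper, adjusted_af, timing_class, reason. A \code{class_counts}
#'   metadata column summary is attached via \code{metadata()}.
#' @export
timingPipeline <- function(mutations, segments, purity,
                           n_boot = 10000L, level = 0.95,
                           allow_low_cn = FALSE, rng_seed = 1L) {
  validateMutations(mutations)
  if (is.null(mutations$ref_count))
    mutations$ref_count <- mutations$alt_count <- NA_integer_
  key <- paste(mutations$sample, mutations$chrom, mutations$pos)
  if (anyDuplicated(key))
    stop("duplicate mutation record(s): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  if (is.null(segments$total_cn))
    stop("segments must carry a total_cn column for timing")
  mutGr <- GenomicRanges::GRanges(
    paste(mutations$sample, mutations$chrom, sep = "\r"),
    IRanges::IRanges(mutations$pos, mutations$pos))
  segGr <- GenomicRanges::GRanges(
    paste(segments$sample, segments$chrom, sep = "\r"),
    IRanges::IRanges(segments$start, segments$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(mutGr, segGr))
  segIdx <- rep(NA_integer_, nrow(mutations))
  segIdx[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  rho <- purity$purity[match(mutations$sample, purity$sample)]
  cn <- segments$total_cn[segIdx]
  n <- nrow(mutations)
  out <- data.frame(sample = mutations$sample, chrom = mutations$chrom,
                    pos = mutations$pos, vaf = rep(NA_real_, n),
                    total_cn = cn, purity = rho,
                    multiplicity_hat = rep(NA_real_, n),
                    ci_lower = rep(NA_real_, n), ci_upper = rep(NA_real_, n),
                    adjusted_af = rep(NA_real_, n),
                    timing_class = rep("unevaluable", n),
                    reason = rep("", n))
  cov <- mutations$ref_count + mutations$alt_count
  out$vaf <- ifelse(cov > 0, mutations$alt_count / cov, NA_real_)
  ## one RNG save/restore around the whole loop; each mutation still gets
  ## its own substream via set.seed on its derived seed
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) oldSeed <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", oldSeed, envir = globalenv()))
  for (i in seq_len(n)) {
    if (is.na(mutations$ref_count[i]) || is.na(mutations$alt_count[i])) {
      out$reason[i] <- "no read counts"; next
    }
    if (is.na(segIdx[i])) { out$reason[i] <- "no segment"; next }
    if (is.na(rho[i])) { out$reason[i] <- "no purity"; next }
    if (cov[i] < 2) { out$reason[i] <- "coverage < 2"; next }
    set.seed(mixSeed(rng_seed, mutations$sample[i], mutations$chrom[i],
                     mutations$pos[i]))
    ci <- bootCICore(mutations$ref_count[i], mutations$alt_count[i], rho[i],
                     cn[i], n_boot = n_boot, level = level)
    out$multiplicity_hat[i] <- ci$multiplicity_hat
    out$ci_lower[i] <- ci$ci_lower
    out$ci_upper[i] <- ci$ci_upper
    out$adjusted_af[i] <- ci$multiplicity_hat / cn[i]
    cls <- classifyClonality(ci$ci_lower, ci$ci_upper, cn[i],
                             allow_low_cn = allow_low_cn)
    out$timing_class[i] <- cls
    if (cls == "unevaluable") out$reason[i] <- "copy number < 2"
  }
  res <- S4Vectors::DataFrame(out)
  S4Vectors::metadata(res) <- list(
    class_counts = table(out$timing_class),
    n_boot = n_boot, level = level, rng_seed = rng_seed)
  res
}
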