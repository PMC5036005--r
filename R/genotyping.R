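## Germline genotyping: APOBEC3B deletion zygosity from copy-number segment
## means (with an optional exon-coverage confirmation) and APOBEC3H
## diplotypes from per-site base-call summaries, plus population allele
## frequencies and their cross-population rank correlation.

#' Default APOBEC3H haplotype-defining allele table
#'
#' Loads the packaged table of defining-site alleles for the seven reported
#' APOBEC3H haplotypes. Haplotype I carries the Gly105 allele; haplotypes
#' II/V/VII carry Arg105 and encode stable proteins; haplotypes III/IV/VI
#' carry the destabilizing codon-15 deletion (tagged by a biallelic marker
#' in this encoding). The full site combinations distinguishing V and VII
#' from II are not uniquely documented, so the table is data, not code:
#' supply your own to override.
#'
#' @return data.frame with columns site, haplotype, base.
#' @export
a3hHaplotypeTable <- function() {
  path <- system.file("extdata", "a3h_haplotype_table.tsv",
                      package = "apobecsig")
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Call APOBEC3B deletion zygosity
#'
#' Classifies a sample as A3B-null, intact, or indeterminate. The primary
#' evidence is the minimum copy-number segment mean over the A3B interval
#' (null when \eqn{\le} the deletion threshold, default -1.5); when per-exon
#' normalized coverage is supplied, a null call additionally requires the
#' mean coverage over deleted exons relative to flanking preserved exons to
#' fall below a ratio threshold, operationalizing the manual
#' alignment-inspection confirmation step.
#'
#' @param segments segment data.frame (\code{\link{readSegments}} columns).
#' @param sample_id sample to call.
#' @param interval list with chrom, start, end of the A3B deletion interval.
#' @param exon_coverage optional data.frame with columns \code{exon},
#'   \code{normalized_depth} and logical \code{in_deletion}.
#' @param thresholds list of cutoffs: \code{seg_null} (default -1.5),
#'   \code{seg_intact} (-0.5), \code{ratio_null} (0.25) and
#'   \code{ratio_intact} (length-2 band, default c(0.75, 1.25)).
#' @return list with \code{sample}, \code{call} (null/intact/indeterminate),
#'   \code{min_segment_mean}, \code{coverage_ratio} and \code{reason}.
#' @examples
#' seg <- data.frame(sample = "s1", chrom = "chr22", start = 37680000,
#'                   end = 37700000, num_probes = 10, segment_mean = -1.8)
#' callA3BZygosity(seg, "s1",
#'                 interval = list(chrom = "chr22", start = 37683000,
#'                                 end = 37696000))
#' @export
callA3BZygosity <- function(segments, sample_id,
                            interval = list(chrom = "chr22",
                                            start = 37683965L,
                                            end = 37713498L),
                            exon_coverage = NULL,
                            thresholds = list(seg_null = -1.5,
                                              seg_intact = -0.5,
                                              ratio_null = 0.25,
                                              ratio_intact = c(0.75, 1.25))) {
  seg <- segments[segments$sample == sample_id &
                  segments$chrom == interval$chrom &
                  segments$start <= interval$end &
                  segments$end >= interval$start, , drop = FALSE]
  minMean <- if (nrow(seg)) min(seg$segment_mean) else NA_real_
  ratio <- NA_real_
  if (!is.null(exon_coverage)) {
    del <- exon_coverage$normalized_depth[exon_coverage$in_deletion]
    flank <- exon_coverage$normalized_depth[!exon_coverage$in_deletion]
    if (length(del) && length(flank) && mean(flank) > 0)
      ratio <- mean(del) / mean(flank)
  }
  if (is.na(minMean) && is.na(ratio))
    return(list(sample = sample_id, call = "indeterminate",
                min_segment_mean = NA_real_, coverage_ratio = NA_real_,
                reason = "no evidence"))
  segNull <- !is.na(minMean) && minMean <= thresholds$seg_null
  segIntact <- !is.na(minMean) && minMean >= thresholds$seg_intact
  ratioNull <- is.na(ratio) || ratio <= thresholds$ratio_null
  ratioIntact <- is.na(ratio) || (ratio >= thresholds$ratio_intact[1] &&
                                  ratio <= thresholds$ratio_intact[2])
  call <- if (segNull && ratioNull) "null"
          else if (segIntact && ratioIntact) "intact"
          else "indeterminate"
  reason <- switch(call,
    null = "segment mean at or below deletion threshold",
    intact = "segment mean and coverage consistent with two intact copies",
    indeterminate = "evidence between thresholds")
  list(sample = sample_id, call = call, min_segment_mean = minMean,
       coverage_ratio = ratio, reason = reason)
}

## diploid genotype at one site from base counts: returns a length-2 allele
## vector, or NULL when coverage/quality/allele balance is insufficient
callSiteGenotype <- function(counts, coverage, mean_quality,
                             min_coverage, min_quality,
                             hom_fraction, het_min) {
  if (coverage < min_coverage || mean_quality < min_quality) return(NULL)
  ord <- order(counts, decreasing = TRUE)
  major <- DNA_BASES[ord[1]]
  second <- DNA_BASES[ord[2]]
  if (counts[ord[1]] / coverage >= hom_fraction) return(c(major, major))
  if (counts[ord[2]] / coverage >= het_min) return(sort(c(major, second)))
  NULL
}

#' Call an APOBEC3H diplotype from base-call summaries
#'
#' Calls the diploid genotype at each haplotype-defining site from base
#' counts (homozygous when the major allele carries at least
#' \code{hom_fraction} of reads; heterozygous when the second allele reaches
#' \code{het_min}), then resolves the genotype pattern against the haplotype
#' table. When multiple haplotype pairs are compatible the
#' lexicographically smallest pair is reported with an ambiguity flag;
#' carrier status (at least one Gly105 copy) depends only on the codon-105
#' site. Sites failing the coverage/quality thresholds are left uncalled;
#' an uncalled codon-105 site makes the sample unknown.
#'
#' @param site_calls data.frame as from \code{\link{simulateSiteCalls}}:
#'   columns sample, site, A, C, G, T, mean_quality, coverage.
#' @param haplotype_table allele table (\code{\link{a3hHaplotypeTable}}).
#' @param min_coverage,min_quality per-site calling thresholds.
#' @param hom_fraction,het_min allele-balance thresholds.
#' @param g105_site,g105_allele identifier and allele of the Gly105 site in
#'   the haplotype table.
#' @return list with \code{sample}, \code{haplotype_pair} (two labels, or
#'   \code{c("unknown", "unknown")}), \code{carrier_status} (logical, NA when
#'   codon 105 is uncallable), \code{g105_copies}, \code{ambiguous} and
#'   \code{site_genotypes}.
#' @export
callA3HDiplotype <- function(site_calls,
                             haplotype_table = a3hHaplotypeTable(),
                             min_coverage = 8L, min_quality = 20,
                             hom_fraction = 0.9, het_min = 0.25,
                             g105_site = "c105", g105_allele = "G") {
  sampleId <- unique(site_calls$sample)
  if (length(sampleId) != 1L)
    stop("site_calls must describe exactly one sample")
  sites <- unique(haplotype_table$site)
  if (!g105_site %in% site_calls$site)
    stop("site_calls must cover the codon-105 site")
  genos <- list()
  for (st in sites) {
    row <- site_calls[site_calls$site == st, , drop = FALSE]
    if (!nrow(row)) { genos[st] <- list(NULL); next }
    counts <- setNames(as.numeric(row[1, DNA_BASES]), DNA_BASES)
    genos[st] <- list(callSiteGenotype(counts, row$coverage[1],
                                       row$mean_quality[1], min_coverage,
                                       min_quality, hom_fraction, het_min))
  }
  g105 <- genos[[g105_site]]
  copies <- if (is.null(g105)) NA_integer_ else sum(g105 == g105_allele)
  carrier <- if (is.na(copies)) NA else copies >= 1L
  haps <- sort(unique(haplotype_table$haplotype))
  alleleOf <- function(hp, st)
    haplotype_table$base[haplotype_table$haplotype == hp &
                         haplotype_table$site == st]
  compatible <- list()
  for (i in seq_along(haps)) for (j in i:length(haps)) {
    ok <- TRUE
    for (st in sites) {
      g <- genos[[st]]
      if (is.null(g)) next  # uncalled sites do not constrain the pair
      pair <- sort(c(alleleOf(haps[i], st), alleleOf(haps[j], st)))
      if (!identical(pair, sort(g))) { ok <- FALSE; break }
    }
    if (ok) compatible[[length(compatible) + 1L]] <- c(haps[i], haps[j])
  }
  if (is.null(g105) || !length(compatible)) {
    pair <- c("unknown", "unknown"); ambiguous <- FALSE
  } else {
    keys <- vapply(compatible, paste, character(1), collapse = "/")
    pair <- compatible[[order(keys)[1]]]
    ambiguous <- length(compatible) > 1L
  }
  list(sample = sampleId, haplotype_pair = pair, carrier_status = carrier,
       g105_copies = copies, ambiguous = ambiguous, site_genotypes = genos)
}

#' Per-population alternate-allele frequencies
#'
#' @param panel a \linkS4class{HaplotypePanel}.
#' @param snp_id SNP identifier in the panel.
#' @return list with \code{by_population} (named frequencies; alternate
#'   haplotype count over 2x samples in the population) and \code{overall}
#'   (pooled across populations, weighted by sample counts).
#' @export
alleleFrequencies <- function(panel, snp_id) {
  if (!snp_id %in% snpIds(panel)) stop("unknown SNP id: ", snp_id)
  col <- haplotypes(panel)[, match(snp_id, snpIds(panel))]
  popPerHap <- rep(populations(panel), each = 2L)
  popPerHap[is.na(popPerHap)] <- "ALL"
  tab <- tapply(col, popPerHap, mean)
  empty <- is.na(tab)
  if (any(empty)) {
    warning("excluding empty population(s): ",
            paste(names(tab)[empty], collapse = ", "))
    tab <- tab[!empty]
  }
  list(by_population = tab, overall = mean(col))
}

#' Cross-population correlation of two allele-frequency vectors
#'
#' Spearman rank correlation (mid-ranks for ties) across paired
#' per-population frequencies, with the exact null distribution when there
#' are 9 or fewer populations and no ties, and the large-sample
#' approximation otherwise.
#'
#' @param freq_x,freq_y paired per-population values (length >= 3).
#' @return list with \code{rho}, \code{p.value}, \code{n}; \code{rho} is NA
#'   with a reason when either vector is constant.
#' @examples
#' populationCorrelation(c(0.96, 0.9, 0.7, 0.6), c(0.05, 0.2, 0.5, 0.65))
#' @export
populationCorrelation <- function(freq_x, freq_y) {
  if (length(freq_x) != length(freq_y)) stop("vectors must be paired")
  if (length(freq_x) < 3) stop("at least 3 populations required")
  if (length(unique(freq_x)) == 1L || length(unique(freq_y)) == 1L)
    return(list(rho = NA_real_, p.value = NA_real_, n = length(freq_x),
                reason = "constant input vector: rank correlation undefined"))
  n <- length(freq_x)
  ct <- suppressWarnings(
    cor.test(freq_x, freq_y, method = "spearman", exact = n <= 9))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = n)
}
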