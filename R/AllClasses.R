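#' Phased haplotype panel
#'
#' Container for a panel of phased biallelic SNP haplotypes, as obtained from
#' a phased population VCF (e.g. a 1000 Genomes extract) or from
#' \code{\link{simulateHaplotypePanel}}. Rows of the haplotype matrix are
#' haplotypes (two consecutive rows per sample), columns are SNPs; entries
#' code the reference allele as 0 and the alternate allele as 1.
#'
#' @slot haplotypes integer matrix (2 * n_samples) x n_snps of 0/1 allele
#'   codes; row i belongs to sample \code{ceiling(i / 2)}.
#' @slot snpId character vector of SNP identifiers (column names).
#' @slot position integer vector of 1-based SNP positions.
#' @slot chrom character vector of SNP chromosomes.
#' @slot sampleId character vector of sample identifiers (length n_samples).
#' @slot population character vector of population labels per sample (may be
#'   \code{NA} when no labels are available).
#'
#' @export
setClass("HaplotypePanel",
  representation(
    haplotypes = "matrix",
    snpId      = "character",
    position   = "integer",
    chrom      = "character",
    sampleId   = "character",
    population = "character"
  )
)

setValidity("HaplotypePanel", function(object) {
  h <- object@haplotypes
  msg <- character()
  if (!is.numeric(h)) msg <- c(msg, "haplotypes must be a numeric matrix")
  if (nrow(h) %% 2L != 0L)
    msg <- c(msg, "haplotype matrix must have an even number of rows (2 per sample)")
  if (length(object@sampleId) * 2L != nrow(h))
    msg <- c(msg, "sampleId length must equal nrow(haplotypes)/2")
  if (length(object@snpId) != ncol(h))
    msg <- c(msg, "snpId length must equal ncol(haplotypes)")
  if (length(object@position) != ncol(h))
    msg <- c(msg, "position length must equal ncol(haplotypes)")
  if (length(object@chrom) != ncol(h))
    msg <- c(msg, "chrom length must equal ncol(haplotypes)")
  if (length(object@population) != length(object@sampleId))
    msg <- c(msg, "population length must equal sampleId length")
  if (length(h) && !all(h %in% c(0L, 1L)))
    msg <- c(msg, "allele codes must be 0 (ref) or 1 (alt)")
  if (anyDuplicated(object@snpId)) msg <- c(msg, "duplicate SNP identifiers")
  if (length(msg)) msg else TRUE
})

#' Construct a HaplotypePanel
#'
#' @param haplotypes 0/1 matrix, two rows per sample.
#' @param snpId,position,chrom per-SNP identifier, 1-based position and
#'   chromosome.
#' @param sampleId sample identifiers, one per pair of rows.
#' @param population optional per-sample population labels.
#' @return A \linkS4class{HaplotypePanel}.
#' @examples
#' h <- matrix(c(0, 1, 1, 0, 0, 0, 1, 1), nrow = 4)
#' HaplotypePanel(h, snpId = c("rs1", "rs2"), position = c(10L, 20L),
#'                chrom = c("chr22", "chr22"), sampleId = c("s1", "s2"))
#' @export
HaplotypePanel <- function(haplotypes, snpId, position, chrom, sampleId,
                           population = rep(NA_character_, length(sampleId))) {
  storage.mode(haplotypes) <- "integer"
  colnames(haplotypes) <- snpId
  new("HaplotypePanel", haplotypes = haplotypes, snpId = as.character(snpId),
      position = as.integer(position), chrom = as.character(chrom),
      sampleId = as.character(sampleId), population = as.character(population))
}

setMethod("show", "HaplotypePanel", function(object) {
  cat("HaplotypePanel:", length(object@sampleId), "samples x",
      length(object@snpId), "SNPs (", nrow(object@haplotypes), "haplotypes )\n")
  pops <- unique(object@population[!is.na(object@population)])
  if (length(pops))
    cat("  populations:", paste(pops, collapse = ", "), "\n")
})

#' 96-channel trinucleotide mutation spectrum
#'
#' Counts of single-base substitutions binned by pyrimidine-centric
#' trinucleotide context (6 substitution types x 16 flanking contexts = 96
#' channels), together with proportions relative to the total mutation count
#' and, optionally, motif-abundance-weighted frequencies
#' (\code{\link{weightedSpectrum}}).
#'
#' @slot counts named numeric vector of length 96 (channel counts).
#' @slot proportions counts / total; all \code{NA} when the spectrum is empty.
#' @slot weighted motif-abundance-adjusted frequencies summing to 1, or a
#'   length-0 vector before weighting has been applied.
#' @slot nTotal total number of mutations.
#' @export
setClass("TrinucSpectrum",
  representation(
    counts      = "numeric",
    proportions = "numeric",
    weighted    = "numeric",
    nTotal      = "integer"
  )
)

setValidity("TrinucSpectrum", function(object) {
  msg <- character()
  if (length(object@counts) != 96L) msg <- c(msg, "counts must have 96 channels")
  if (any(object@counts < 0)) msg <- c(msg, "counts must be non-negative")
  if (!identical(names(object@counts), trinucChannels()))
    msg <- c(msg, "counts must be named by the canonical 96 channels")
  if (object@nTotal > 0L) {
    if (abs(sum(object@proportions) - 1) > 1e-9)
      msg <- c(msg, "proportions must sum to 1")
    if (length(object@weighted) && abs(sum(object@weighted) - 1) > 1e-9)
      msg <- c(msg, "weighted frequencies must sum to 1")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TrinucSpectrum", function(object) {
  cat("TrinucSpectrum: 96 channels,", object@nTotal, "mutations\n")
  if (object@nTotal > 0L) {
    top <- sort(object@proportions, decreasing = TRUE)[1:3]
    cat("  top channels:",
        paste(sprintf("%s (%.3f)", names(top), top), collapse = ", "), "\n")
  }
  if (length(object@weighted)) cat("  weighted frequencies present\n")
})

#' Amplicon mutation report
#'
#' Substitution counts and context spectra from aligned amplicon sequences,
#' as produced by \code{\link{countAmpliconMutations}}.
#'
#' @slot nSequences number of amplicon sequences counted.
#' @slot alignedBases number of unambiguous, non-gap-adjacent aligned
#'   reference bases (the per-kb denominator).
#' @slot substitutionCounts named vector of the 12 substitution types.
#' @slot focalType substitution type summarised by rate/context (e.g. "C>T").
#' @slot ratePerKb 1000 * focal-type count / alignedBases.
#' @slot contextCounts focal-type counts keyed by 5' dinucleotide
#'   (TC/CC/GC/AC).
#' @slot trinucContextCounts focal-type counts keyed by trinucleotide.
#' @slot strandMode "as-given" or "cDNA".
#' @export
setClass("AmpliconReport",
  representation(
    nSequences          = "integer",
    alignedBases        = "integer",
    substitutionCounts  = "numeric",
    focalType           = "character",
    ratePerKb           = "numeric",
    contextCounts       = "numeric",
    trinucContextCounts = "numeric",
    strandMode          = "character"
  )
)

setValidity("AmpliconReport", function(object) {
  msg <- character()
  if (length(object@substitutionCounts) != 12L)
    msg <- c(msg, "substitutionCounts must have 12 types")
  if (sum(object@contextCounts) != object@substitutionCounts[object@focalType])
    msg <- c(msg, "context counts must sum to the focal substitution count")
  if (!object@strandMode %in% c("as-given", "cDNA"))
    msg <- c(msg, "strandMode must be 'as-given' or 'cDNA'")
  if (length(msg)) msg else TRUE
})

setMethod("show", "AmpliconReport", function(object) {
  cat("AmpliconReport:", object@nSequences, "sequences,",
      object@alignedBases, "aligned bases (", object@strandMode, ")\n")
  cat(sprintf("  %s: %d events, %.3f per kb\n", object@focalType,
              object@substitutionCounts[object@focalType], object@ratePerKb))
  cat("  5' context:", paste(sprintf("%s=%d", names(object@contextCounts),
                                     object@contextCounts), collapse = " "), "\n")
})
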