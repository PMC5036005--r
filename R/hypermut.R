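## Amplicon hypermutation counting: global alignment of full-length amplicon
## sequences against their reference, substitution tallies by type, per-kb
## rates and 5'-dinucleotide context spectra. Amplicons are short,
## full-length and near-identical to the reference, so a global affine-gap
## aligner is used in place of a read mapper.

SUB_TYPES <- as.vector(outer(DNA_BASES, DNA_BASES, function(r, a)
  paste0(r, ">", a)))[as.vector(outer(DNA_BASES, DNA_BASES, `!=`))]

#' Globally align amplicon sequences to a reference
#'
#' Needleman-Wunsch global alignment with affine gap penalties
#' (match +1, mismatch -1, gap open -4, gap extend -1 per position by
#' default). Ambiguity codes (e.g. R from degenerate primers) are permitted
#' in the input and resolved at the counting stage.
#'
#' @param queries amplicon sequences (\code{DNAStringSet} or character
#'   vector).
#' @param reference reference sequence (\code{DNAString} or character).
#' @param match,mismatch,gap_open,gap_extend alignment scores.
#' @return list of alignments, each a list with \code{pattern} and
#'   \code{subject} (gapped query/reference strings) and \code{score}.
#' @export
alignAmplicons <- function(queries, reference, match = 1, mismatch = -1,
                           gap_open = -4, gap_extend = -1) {
  if (is.character(queries)) queries <- Biostrings::DNAStringSet(queries)
  ref <- Biostrings::DNAString(unname(refAsCharacter(reference)[1]))
  if (any(Biostrings::width(queries) == 0) || length(ref) == 0)
    stop("sequences must be nonempty")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(queries, ref, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = -gap_open,
                                       gapExtension = -gap_extend)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  lapply(seq_along(pat), function(i)
    list(pattern = pat[i], subject = sub[i],
         score = Biostrings::score(aln)[i]))
}

#' Count substitutions in aligned amplicons
#'
#' Tallies every mismatch column of the alignments by substitution type,
#' computes the per-kb rate of a focal type over the aligned reference
#' bases, and resolves the 5'-dinucleotide (and trinucleotide) context of
#' each focal-type event from the reference strand being reported. In
#' \code{"cDNA"} mode both strands are reverse-complemented before counting,
#' so genomic-strand G>A hypermutation is reported as C>T with
#' reverse-complemented context. Columns adjacent to alignment gaps (within
#' \code{gap_flank} positions) and columns containing ambiguity characters
#' are excluded from both the counts and the per-kb denominator.
#'
#' @param alignments output of \code{\link{alignAmplicons}}.
#' @param strand_mode "as-given" or "cDNA".
#' @param focal_type substitution summarised by rate and context (default
#'   "C>T").
#' @param gap_flank number of columns on each side of a gap to exclude
#'   (default 1; 0 disables the exclusion).
#' @return An \linkS4class{AmpliconReport}.
#' @export
countAmpliconMutations <- function(alignments,
                                   strand_mode = c("as-given", "cDNA"),
                                   focal_type = "C>T", gap_flank = 1L) {
  strand_mode <- match.arg(strand_mode)
  if (!focal_type %in% SUB_TYPES) stop("invalid focal substitution type")
  focalRef <- substr(focal_type, 1, 1)
  subCounts <- setNames(numeric(length(SUB_TYPES)), SUB_TYPES)
  ctxCounts <- setNames(numeric(4), c("TC", "CC", "GC", "AC"))
  triCounts <- numeric(0)
  alignedBases <- 0L
  refLens <- vapply(alignments, function(a)
    nchar(gsub("-", "", a$subject, fixed = TRUE)), integer(1))
  if (length(unique(refLens)) > 1L)
    stop("alignments reference sequences of different lengths")
  for (a in alignments) {
    pat <- strsplit(a$pattern, "")[[1]]
    ref <- strsplit(a$subject, "")[[1]]
    if (strand_mode == "cDNA") {
      comp <- c(COMP, `-` = "-")
      pat <- rev(ifelse(pat %in% names(comp), comp[pat], pat))
      ref <- rev(ifelse(ref %in% names(comp), comp[ref], ref))
    }
    L <- length(ref)
    gapCol <- pat == "-" | ref == "-"
    nearGap <- rep(FALSE, L)
    if (gap_flank > 0 && any(gapCol)) {
      for (k in seq_len(gap_flank)) {
        idx <- which(gapCol)
        nearGap[pmax(idx - k, 1L)] <- TRUE
        nearGap[pmin(idx + k, L)] <- TRUE
      }
      nearGap <- nearGap & !gapCol
    }
    ambiguous <- !(pat %in% DNA_BASES) & !gapCol |
                 !(ref %in% DNA_BASES) & !gapCol
    counted <- !gapCol & !nearGap & !ambiguous
    alignedBases <- alignedBases + sum(counted)
    mism <- counted & pat != ref
    if (any(mism)) {
      types <- paste0(ref[mism], ">", pat[mism])
      tab <- table(factor(types, levels = SUB_TYPES))
      subCounts <- subCounts + as.numeric(tab)
      ## context of the focal-type events, from the reporting-strand
      ## reference; events at the first reference position have no 5' base
      ## and are excluded from both the type tally and the spectrum
      foc <- which(mism & ref == focalRef &
                   pat == substr(focal_type, 3, 3))
      for (i in foc) {
        prev <- if (i > 1) max(which(ref[seq_len(i - 1)] != "-")) else NA
        if (is.na(prev) || !(ref[prev] %in% DNA_BASES)) {
          subCounts[focal_type] <- subCounts[focal_type] - 1
          next
        }
        ctxKey <- paste0(ref[prev], focalRef)
        ctxCounts[ctxKey] <- ctxCounts[ctxKey] + 1
        nxtIdx <- if (i < L) which(ref[(i + 1):L] != "-") else integer()
        nxt <- if (length(nxtIdx)) ref[i + nxtIdx[1]] else "N"
        triKey <- paste0(ref[prev], focalRef, nxt)
        triCounts[triKey] <- (if (triKey %in% names(triCounts))
                                triCounts[triKey] else 0) + 1
      }
    }
  }
  rate <- if (alignedBases > 0) 1000 * subCounts[[focal_type]] / alignedBases
          else NA_real_
  new("AmpliconReport", nSequences = length(alignments),
      alignedBases = as.integer(alignedBases),
      substitutionCounts = subCounts, focalType = focal_type,
      ratePerKb = rate, contextCounts = ctxCounts,
      trinucContextCounts = triCounts, strandMode = strand_mode)
}

#' One-call amplicon hypermutation report
#'
#' Aligns amplicon sequences to a reference and counts substitutions in one
#' step.
#'
#' @inheritParams alignAmplicons
#' @inheritParams countAmpliconMutations
#' @return An \linkS4class{AmpliconReport}.
#' @export
hypermutReport <- function(queries, reference,
                           strand_mode = c("as-given", "cDNA"),
                           focal_type = "C>T", gap_flank = 1L) {
  countAmpliconMutations(alignAmplicons(queries, reference),
                         strand_mode = match.arg(strand_mode),
                         focal_type = focal_type, gap_flank = gap_flank)
}
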