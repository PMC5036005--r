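## 96-channel trinucleotide mutation spectra, motif-abundance weighting,
## signature category classification, per-patient proportions with the
## minimum-mutation inclusion rule, and the group comparison statistics.

#' Canonical 96-channel keys
#'
#' The 96 pyrimidine-centric channels, ordered alphabetically by
#' (ref, alt, 5' base, 3' base) so that output files are byte-stable.
#'
#' @return character vector of keys like \code{"A[C>A]A"}.
#' @export
trinucChannels <- function() {
  types <- rbind(expand.grid(ref = "C", alt = c("A", "G", "T")),
                 expand.grid(ref = "T", alt = c("A", "C", "G")))
  out <- character()
  for (k in seq_len(nrow(types)))
    for (five in DNA_BASES) for (three in DNA_BASES)
      out <- c(out, sprintf("%s[%s>%s]%s", five, types$ref[k], types$alt[k],
                            three))
  ## order by (ref, alt, five, three)
  parts <- regmatches(out, regexec("^(.)\\[(.)>(.)\\](.)$", out))
  key <- vapply(parts, function(p) paste(p[3], p[4], p[2], p[5]), character(1))
  out[order(key)]
}

#' Trinucleotide context channel of a mutation
#'
#' Maps each single-base substitution to its pyrimidine-centric 96-channel
#' key: purine-reference mutations are reverse-complemented so the mutated
#' base is always C or T. The reference base at each position must match the
#' recorded ref allele.
#'
#' @param reference reference sequences (\code{DNAStringSet}, or a named
#'   character vector; a single unnamed sequence is allowed when all
#'   mutations share one chromosome).
#' @param mutations data.frame with columns sample, chrom, pos, ref, alt.
#' @return character vector of channel keys.
#' @examples
#' mutationContext(c(chr1 = "ATCAG"),
#'                 data.frame(sample = "s", chrom = "chr1", pos = 3,
#'                            ref = "C", alt = "T"))
#' @export
mutationContext <- function(reference, mutations) {
  refs <- refAsCharacter(reference)
  if (length(refs) == 1L && !all(mutations$chrom %in% names(refs)))
    names(refs) <- unique(mutations$chrom)[1]
  unknown <- setdiff(unique(mutations$chrom), names(refs))
  if (length(unknown))
    stop("chromosome(s) absent from reference: ", paste(unknown, collapse = ", "))
  lens <- nchar(refs)[mutations$chrom]
  bad <- which(mutations$pos < 2L | mutations$pos > lens - 1L)
  if (length(bad))
    stop(sprintf("position %d on %s has no trinucleotide context (sample %s)",
                 mutations$pos[bad[1]], mutations$chrom[bad[1]],
                 mutations$sample[bad[1]]))
  seqs <- refs[mutations$chrom]
  five <- substring(seqs, mutations$pos - 1L, mutations$pos - 1L)
  cen <- substring(seqs, mutations$pos, mutations$pos)
  three <- substring(seqs, mutations$pos + 1L, mutations$pos + 1L)
  mism <- which(cen != mutations$ref)
  if (length(mism))
    stop(sprintf(
      "reference mismatch for sample %s at %s:%d (expected %s, reference has %s)",
      mutations$sample[mism[1]], mutations$chrom[mism[1]],
      mutations$pos[mism[1]], mutations$ref[mism[1]], cen[mism[1]]))
  alt <- mutations$alt
  flip <- cen %in% c("A", "G")
  if (any(flip)) {
    f5 <- unname(COMP[three[flip]])
    f3 <- unname(COMP[five[flip]])
    cen[flip] <- unname(COMP[cen[flip]])
    alt[flip] <- unname(COMP[alt[flip]])
    five[flip] <- f5
    three[flip] <- f3
  }
  sprintf("%s[%s>%s]%s", five, cen, alt, three)
}

#' Build a 96-channel trinucleotide spectrum
#'
#' Bins mutations by pyrimidine-centric trinucleotide context and normalizes
#' counts to proportions of the total somatic mutation count.
#'
#' @inheritParams mutationContext
#' @return A \linkS4class{TrinucSpectrum}. An empty input yields a spectrum
#'   with \code{nTotal = 0} and all-NA proportions.
#' @export
buildSpectrum <- function(mutations, reference) {
  channels <- trinucChannels()
  if (nrow(mutations) == 0L) {
    counts <- setNames(numeric(96), channels)
    return(new("TrinucSpectrum", counts = counts,
               proportions = counts * NA_real_, weighted = numeric(0),
               nTotal = 0L))
  }
  keys <- mutationContext(reference, mutations)
  counts <- as.numeric(table(factor(keys, levels = channels)))
  names(counts) <- channels
  new("TrinucSpectrum", counts = counts, proportions = counts / sum(counts),
      weighted = numeric(0), nTotal = as.integer(sum(counts)))
}

#' Trinucleotide motif frequencies of a reference
#'
#' Counts every trinucleotide window of the reference and divides by the
#' total number of windows (sequence length - 2, summed over sequences). In
#' the default \code{"collapsed"} mode each window is keyed by its
#' pyrimidine-centric representation (purine-centre windows are
#' reverse-complemented), matching the strand collapse applied to mutation
#' spectra; \code{"literal"} mode keys windows as written, over all 64
#' trinucleotides.
#'
#' @param reference \code{DNAStringSet}/\code{DNAString} or character.
#' @param mode "collapsed" (32 pyrimidine-centre keys) or "literal" (64 keys).
#' @return list with \code{frequencies} (named, summing to 1),
#'   \code{counts} and \code{denominator} (total windows).
#' @examples
#' referenceMotifFrequencies("ATCAGT", mode = "literal")$frequencies
#' @export
referenceMotifFrequencies <- function(reference,
                                      mode = c("collapsed", "literal")) {
  mode <- match.arg(mode)
  refs <- refAsCharacter(reference)
  if (any(nchar(refs) < 3)) stop("reference sequences must have length >= 3")
  counts64 <- Reduce(`+`, lapply(refs, function(x)
    Biostrings::trinucleotideFrequency(Biostrings::DNAString(x))))
  denom <- sum(nchar(refs) - 2L)
  if (mode == "literal") {
    counts <- counts64
  } else {
    keys <- names(counts64)
    centre <- substr(keys, 2, 2)
    collapsedKey <- ifelse(centre %in% c("C", "T"), keys, revComp(keys))
    agg <- tapply(counts64, collapsedKey, sum)
    counts <- setNames(as.numeric(agg), names(agg))
    counts <- counts[sort(names(counts))]
  }
  list(frequencies = counts / denom, counts = counts, denominator = denom,
       mode = mode)
}

channelContext <- function(channels) {
  sub("^(.)\\[(.)>.\\](.)$", "\\1\\2\\3", channels)
}

#' Motif-abundance-weighted spectrum
#'
#' Adjusts each channel's mutation count by the frequency of its
#' trinucleotide motif in the reference — count divided by motif frequency —
#' and renormalizes the adjusted counts to sum to 1. Underrepresented motifs
#' (e.g. CG-containing trinucleotides in exomes) are thereby up-weighted in
#' proportion to their rarity.
#'
#' @param spectrum a \linkS4class{TrinucSpectrum}.
#' @param motif_freqs result of \code{\link{referenceMotifFrequencies}} (or a
#'   named frequency vector covering the contexts present in the spectrum).
#' @return The spectrum with its \code{weighted} slot filled.
#' @export
weightedSpectrum <- function(spectrum, motif_freqs) {
  freqs <- if (is.list(motif_freqs)) motif_freqs$frequencies else motif_freqs
  counts <- channelCounts(spectrum)
  ctx <- channelContext(names(counts))
  f <- as.numeric(freqs[ctx])
  zero <- counts > 0 & (is.na(f) | f == 0)
  if (any(zero))
    stop("nonzero mutation count at motif with zero reference frequency: ",
         paste(unique(ctx[zero]), collapse = ", "))
  adj <- ifelse(counts > 0, counts / f, 0)
  w <- if (sum(adj) > 0) adj / sum(adj) else adj
  names(w) <- names(counts)
  initialize(spectrum, weighted = w)
}

#' Signature category of 96-channel keys
#'
#' Classifies channels into the three signature categories: APOBEC (C>T at
#' TCW, i.e. 5' T and 3' A or T), smoking (C>A in any context) and ageing
#' (C>T at CG motifs, i.e. 3' G). In \code{"extended"} mode C>G at TCW also
#' counts as APOBEC, matching the broader TCW accounting that includes
#' APOBEC-attributed transversions. The categories are mutually exclusive
#' in both modes (TCW excludes a 3' G).
#'
#' @param channels character vector of 96-channel keys.
#' @param mode "ct-only" (default) or "extended".
#' @return factor with levels APOBEC, smoking, ageing (NA for channels in no
#'   category).
#' @examples
#' classifyCategory(c("T[C>T]A", "C[C>A]G", "A[C>T]G"))
#' @export
classifyCategory <- function(channels, mode = c("ct-only", "extended")) {
  mode <- match.arg(mode)
  parts <- regmatches(channels, regexec("^(.)\\[(.)>(.)\\](.)$", channels))
  bad <- lengths(parts) != 5L
  if (any(bad)) stop("invalid channel key: ", channels[bad][1])
  five <- vapply(parts, `[`, character(1), 2)
  ref <- vapply(parts, `[`, character(1), 3)
  alt <- vapply(parts, `[`, character(1), 4)
  three <- vapply(parts, `[`, character(1), 5)
  tcw <- ref == "C" & five == "T" & three %in% c("A", "T")
  apobec <- (ref == "C" & alt == "T" & tcw) |
            (mode == "extended" & ref == "C" & alt == "G" & tcw)
  smoking <- ref == "C" & alt == "A"
  ageing <- ref == "C" & alt == "T" & three == "G"
  out <- rep(NA_character_, length(channels))
  out[ageing] <- "ageing"
  out[smoking] <- "smoking"
  out[apobec] <- "APOBEC"
  factor(out, levels = c("APOBEC", "smoking", "ageing"))
}

#' Per-patient, per-timing-class signature category proportions
#'
#' For every (patient, timing class) cell, computes the proportion of that
#' cell's mutations falling in each signature category. Cells with fewer
#' than \code{min_count} mutations are excluded (and reported in the
#' \code{excluded} attribute) to avoid unstable proportions.
#'
#' @param mutations mutation data.frame; when \code{timing} is NULL all
#'   mutations form a single "all" class.
#' @param reference reference sequences for context lookup.
#' @param timing optional character vector of timing classes, row-aligned
#'   with \code{mutations}; mutations with class "unevaluable" are dropped.
#' @param min_count minimum mutations per cell (default 4: cells with 3 or
#'   fewer are excluded).
#' @param mode category mode passed to \code{\link{classifyCategory}}.
#' @return data.frame with sample, timing_class, category, proportion,
#'   n_mutations (cell total); attribute \code{excluded} lists dropped cells.
#' @export
categoryProportions <- function(mutations, reference, timing = NULL,
                                min_count = 4L,
                                mode = c("ct-only", "extended")) {
  mode <- match.arg(mode)
  if (is.null(timing)) timing <- rep("all", nrow(mutations))
  if (length(timing) != nrow(mutations))
    stop("timing must be row-aligned with mutations")
  keep <- timing != "unevaluable" & !is.na(timing)
  mutations <- mutations[keep, , drop = FALSE]
  timing <- timing[keep]
  if (!nrow(mutations)) {
    out <- data.frame(sample = character(), timing_class = character(),
                      category = character(), proportion = numeric(),
                      n_mutations = integer())
    attr(out, "excluded") <- data.frame(sample = character(),
                                        timing_class = character(),
                                        n_mutations = integer())
    return(out)
  }
  cat <- classifyCategory(mutationContext(reference, mutations), mode = mode)
  cell <- paste(mutations$sample, timing, sep = "\r")
  rows <- list(); excl <- list()
  for (cl in unique(cell)) {
    idx <- cell == cl
    n <- sum(idx)
    parts <- strsplit(cl, "\r", fixed = TRUE)[[1]]
    if (n < min_count) {
      excl[[length(excl) + 1L]] <- data.frame(sample = parts[1],
                                              timing_class = parts[2],
                                              n_mutations = n)
      next
    }
    tab <- table(cat[idx])
    for (cg in names(tab))
      rows[[length(rows) + 1L]] <- data.frame(
        sample = parts[1], timing_class = parts[2], category = cg,
        proportion = as.numeric(tab[[cg]]) / n, n_mutations = n)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(sample = character(), timing_class = character(),
                         category = character(), proportion = numeric(),
                         n_mutations = integer())
  attr(out, "excluded") <- if (length(excl)) do.call(rbind, excl)
                           else data.frame(sample = character(),
                                           timing_class = character(),
                                           n_mutations = integer())
  out
}

#' Welch two-sample comparison of category proportions
#'
#' Welch's unequal-variance two-tailed t-test (Welch-Satterthwaite degrees
#' of freedom) between two groups of per-patient proportions.
#'
#' @param values numeric vector of per-patient proportions.
#' @param group logical or two-level factor splitting \code{values}.
#' @return list with \code{statistic}, \code{p.value}, \code{df},
#'   \code{means}, \code{sems} and \code{n} per group.
#' @export
compareGroups <- function(values, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly two levels")
  ns <- table(g)
  if (any(ns < 2)) stop("insufficient group size: both groups need >= 2 values")
  sems <- tapply(values, g, function(x) stats::sd(x) / sqrt(length(x)))
  vars <- tapply(values, g, stats::var)
  if (all(vars == 0)) {
    ## both groups constant: t.test cannot run; the comparison degenerates
    means <- tapply(values, g, mean)
    equal <- means[1] == means[2]
    return(list(statistic = if (equal) 0 else sign(means[1] - means[2]) * Inf,
                p.value = if (equal) 1 else 0, df = NA_real_,
                means = means, sems = sems, n = as.integer(ns)))
  }
  tt <- t.test(values ~ g, var.equal = FALSE)
  list(statistic = unname(tt$statistic), p.value = tt$p.value,
       df = unname(tt$parameter), means = tapply(values, g, mean),
       sems = sems, n = as.integer(ns))
}

#' Fisher's exact test for a 2x2 enrichment table
#'
#' Two-sided exact hypergeometric P (sum of the probabilities of all tables
#' with the observed margins that are no more probable than the observed
#' table), with the sample odds ratio (Haldane 0.5 continuity correction
#' when a cell is zero).
#'
#' @param tbl 2x2 matrix of non-negative integer counts.
#' @return list with \code{odds_ratio}, \code{p.value} and
#'   \code{continuity_corrected}.
#' @examples
#' fisherEnrichment(matrix(c(10, 0, 0, 10), 2))
#' @export
fisherEnrichment <- function(tbl) {
  tbl <- as.matrix(tbl)
  if (!all(dim(tbl) == c(2L, 2L))) stop("a 2x2 table is required")
  if (any(tbl < 0) || any(tbl != round(tbl)))
    stop("cells must be non-negative integers")
  if (any(rowSums(tbl) == 0) || any(colSums(tbl) == 0))
    stop("table has an all-zero margin")
  ft <- fisher.test(tbl, alternative = "two.sided")
  cc <- any(tbl == 0)
  t2 <- if (cc) tbl + 0.5 else tbl
  orHat <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(odds_ratio = orHat, p.value = ft$p.value, continuity_corrected = cc)
}
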