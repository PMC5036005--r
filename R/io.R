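## Readers and writers for the external formats the pipeline touches.
## Internal convention everywhere: 1-based inclusive coordinates (MAF/SEG
## style); 0-based half-open sources must be converted before entry.

#' Default MAF column dialect
#'
#' Column-name mapping from the internal mutation-table fields to TCGA MAF
#' export headers. Pass a modified copy to \code{\link{readMutationTable}}
#' for other dialects.
#'
#' @return Named character vector mapping internal names (sample, chrom, pos,
#'   ref, alt, ref_count, alt_count) to file column names.
#' @export
mafDialect <- function() {
  c(sample    = "Tumor_Sample_Barcode",
    chrom     = "Chromosome",
    pos       = "Start_Position",
    ref       = "Reference_Allele",
    alt       = "Tumor_Seq_Allele2",
    ref_count = "t_ref_count",
    alt_count = "t_alt_count")
}

plainDialect <- function() {
  c(sample = "sample", chrom = "chrom", pos = "pos", ref = "ref", alt = "alt",
    ref_count = "ref_count", alt_count = "alt_count")
}

## internal validator shared by the reader and the simulator
validateMutations <- function(m) {
  stopifnot(is.data.frame(m))
  need <- c("sample", "chrom", "pos", "ref", "alt")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stop("mutation table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(m$ref %in% DNA_BASES) || !all(m$alt %in% DNA_BASES))
    stop("ref/alt alleles must be single bases A/C/G/T")
  if (any(m$ref == m$alt)) stop("ref and alt alleles must differ")
  if (any(m$pos < 1)) stop("positions must be >= 1")
  if (!is.null(m$ref_count) &&
      (any(m$ref_count < 0, na.rm = TRUE) || any(m$alt_count < 0, na.rm = TRUE)))
    stop("read counts must be non-negative")
  invisible(m)
}

#' Read a MAF-like somatic mutation table
#'
#' Reads a tab-separated mutation table, keeping single-nucleotide
#' substitutions and skipping (with a count) indel or multi-base rows.
#' Comment lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @param dialect named map from internal field names to file column names;
#'   defaults to TCGA MAF names (\code{\link{mafDialect}}). Files written by
#'   \code{\link{writeMutationTable}} use the plain internal names, which are
#'   also accepted automatically.
#' @return A list with \code{mutations} (data.frame with columns sample,
#'   chrom, pos, ref, alt and, when present in the file, ref_count/alt_count),
#'   \code{n_skipped}, and \code{skipped} (row numbers of skipped records).
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("sample\tchrom\tpos\tref\talt\tref_count\talt_count",
#'              "s1\tchr1\t10\tC\tT\t60\t140"), f)
#' readMutationTable(f, dialect = NULL)$mutations
#' @export
readMutationTable <- function(path, dialect = mafDialect()) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (is.null(dialect)) dialect <- plainDialect()
  if (!all(dialect[c("sample", "chrom", "pos")] %in% names(raw)) &&
      all(plainDialect()[c("sample", "chrom", "pos")] %in% names(raw)))
    dialect <- plainDialect()
  mandatory <- c("sample", "chrom", "pos", "ref", "alt")
  for (f in mandatory) {
    if (!dialect[[f]] %in% names(raw))
      stop(sprintf("mutation table format error: missing mandatory column '%s'",
                   dialect[[f]]))
  }
  out <- data.frame(
    sample = as.character(raw[[dialect[["sample"]]]]),
    chrom  = as.character(raw[[dialect[["chrom"]]]]),
    pos    = suppressWarnings(as.integer(raw[[dialect[["pos"]]]])),
    ref    = toupper(as.character(raw[[dialect[["ref"]]]])),
    alt    = toupper(as.character(raw[[dialect[["alt"]]]])),
    stringsAsFactors = FALSE)
  if (anyNA(out$pos)) {
    bad <- which(is.na(out$pos))[1]
    stop(sprintf("unparsable position at data row %d of %s", bad, path))
  }
  hasCounts <- all(dialect[c("ref_count", "alt_count")] %in% names(raw))
  if (hasCounts) {
    out$ref_count <- as.integer(raw[[dialect[["ref_count"]]]])
    out$alt_count <- as.integer(raw[[dialect[["alt_count"]]]])
  }
  snv <- out$ref %in% DNA_BASES & out$alt %in% DNA_BASES & out$ref != out$alt
  skipped <- which(!snv)
  out <- out[snv, , drop = FALSE]
  rownames(out) <- NULL
  validateMutations(out)
  list(mutations = out, n_skipped = length(skipped), skipped = skipped)
}

#' Write / read copy-number segments (SEG format)
#'
#' The SEG dialect used has columns Sample, Chromosome, Start, End,
#' Num_Probes, Segment_Mean, plus an optional Total_CN integer column.
#' Coordinates are 1-based inclusive.
#'
#' @param path file path.
#' @return \code{readSegments}: data.frame with columns sample, chrom, start,
#'   end, num_probes, segment_mean and (when present) total_cn.
#' @export
readSegments <- function(path) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("Sample", "Chromosome", "Start", "End", "Num_Probes", "Segment_Mean")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("SEG format error: missing column(s): ", paste(miss, collapse = ", "))
  seg <- data.frame(
    sample = as.character(raw$Sample), chrom = as.character(raw$Chromosome),
    start = as.integer(raw$Start), end = as.integer(raw$End),
    num_probes = as.integer(raw$Num_Probes),
    segment_mean = as.numeric(raw$Segment_Mean), stringsAsFactors = FALSE)
  if ("Total_CN" %in% names(raw)) seg$total_cn <- as.integer(raw$Total_CN)
  bad <- which(seg$start > seg$end)
  if (length(bad))
    stop(sprintf("SEG format error: start > end at data row %d", bad[1]))
  ## non-overlap within sample/chrom
  sp <- split(seg, list(seg$sample, seg$chrom), drop = TRUE)
  for (g in sp) {
    g <- g[order(g$start), , drop = FALSE]
    if (nrow(g) > 1 && any(g$start[-1] <= g$end[-nrow(g)]))
      stop(sprintf("overlapping segments for sample %s on %s",
                   g$sample[1], g$chrom[1]))
  }
  if (!is.null(seg$total_cn)) {
    inconsistent <- (seg$total_cn < 2 & seg$segment_mean >= 0) |
                    (seg$segment_mean < 0 & seg$total_cn >= 2)
    if (any(inconsistent, na.rm = TRUE))
      stop("segment_mean sign inconsistent with total copy number")
  }
  seg
}

#' @rdname readSegments
#' @param segments data.frame as returned by \code{readSegments}.
#' @param meta optional named list written as \code{# key=value} header lines.
#' @export
writeSegments <- function(path, segments, meta = NULL) {
  out <- data.frame(Sample = segments$sample, Chromosome = segments$chrom,
                    Start = segments$start, End = segments$end,
                    Num_Probes = segments$num_probes %||% NA_integer_,
                    Segment_Mean = segments$segment_mean)
  if (!is.null(segments$total_cn)) out$Total_CN <- segments$total_cn
  writeTsv(path, out, meta)
}

#' Read a per-sample purity table
#'
#' @param path tab-separated file with columns sample, purity and optional
#'   population.
#' @return data.frame with sample, purity (in (0, 1]) and population.
#' @export
readPurity <- function(path) {
  raw <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  miss <- setdiff(c("sample", "purity"), names(raw))
  if (length(miss))
    stop("purity table missing column(s): ", paste(miss, collapse = ", "))
  p <- data.frame(sample = as.character(raw$sample),
                  purity = as.numeric(raw$purity),
                  population = if ("population" %in% names(raw))
                    as.character(raw$population) else NA_character_,
                  stringsAsFactors = FALSE)
  if (any(p$purity <= 0 | p$purity > 1))
    stop("purity values must lie in (0, 1]")
  p
}

#' Read a FASTA reference
#'
#' @param path FASTA file.
#' @return A \code{DNAStringSet}; duplicate sequence names are an error.
#' @export
readReference <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("FASTA contains duplicate sequence names")
  seqs
}

#' Read a phased VCF into a haplotype panel
#'
#' Genotypes must be phased (\code{|} separator); unphased records are
#' rejected because linkage disequilibrium here is defined on phased
#' haplotypes only. Multi-allelic records are split into bi-allelic
#' pseudo-sites (one per alternate allele, suffixed \code{_2}, \code{_3}...).
#'
#' @param path VCF file (plain text or gzipped).
#' @param populationMap optional named character vector mapping sample name
#'   to population label.
#' @return A \linkS4class{HaplotypePanel}.
#' @export
readPhasedVcf <- function(path, populationMap = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) < 1) stop("VCF contains no genotype columns")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype found ('/' separator); phased genotypes required")
  samples <- colnames(gt)
  ids <- fix[, "ID"]
  noid <- is.na(ids) | ids == "."
  ids[noid] <- paste0(fix[noid, "CHROM"], ":", fix[noid, "POS"])
  hapA <- sub("\\|.*$", "", gt)
  hapB <- sub("^.*\\|", "", gt)
  if (any(hapA == "" | hapB == "" | is.na(gt)))
    stop("missing or malformed genotype in VCF")
  cols <- list(); colId <- character(); colPos <- integer(); colChr <- character()
  for (i in seq_len(nrow(gt))) {
    nAlt <- length(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    for (a in seq_len(nAlt)) {
      codes <- rbind(as.integer(hapA[i, ] == a), as.integer(hapB[i, ] == a))
      cols[[length(cols) + 1L]] <- as.vector(codes)  # hapA,hapB per sample
      colId <- c(colId, if (nAlt == 1) ids[i] else paste0(ids[i], "_", a + 1L))
      colPos <- c(colPos, as.integer(fix[i, "POS"]))
      colChr <- c(colChr, fix[i, "CHROM"])
    }
  }
  h <- do.call(cbind, cols)
  pops <- if (is.null(populationMap)) rep(NA_character_, length(samples))
          else unname(populationMap[samples])
  HaplotypePanel(h, snpId = colId, position = colPos, chrom = colChr,
                 sampleId = samples, population = pops)
}

#' Write a haplotype panel as a phased VCF
#'
#' @param path output path.
#' @param panel a \linkS4class{HaplotypePanel}.
#' @export
writePhasedVcf <- function(path, panel) {
  h <- haplotypes(panel)
  n <- length(sampleIds(panel))
  lines <- c("##fileformat=VCFv4.2",
             paste0("##source=apobecsig-", as.character(packageVersion("apobecsig"))),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", sampleIds(panel)), collapse = "\t"))
  for (j in seq_along(snpIds(panel))) {
    a <- h[seq(1, 2 * n, by = 2), j]
    b <- h[seq(2, 2 * n, by = 2), j]
    gts <- paste0(a, "|", b)
    lines <- c(lines, paste(c(panel@chrom[j], panel@position[j],
                              snpIds(panel)[j], "A", "G", ".", "PASS", ".",
                              "GT", gts), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a table as TSV with metadata header comments
#'
#' All pipeline outputs go through this writer: optional \code{# key=value}
#' comment lines (recording version, seed and parameters) followed by a
#' tab-separated table with header.
#'
#' @param path output path.
#' @param x data.frame.
#' @param meta optional named list of metadata values.
#' @export
writeTsv <- function(path, x, meta = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# apobecsig=%s", as.character(packageVersion("apobecsig"))),
             con)
  for (nm in names(meta))
    writeLines(sprintf("# %s=%s", nm, paste(format(meta[[nm]]), collapse = ",")), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname readMutationTable
#' @param mutations data.frame of mutations (internal column names).
#' @param meta optional metadata list, written as header comments.
#' @export
writeMutationTable <- function(path, mutations, meta = NULL) {
  validateMutations(mutations)
  writeTsv(path, mutations, meta)
}

#' @rdname readPurity
#' @param purity data.frame with sample, purity, optional population.
#' @param meta optional metadata list.
#' @export
writePurity <- function(path, purity, meta = NULL) {
  writeTsv(path, purity, meta)
}
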