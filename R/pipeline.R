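## End-to-end association analysis: genotype -> timing -> per-patient
## signature proportions -> carrier-vs-non-carrier comparisons.

#' Pipeline configuration defaults
#'
#' Thresholds and parameters for \code{\link{runEndToEnd}}, all recorded in
#' the run manifest: copy-number segment-mean deletion cutoff -1.5, minimum
#' 4 mutations per patient-timing cell, 10,000 bootstrap replicates, 95%
#' confidence level, C>T-only APOBEC category.
#'
#' @param seg_null A3B-null segment-mean threshold.
#' @param min_count minimum mutations per patient-timing cell.
#' @param n_boot bootstrap replicates for timing CIs.
#' @param level CI confidence level.
#' @param category_mode "ct-only" or "extended" (adds C>G at TCW to APOBEC).
#' @param min_coverage,min_quality A3H site-calling thresholds.
#' @param rng_seed global seed.
#' @return named list of parameters.
#' @export
pipelineConfig <- function(seg_null = -1.5, min_count = 4L, n_boot = 10000L,
                           level = 0.95, category_mode = "ct-only",
                           min_coverage = 8L, min_quality = 20,
                           rng_seed = 1L) {
  list(seg_null = seg_null, min_count = as.integer(min_count),
       n_boot = as.integer(n_boot), level = level,
       category_mode = category_mode, min_coverage = as.integer(min_coverage),
       min_quality = min_quality, rng_seed = as.integer(rng_seed))
}

#' Run the genotype-to-association analysis end to end
#'
#' Composes the full analysis on one cohort: (1) call the A3H diplotype and
#' carrier status of every sample from base-call summaries; (2) time every
#' mutation (early-clonal / late-clonal / subclonal) with half-coverage
#' bootstrap CIs; (3) compute per-patient, per-timing-class signature
#' category proportions under the minimum-count inclusion rule; (4) compare
#' carriers against non-carriers with Welch's two-tailed t-test for every
#' (timing class x category) cell; and (5) build carrier-stratified
#' 96-channel spectra. All thresholds, seeds and versions are recorded in
#' the returned manifest; when \code{out_dir} is given, every result table
#' is also written as TSV with the manifest in its header comments.
#'
#' @param mutations,segments,purity,site_calls cohort tables (see
#'   \code{\link{readMutationTable}}, \code{\link{readSegments}},
#'   \code{\link{readPurity}}, \code{\link{simulateSiteCalls}}), or file
#'   paths to them.
#' @param reference reference sequences (\code{DNAStringSet} or FASTA path).
#' @param config parameter list from \code{\link{pipelineConfig}}.
#' @param out_dir optional output directory for TSV results.
#' @return list with \code{genotypes}, \code{timing}, \code{proportions},
#'   \code{comparisons}, \code{spectra} (per carrier group) and
#'   \code{manifest}.
#' @export
runEndToEnd <- function(mutations, segments, purity, site_calls, reference,
                        config = pipelineConfig(), out_dir = NULL) {
  if (is.character(mutations) && length(mutations) == 1L)
    mutations <- readMutationTable(mutations, dialect = NULL)$mutations
  if (is.character(segments) && length(segments) == 1L)
    segments <- readSegments(segments)
  if (is.character(purity) && length(purity) == 1L)
    purity <- readPurity(purity)
  if (is.character(site_calls) && length(site_calls) == 1L)
    site_calls <- read.delim(site_calls, comment.char = "#",
                             stringsAsFactors = FALSE)
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference))
    reference <- readReference(reference)
  stage <- "genotyping"
  genos <- tryCatch({
    ids <- unique(site_calls$sample)
    do.call(rbind, lapply(ids, function(id) {
      g <- callA3HDiplotype(site_calls[site_calls$sample == id, , drop = FALSE],
                            min_coverage = config$min_coverage,
                            min_quality = config$min_quality)
      data.frame(sample = id,
                 haplotype_pair = paste(g$haplotype_pair, collapse = "/"),
                 g105_copies = g$g105_copies,
                 is_carrier = g$carrier_status, ambiguous = g$ambiguous)
    }))
  }, error = function(e) stop("stage ", stage, " failed: ",
                              conditionMessage(e), call. = FALSE))
  stage <- "timing"
  timing <- tryCatch(
    timingPipeline(mutations, segments, purity, n_boot = config$n_boot,
                   level = config$level, rng_seed = config$rng_seed),
    error = function(e) stop("stage ", stage, " failed: ",
                             conditionMessage(e), call. = FALSE))
  stage <- "proportions"
  props <- tryCatch(
    categoryProportions(mutations, reference,
                        timing = as.character(timing$timing_class),
                        min_count = config$min_count,
                        mode = config$category_mode),
    error = function(e) stop("stage ", stage, " failed: ",
                             conditionMessage(e), call. = FALSE))
  props$is_carrier <- genos$is_carrier[match(props$sample, genos$sample)]
  stage <- "comparison"
  cmp <- list()
  for (tc in unique(props$timing_class)) {
    for (cg in levels(classifyCategory(character(0)))) {
      cell <- props[props$timing_class == tc & props$category == cg &
                    !is.na(props$is_carrier), , drop = FALSE]
      if (length(unique(cell$is_carrier)) < 2L) next
      if (min(table(cell$is_carrier)) < 2L) next
      w <- compareGroups(cell$proportion, cell$is_carrier)
      cmp[[length(cmp) + 1L]] <- data.frame(
        timing_class = tc, category = cg, statistic = w$statistic,
        p.value = w$p.value, df = w$df,
        mean_noncarrier = unname(w$means[["FALSE"]]),
        mean_carrier = unname(w$means[["TRUE"]]),
        sem_noncarrier = unname(w$sems[["FALSE"]]),
        sem_carrier = unname(w$sems[["TRUE"]]),
        n_noncarrier = w$n[1], n_carrier = w$n[2])
    }
  }
  comparisons <- if (length(cmp)) do.call(rbind, cmp) else
    data.frame(timing_class = character(), category = character(),
               statistic = numeric(), p.value = numeric())
  stage <- "spectra"
  carrierIds <- genos$sample[genos$is_carrier %in% TRUE]
  spectra <- list(
    carrier = buildSpectrum(
      mutations[mutations$sample %in% carrierIds, , drop = FALSE], reference),
    noncarrier = buildSpectrum(
      mutations[!(mutations$sample %in% carrierIds), , drop = FALSE],
      reference))
  manifest <- c(config,
                list(version = as.character(packageVersion("apobecsig")),
                     n_samples = length(unique(mutations$sample)),
                     n_mutations = nrow(mutations)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    writeTsv(file.path(out_dir, "genotypes.tsv"), genos, manifest)
    writeTsv(file.path(out_dir, "timing.tsv"), as.data.frame(timing), manifest)
    writeTsv(file.path(out_dir, "proportions.tsv"), props, manifest)
    writeTsv(file.path(out_dir, "comparisons.tsv"), comparisons, manifest)
    specTab <- data.frame(channel = trinucChannels(),
                          carrier_count = channelCounts(spectra$carrier),
                          noncarrier_count = channelCounts(spectra$noncarrier))
    writeTsv(file.path(out_dir, "spectra.tsv"), specTab, manifest)
  }
  list(genotypes = genos, timing = timing, proportions = props,
       comparisons = comparisons, spectra = spectra, manifest = manifest)
}
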