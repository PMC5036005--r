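Package: apobecsig
Title: APOBEC3 Germline Genotypes, Trinucleotide Mutation Signatures and
    Clonality Timing in Tumour Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools to link APOBEC3 germline variation (the APOBEC3B deletion
    polymorphism and the APOBEC3H haplotype I / Gly105 allele) to somatic
    mutational signatures and their clonal timing in tumour sequencing
    cohorts. Builds 96-channel trinucleotide mutation spectra with
    motif-abundance weighting, classifies mutations into APOBEC, smoking and
    ageing signature categories, times mutations as early-clonal, late-clonal
    or subclonal from purity- and copy-number-adjusted allele fractions with
    half-coverage bootstrap confidence intervals, computes linkage
    disequilibrium r-squared matrices from phased haplotype panels, calls
    APOBEC3B deletion zygosity and APOBEC3H diplotypes from copy-number and
    base-call evidence, and counts context-resolved cytosine mutations in
    deaminated amplicon sequences. A synthetic-cohort generator with known
    ground truth (mixed mutational processes, clonal architecture, read
    counts, block-structured haplotype panels) makes every stage testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
biocViews: SomaticMutation, Software, StatisticalMethod, Genetics
RoxygenNote: 7.3.3
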