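# apobecsig

Tools for linking **APOBEC3 germline variation** to **somatic mutational
signatures** and their **clonal timing** in tumour sequencing cohorts.

Two germline features of the APOBEC3 locus shape cancer mutagenesis: the
~29.5 kbp deletion polymorphism that removes *APOBEC3B* (an *A3B-null*
genome), and the *APOBEC3H* haplotype-I allele, whose defining Gly105
variant lowers protein expression but permits nuclear access of an active
cytosine deaminase. This package implements the computational pipeline
needed to ask whether carriers of such alleles show more APOBEC-signature
mutations, and *when* in tumour evolution those mutations arose — aimed at
cancer-genomics analysts working with MAF-style somatic mutation tables,
SEG copy-number segments, purity estimates and phased population VCFs.

## What it computes

* **96-channel trinucleotide spectra** — substitutions keyed by
  pyrimidine-centric context `5'[ref>alt]3'`, with motif-abundance
  weighting: channel counts are divided by the reference frequency of
  their motif (windows / (length − 2)) and renormalized,
  `w_c = (n_c/f_c) / Σ_k (n_k/f_k)`.
* **Signature categories** — APOBEC (C→T at TCW; optionally also C→G at
  TCW), smoking (C→A anywhere), ageing (C→T at CG), as per-patient
  proportions per timing class, excluding any patient–class cell with
  fewer than four mutations.
* **Clonality timing** — multiplicity `m = f·(ρC + 2(1−ρ))/ρ` from variant
  allele fraction `f`, purity `ρ` and total copy number `C`, with a 95%
  bootstrap interval that resamples reads at *half* the observed coverage
  (10,000 replicates). Early-clonal: lower bound > 1 copy (≥ 2 in
  amplified regions); subclonal: upper bound < 1; late-clonal otherwise.
* **Germline genotyping** — A3B-null calls from segment means ≤ −1.5 with
  an optional exon-coverage confirmation; A3H diplotypes and Gly105
  carrier status from per-site base-call summaries.
* **Linkage disequilibrium** — r² = D²/(p_A(1−p_A)p_B(1−p_B)) matrices
  from phased haplotype panels, plus per-population allele frequencies and
  their Spearman correlation.
* **Amplicon hypermutation** — global alignment of deaminated amplicon
  sequences, substitution counts per kb and 5′-dinucleotide (TC/CC/GC/AC)
  context spectra, with a cDNA strand mode for retroviral G→A
  hypermutation.
* **Synthetic cohorts** — a generator for mutation catalogs with known
  mutational-process mixtures and clonal architecture, copy-number/purity
  tables, LD-block haplotype panels, site-call summaries and deaminated
  amplicons, so every stage is testable with recoverable ground truth.

## Worked example

Simulate a 25 + 25 association study in which carriers of at least one
Gly105 copy get a +0.15 increment to their early-clonal APOBEC mixture
weight, then run the full pipeline (genotype → timing → proportions →
Welch comparisons):

```r
library(apobecsig)

ref <- simulateReference(30000, gc_fraction = 0.45, rng_seed = 7)
study <- simulateAssociationStudy(
  n_carrier = 25, n_noncarrier = 25, carrier_effect = 0.15,
  reference = ref,
  base_config = cohortConfig(n_patients = 1, muts_per_patient = 80),
  rng_seed = 7)
res <- runEndToEnd(study$mutations, study$segments, study$purity,
                   study$site_calls, ref,
                   config = pipelineConfig(n_boot = 2000, rng_seed = 7))

head(res$genotypes, 3)
#>   sample haplotype_pair g105_copies is_carrier ambiguous
#> 1 CAR001           I/II           1       TRUE     FALSE
#> 2 CAR002            I/I           2       TRUE     FALSE
#> 3 CAR003           I/II           1       TRUE     FALSE

subset(res$comparisons, timing_class == "early_clonal",
       c(category, statistic, p.value, mean_noncarrier, mean_carrier))
#>   category statistic      p.value mean_noncarrier mean_carrier
#> 4   APOBEC -3.995459 0.0002230327       0.1717919    0.2736701
#> 5  smoking  3.278082 0.0019573946       0.2976150    0.2212101
#> 6   ageing  3.662557 0.0006473191       0.2752367    0.1837366

show(res$spectra$carrier)
#> TrinucSpectrum: 96 channels, 2010 mutations
#>   top channels: T[C>T]A (0.117), T[C>T]T (0.099), T[C>G]T (0.067)
```

Genotypes are recovered from simulated base calls (not read off the
truth), and the early-clonal APOBEC comparison detects the planted carrier
effect: carriers average a 0.27 early-clonal APOBEC proportion against
0.17 in non-carriers (Welch P = 2.2e-4). The smoking and ageing categories
move in the opposite direction because the carrier arm's remaining early
weights are rescaled. The carrier-group spectrum concentrates on the TCW
channels (`T[C>T]A`, `T[C>T]T`, `T[C>G]T`), the APOBEC hallmark.

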