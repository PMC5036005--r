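---
title: "Methods: APOBEC3 germline genotypes, mutation signatures and clonality timing"
author: "apobecsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: APOBEC3 germline genotypes, mutation signatures and clonality timing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apobecsig)
```

# Scope

`apobecsig` implements the computational core of an association analysis
between APOBEC3 germline variation and somatic mutational signatures in
tumour cohorts. Two germline features are called: homozygosity for the
~29.5 kbp APOBEC3B deletion polymorphism (A3B-null), and the APOBEC3H
haplotype-I allele defined by Gly105 (an A3H-I *carrier* has at least one
Gly105 copy). On the somatic side, the package builds 96-channel
trinucleotide mutation spectra, assigns mutations to APOBEC / smoking /
ageing signature categories, times each mutation relative to copy-number
change (early-clonal, late-clonal, subclonal), and compares per-patient
category proportions between carrier groups. Linkage disequilibrium between
SNP sets and context-resolved counting of deaminated amplicon sequences
complete the toolkit. Because the cohorts this analysis was designed for are
controlled-access, every stage is paired with a synthetic generator whose
ground truth is recoverable, and the test suite quantifies that recovery.

# The timing model

For a somatic substitution with variant allele fraction $f$ observed in a
tumour of purity $\rho$ at a locus of total copy number $C$, the estimated
number of tumour chromosomal copies bearing the mutation (its
*multiplicity*) is

$$\hat m \;=\; f\,\frac{\rho C + 2(1-\rho)}{\rho},$$

and the adjusted allele fraction is $\hat m / C$. The formula reproduces
the two standard anchors at $\rho = 1$: $f = 0.50$ corresponds to 1 of 2
copies in a diploid region, and $f = 0.667$ to 2 of 3 copies under a
single-copy amplification. Several equivalent published parameterizations
exist; this one was adopted because it is the unique affine-in-$f$ form
matching both anchors.

Uncertainty is quantified by a resampling interval: each of `n_boot`
(default 10,000) replicates draws an alternate-read count from
$\mathrm{Binomial}(\lceil n/2 \rceil, \hat f)$ — *half* of the observed
coverage $n$, which deliberately widens the interval and makes the timing
calls conservative — and maps the replicate fraction through the formula
above. The percentile interval (plain, not bias-corrected: the procedure is
stated as simple resampling, and the percentile form is its most faithful
reading) at level 0.95 gives `ci_lower` and `ci_upper` on the copy scale.
Odd coverages round the half upward. Timing classes follow from where this
interval sits relative to one copy:

* **early_clonal** — `ci_lower` > 1 in diploid regions, or `ci_lower` ≥ 2 in
  amplified regions ($C \ge 3$): the mutation preceded the copy-number
  gain. The amplified rule uses the CI bound rather than the point
  estimate, mirroring the diploid rule; the alternative (point-estimate ≥ 2)
  was rejected for inconsistency with how the diploid case is stated.
* **subclonal** — `ci_upper` < 1: the mutation is carried by a
  subpopulation of tumour cells.
* **late_clonal** — everything else. The two printed definitions (interval
  overlaps 1; interval below 1) are jointly exhaustive only when no interval
  sits strictly between 1 and 2 in an amplified region; such intervals are
  assigned late_clonal here, which is also the biologically coherent
  reading (a clonal mutation on one of several copies, acquired after the
  gain).
* **unevaluable** — no read counts, no overlapping segment, no purity,
  coverage < 2, or $C < 2$. Deleted regions have no stated rule; an opt-in
  flag (`allow_low_cn`) applies the interval-versus-one-copy logic there.

Each mutation's bootstrap stream is seeded from the global seed and the
mutation's (sample, chromosome, position), so calls are reproducible and
independent of record order.

# Spectra, weighting and categories

Substitutions are keyed by pyrimidine-centric trinucleotide context:
purine-reference mutations are reverse-complemented so the mutated base is
always C or T, giving 6 substitution types × 16 flanking contexts = 96
channels, ordered alphabetically by (ref, alt, 5′, 3′) for byte-stable
output. Spectrum proportions divide channel counts by the total.

Motif-abundance weighting corrects for reference composition: each
channel's count is divided by the frequency of its trinucleotide motif in
the reference, and the adjusted counts are renormalized to sum to one.
Motif frequencies divide motif counts by the total number of windows
(length − 2 per sequence). Two accounting modes exist because mutation
spectra are strand-collapsed: the default collapses each window to its
pyrimidine-centric key (so the motif space matches the spectrum's), while a
literal mode counts the 64 trinucleotides exactly as written on the given
strand — appropriate for single-stranded targets such as amplicon cDNA.
Which of the two a given published analysis used is generally not stated;
the collapsed default is the self-consistent choice and the literal mode
reproduces the written formula verbatim.

Signature categories follow the standard motif definitions: APOBEC is C→T
at TCW (5′ T, 3′ A or T), smoking is C→A in any context, ageing is C→T at
CG motifs. The default counts only C→T as APOBEC; an extended mode adds C→G
at TCW, the transversion component of the APOBEC process. Both modes are
explicit flags because published figures differ in which accounting they
use; the categories are mutually exclusive in either mode since TCW
excludes a 3′ G. Per-patient proportions are computed per timing class, and
any patient-timing cell with fewer than four mutations is excluded — the
boundary is sharp: three mutations exclude the cell, four retain it.
Carrier groups are compared with Welch's unequal-variance two-tailed
t-test; 2×2 enrichment uses Fisher's exact test.

# Germline calling

**A3B zygosity.** A sample is called A3B-null when the minimum copy-number
segment mean over the A3B interval is ≤ −1.5 (the deletion threshold, in
log2 copy-ratio units). When normalized per-exon depths are available, a
null call additionally requires mean coverage over the deleted exons to
fall below 0.25 of the flanking preserved exons — this ratio operationalizes
the manual alignment-inspection step that a human analyst would perform,
and it is flagged as a surrogate in the output. Intact calls require a
segment mean ≥ −0.5 with a coverage ratio inside [0.75, 1.25]; anything
between is indeterminate. All thresholds are configurable.

**A3H diplotypes.** Diploid genotypes at the haplotype-defining sites are
called from base counts: homozygous when the major allele holds ≥ 0.9 of
reads, heterozygous when the second allele reaches ≥ 0.25, uncalled below 8
reads or mean quality 20. These defaults replace a manual review step that
has no printed criteria, and all four are configurable. The genotype
pattern is resolved against a packaged haplotype allele table (data, not
code: the site-level combinations separating the rarer stable haplotypes
are not uniquely documented, so the table is overridable). Phase between
sites is not inferred; when several haplotype pairs are compatible the
lexicographically smallest is reported with an ambiguity flag. This is
harmless for the analysis-driving quantity — carrier status depends only on
the number of Gly105 copies at the codon-105 site, and an uncallable
codon-105 site yields an unknown, never a guessed, carrier status.

# Linkage and population frequencies

$r^2$ between two SNPs is computed from phased haplotypes only:
$D = p_{AB} - p_A p_B$ and $r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))$. Unphased
genotypes are rejected at the reader rather than approximated with
composite LD, so a cell in the matrix always means haplotype-level
correlation. Monomorphic SNPs, and SNPs below a minor-allele-frequency
floor (default 0.01, recorded in the output), give NA cells — never 0,
which would fabricate "no linkage". Population allele frequencies count
alternate haplotypes over 2× samples per population; cross-population
correlation uses Spearman's rank correlation with mid-ranks for ties, the
exact null distribution for ≤ 9 populations (without ties) and the
large-sample approximation otherwise.

# Amplicon hypermutation counting

Amplicons are short, full-length and near-identical to their reference, so
a global Needleman–Wunsch alignment with affine gaps (match +1, mismatch
−1, gap open −4, extend −1) replaces a read mapper. Every mismatch column
is tallied by substitution type; the per-kb rate divides the focal type's
count by the aligned (non-gap) reference bases, not the raw read length. In
cDNA mode both strands are reverse-complemented before counting, so
genomic-strand G→A hypermutation is reported as C→T with
reverse-complemented context, and the 5′-dinucleotide context (TC/CC/GC/AC)
of each counted cytosine is taken from the reporting strand's reference.
Columns within one position of an alignment gap are excluded from both
counts and denominator to avoid alignment-artifact miscounts (the window is
configurable; 0 disables it), and ambiguity characters — expected from
degenerate primers — count as neither match nor mismatch. Focal-type events
at the first reference position have no 5′ context and are excluded from
both the tally and the spectrum, keeping the two consistent.

# The synthetic generator

The generator exists so that every stage can be tested against recoverable
truth; its defaults define the reference study conditions used throughout
the test suite and are not tuned per test.

* **Mutational processes.** APOBEC events are planted only at TCW sites (on
  either strand, exercising strand collapse) as C→T (65%) or C→G (35%);
  smoking as C→A at any cytosine; ageing as C→T at CG sites; a fourth
  "other" process draws uniform substitutions anywhere. Mixture weights are
  configurable per timing class.
* **Clonal architecture.** 30% of mutations are early-clonal (planted on
  all copies of their segment, hence restricted to CN ≥ 2), 40%
  late-clonal (single copy, cancer-cell fraction 1) and 30% subclonal
  (single copy, cancer-cell fraction uniform on (0.1, 0.5) — clearly below
  the clonal boundary so classification-recovery tests are sharp).
* **Reads.** Expected allele fraction follows the multiplicity algebra
  exactly — $\mathrm{ccf}\cdot m\rho / (C\rho + 2(1-\rho))$ — and alternate
  counts are binomial at constant depth 120 (real per-site depths are not
  available to emulate; a constant is the transparent default). Purity is
  uniform on [0.6, 1]; per-patient mutation counts are Poisson with mean
  100; copy-number segments (12 per patient) draw CN 1/2/3 with
  probabilities 0.05/0.75/0.20 and carry segment means of exactly
  $\log_2(C/2)$.
* **Haplotype panels.** SNPs within a block are noisy copies of an
  unobserved founder: each copies the founder with probability $1-f$ and
  otherwise redraws at the founder frequency, with $f = 1 - r_2^{1/4}$ so
  every within-block pair has expected $r^2$ equal to the block target
  while marginal frequencies are preserved exactly. Blocks are mutually
  independent. Founder frequencies may differ by population.
* **Site calls and amplicons.** Base calls draw one of the two haplotype
  alleles per read and corrupt it to a uniform other base at the error
  rate; amplicon deaminations are planted per cytosine at 5′-dinucleotide
  context-specific rates (defaults biased to TC).

What the generator does **not** emulate: sequencing-error models beyond the
uniform per-read error, indels, mapping artefacts, subclonal population
structure (each subclonal mutation has an independent cancer-cell
fraction), kataegis clustering, and germline variation outside the phased
panel. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated model, not robustness to real-data artefacts.

# Numerical choices and degenerate inputs

Empty mutation sets produce a spectrum with zero total and NA proportions
rather than an error; zero-coverage site calls are flagged "no coverage";
monomorphic SNPs and constant frequency vectors yield NA with a reason.
A nonzero mutation count at a motif with zero reference frequency is an
error (an impossible mutation), as is a duplicated (sample, chromosome,
position) record in timing. Channels are ordered alphabetically and all
writers emit `# key=value` metadata headers so outputs are byte-stable and
reproducible from their manifest alone. All randomness flows from explicit
integer seeds; per-record substreams are derived with a deterministic
31-bit string hash.

# Problem sizes in the test suite

The suite exercises recovery at sizes chosen to make the statistical
assertions sharp while keeping a full run in minutes: mixture-weight
recovery on cohorts of 8 patients × 550 mutations at APOBEC weights 0.2 /
0.5 / 0.8 (3-SD multinomial bands); LD-block recovery and cross-block
independence at 5,000 haplotypes (±0.03); diplotype recovery over 1,000
simulated samples at depth 30 and 1% error (≥ 99%); bootstrap-CI coverage
over 2,000 replicates at depth 100 (≥ 93% at nominal 95%, the half-coverage
resampling pushing realized coverage above nominal); timing-class recovery
on a ~2,000-mutation cohort at depth 120 (≥ 90% early-clonal sensitivity,
≤ 5% subclonal miscalls); a planted +0.15 carrier effect detected at
P < 0.01 in a 60 + 60 cohort; and a 200-run null study holding the type-I
error at 5% ± 2% (these lighter null runs use 12 + 12 patients and 120
bootstrap replicates). `scripts/acceptance.R` recomputes the same
quantities from scratch under a caller-supplied seed.

# Known limitations

The A3H haplotype table's site combinations for the rarer stable
haplotypes are a documented default, not an authority; override it for
serious use. The A3B coverage-ratio confirmation is a surrogate for expert
alignment review. Timing treats each mutation independently — no joint
subclonal deconvolution — and copy-number input is total (not
allele-specific), so the multiplicity of mutations on minor alleles in
unbalanced regions is approximate. Signature assignment is motif-based, by
category, not a full signature deconvolution.
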