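---
title: "Haplotype-resolved methylation from long bisulfite amplicons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-resolved methylation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplometh)
```

## The problem

Targeted bisulfite PCR of long (~1.3 kbp) amplicons read on a long-read
platform yields, per single molecule, the methylation state of every CpG in
the amplicon *and* the alleles of any polymorphism it spans. That makes two
things possible that short-read or array assays cannot do directly: sorting
reads into the two parental haplotypes via an amplicon-internal SNP, and
therefore measuring allele-specific methylation (ASM); and exploiting many
CpGs per locus instead of a single index probe when predicting an exposure
phenotype (here: smoking status) from blood DNA methylation.

`haplometh` implements the full computational path: demultiplexing of dual
5-nt barcodes, read QC, bisulfite-aware alignment to amplicon references,
allele calling, per-haplotype methylation quantification, covariate and ASM
statistics, Boruta CpG selection, and three stacked logistic smoking models
("index", "boruta", "boruta.adjusted"). Because the motivating cohort data
are not public, a first-class synthetic generator reproduces the cohort's
statistical structure with full truth tables.

## Processing model and thresholds

Every threshold is a named configuration key with the documented default:

* **Mean read quality ≥ 30** (`min_q`). The aggregate accuracy of a
  circular-consensus read is a per-read quantity, so the filter uses the
  mean Phred score (a per-base mode exists). The gate is inclusive: a read
  at exactly Q30 passes. The simulator emits constant Q40 by default.
* **Exact-match demultiplexing.** The first five bases carry barcode 1 and
  the last five the reverse complement of barcode 2; both must match a
  mapped 8 × 12 combination exactly — no error-tolerant rescue. Reads are
  tried in both orientations and normalised.
* **Unconverted CpH < 5%** (`conv_threshold`, strict inequality: exactly 5%
  fails). CpH methylation is rare, so unconverted CpH marks failed
  bisulfite conversion. Reads without observable CpH sites pass vacuously —
  the failure is unobservable there — and are flagged in QC. The per-target
  conversion rate, `1 − Σunconverted/ΣCpH`, is audited against a 0.98 gate.
* **De-duplication** collapses reads sharing (start, CIGAR, full
  methylation vector, full allele vector) within a sample × target — a
  deliberately conservative key, because without molecular identifiers a
  byte-identical molecule cannot be distinguished from a PCR clone. A
  looser position-only mode exists.
* **Per-haplotype depth ≥ 5** (`min_depth`, inclusive) and a per-target
  coverage rule: a target is dropped when fewer than `min_sample_fraction`
  (default 0.8; the underlying study reports only the outcome of such a
  drop, not the rule, so the fraction is this package's choice) of samples
  retain a row.

### Alignment

Amplicon data need no genome-scale aligner: reads are aligned against at
most six known references. Both read and reference are fully C→T converted
("three-letter space") so methylation state cannot penalise the alignment;
methylation is then called from the *original* read base over each
reference CpG (C = methylated, T = unmethylated, anything else missing).
Equal-length reads take an exact ungapped comparison; length mismatches
fall back to global affine-gap dynamic programming (via
`Biostrings::pairwiseAlignment`, match +1, mismatch −1, gap open 4, gap
extend 1), whose scores are tested against an independent full-matrix DP
oracle. Reads under an identity floor (default 0.8) are unmapped.

### Allele calls

On bisulfite-converted DNA an unmethylated C reads as T, so alleles are
compared after equivalence-classing: C ≡ T on the amplified plus strand,
G ≡ A (in plus-strand coordinates) when the amplified strand is the minus
strand. SNPs whose alleles collapse to one class (C>T on plus, G>A on
minus) are structurally uninformative and always yield `unknown`, as do
gapped or off-class bases. CpGs overlapped by a known CpG-SNP are masked
from all downstream analysis: their methylation signal is confounded by
genotype.

## The methylation matrix

Reads of each sample × target are sorted by the consolidated allele call
over the target's usable SNPs (conflicting calls within one read exclude
it). Heterozygotes — both alleles supported by ≥ 2 reads and ≥ 10% of
informative reads, a package choice since the study does not state its
rule — contribute two haplotype rows; homozygotes one row over all their
reads, including allele-uninformative ones. When exactly one haplotype of
a heterozygote passes the depth filter, the passing row is kept.

Missing rates are mean-imputed per CpG column (observed cells never
change), then transformed by the smoothed logit

$$M = \log\frac{m'}{1-m'},\qquad m' = \frac{m\,(n-1) + 0.5}{n},$$

with `m` the raw methylation rate and `n` *the sample size of the analysis
set* — read literally; a per-cell-depth alternative is exposed as an
option but off by default. The natural log is used (the base is not
specified anywhere; t tests and logistic fits are invariant to it). The
smoothing keeps `M` finite, with `|M| ≤ log((n−0.5)/0.5)` attained at
m ∈ {0, 1}, `M(0.5, n) = 0`, and antisymmetry `M(m) = −M(1−m)`.

## Statistics

Age, gender and diagnosis are regressed out per CpG by OLS and the
residuals carried forward; the allele-adjusted variant also regresses out
the haplotype allele indicator. Binary covariates are tested per CpG by a
two-tailed Welch t test (the unequal-variance form, since only "t test" is
stated); age by the t statistic of its OLS slope, the only two-sample
analogue defined for a continuous covariate. The ASM contrast compares
ref- vs alt-haplotype rows among heterozygotes after covariate
residualisation. p-values are Benjamini–Hochberg adjusted within each
target by default (the display of per-target significance tracks suggests
per-target families; a pooled mode exists because the family is not
actually stated).

## Boruta selection

The all-relevant selector is reimplemented: each iteration appends one
permuted shadow per surviving feature (padded to a minimum of five shadows
so the bar stays stable late in a run), scores a hit when a real feature's
importance exceeds the maximum shadow importance, and applies two-sided
binomial tests (hits vs Binomial(iterations, ½)) with Bonferroni
correction — significantly many hits confirm, significantly few reject and
remove the feature. The importance oracle is pluggable; the default is the
Z-score of out-of-bag permutation importance from a compact random forest
(Rcpp), chosen because no random-forest package is available in the target
environment. Tentative features are excluded from models by default (the
stricter reading of "important" CpGs); a target with zero confirmed CpGs
falls back to its index CpG so the stacked model always sees all retained
targets.

A caveat worth stating: on a *frozen* all-noise design the luckiest chance
correlate of the fixed matrix can persistently beat freshly permuted
shadows, so a minority of pure-noise runs confirm one or two features.
This is a property of the max-shadow/binomial design itself (it reproduces
with a deterministic t-statistic importance), not of the forest backend;
the test suite documents both the realistic bounds and the idealised
expectation.

## Prediction models

The subjects are split 1:1 into train and test, unstratified (only
"randomly split 1:1" is stated; a stratified option exists). Per target, a
logistic model of smoking on the selected CpGs' residualised `M` values is
fitted on training *haplotype rows*; heterozygote averaging applies at
prediction time (the procedure places averaging among "prediction
values"), giving one probability per subject per target. A stacked
logistic combiner is fitted on the per-target prediction columns; subjects
missing a target receive the training-set mean prediction there. All fits
use maximum-likelihood IRLS with a mild L2 penalty (λ = 1e-4 on
standardised slopes, never the intercept) purely as a guard against
separation in 77-row fits; λ = 0 reproduces `glm` to 1e-6. ROC/AUC uses
the rank (Mann–Whitney) formulation with ties counted ½, verified against
exhaustive pairwise concordance. Test subjects influence nothing fitted —
permuting their labels changes no coefficient.

The three models differ only in feature supply: **index** uses the one
designated reference CpG per target; **boruta** the confirmed CpGs on
covariate residuals; **boruta.adjusted** the confirmed CpGs on
covariate-plus-haplotype residuals.

## The synthetic world

The generator's defaults state the cohort being emulated: 154 subjects
with 50/154 smokers; ages ~26–28 ± 6 years, about half women, 54%
patients, all smoking-independent by default (a confounding knob exists);
six amplicons with lengths (1342, 1301, 1319, 1304, 1358, 1300) bp and CpG
counts (44, 114, 19, 85, 73, 17); one usable A/G sorting SNP per target at
alt-allele frequency 0.3 (Hardy–Weinberg), one C>T CpG-SNP in the first
target; baseline methylation 0.75; a −1.5 logit smoking effect at 3 CpGs
centred on each index CpG (smoking hypomethylates these loci); a +1.0
logit ASM effect on the alt haplotype at one CpG adjacent to the index in
two targets — ASM variance sitting on a smoking-informative CpG is
precisely the scenario allele adjustment is meant to recover.

Noise has three layers, all needed for realism: (i) per-haplotype Beta
jitter with concentration 30; (ii) a per-subject global baseline shift
(sd 0.5 logit) shared across CpGs, standing in for cell-composition-like
variation; (iii) per-smoker dose heterogeneity (sd 0.75 logit) shared
across smoking CpGs. Without the two subject-level layers every model
saturates at AUC 1.0, which no real methylation cohort of this kind does;
with them prediction is good but imperfect, and the acceptance suite
verifies the median test AUC of the allele-adjusted model exceeds the
index model's by at least 0.02 over 50 seeds — the qualitative regime the
assay reports. Read depth is
negative binomial (mean 17 per haplotype per target, size 6 — about 200
reads per barcode across six targets; the depth distribution's shape is
this package's choice). Reads are full-length amplicons (no fragmenting:
single-molecule consensus reads span whole products), carry substitution
errors only (Q40 consensus reads; indel handling is exercised with
explicitly constructed gapped reads), constant Q40 qualities, exact PCR
duplicates at rate 0.05, and the layout
`bc1 + U1 + insert + revcomp(U1) + revcomp(bc2)` with random strand.
Synthetic amplicons are generated as plus-strand targets; minus-strand
allele collapse is implemented and tested at the type level.

What a green test therefore establishes: the pipeline recovers what this
generator injects (haplotypes, methylation vectors, effects, model
ordering) under the stated noise. What it does not establish: performance
under PCR amplification bias, chimeric reads, indel-rich raw reads,
barcode cross-talk, or population LD structure — none of which the
generator models.

## Numerical and degenerate-input choices

* Threshold comparisons are exactly as documented: strict `< 5%`
  unconverted CpH; inclusive depth ≥ 5, quality ≥ 30, conversion ≥ 0.98.
* Zero-CpH reads pass conversion vacuously but are flagged.
* Constant covariate columns are dropped before residualisation;
  genuinely collinear designs are an error naming the columns.
* A fully missing CpG column is an error naming the CpG (imputation has no
  donor); identical groups in a t test give p = 1; zero-variance groups
  with a nonzero difference give p = 0.
* Duplicate representatives, split membership, Boruta permutations and
  forest resampling are all deterministic under the configured seeds; the
  forest uses its own RNG so results do not depend on R's RNG state.
* Heterozygote averaging is symmetric in the two rows by construction.

## Known limitations

* The real de-duplication procedure is unpublished detail; the
  conservative key here may merge distinct molecules that coincide in
  every called position (survivor counts are therefore a lower bound).
* Single effective phase per target: multi-SNP haplotype reconstruction
  beyond the consolidated sorting call is out of scope.
* The targeted aligner makes no claim of equivalence with genome-wide
  mapping efficiency figures.
* With more than 96 subjects the read simulator requires an explicit
  multi-library barcode plan; the packaged default covers one library.
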