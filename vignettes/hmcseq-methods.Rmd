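---
title: "Methods: gene-body 5hmC quantification, integration and liquid-biopsy scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-body 5hmC quantification, integration and liquid-biopsy scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmcseq)
```

# Scope

`hmcseq` implements an analysis pipeline for 5-hydroxymethylcytosine (5hmC)
enrichment sequencing of prostate tumor tissue and cell-free DNA (cfDNA):

1. gene-body 5hmC quantification (fragment counting, TPM, promoter windows,
   peak annotation, variable-gene selection, PCA/clustering);
2. per-gene linear models quantifying the explanatory value 5hmC adds to
   promoter methylation, copy number and mutation burden for expression;
3. pre-ranked gene set enrichment (GSEA) with a permutation null;
4. reference-panel tissue deconvolution of cfDNA 5hmC profiles and a
   gastrointestinal (GI) lineage-plasticity score;
5. circulating-tumor-DNA (ctDNA) fraction estimation from targeted
   sequencing variant allele fractions (VAF);
6. an elastic-net 5hmC classifier of tumor fraction, quartile-based
   driver-event and TOP2A/EZH2 prognostic scores;
7. Kaplan–Meier and Cox proportional-hazards analyses of those scores.

Patient-level data are access-controlled, so the package ships a
synthetic-cohort generator with known ground truth; every downstream stage
is validated against planted effects, closed-form references, or
brute-force oracles.

# Quantification

**Gene-body counting.** A fragment is counted into every gene body it
overlaps by at least one base pair (multioverlap counting, the convention
for enrichment sequencing where overlapping annotations are common).
Coordinates are BED-style 0-based half-open throughout; 1-based inclusive
inputs are converted once at the boundary, which avoids off-by-one errors
in promoter windows. Gene length is the genomic span (end − start), not
the exonic length, because counts cover the entire gene body. Counting is
implemented as a sorted sweep and is tested against a quadratic all-pairs
scan.

**TPM.** Counts are divided by gene length in kb and rescaled per sample to
sum to $10^6$:
$\mathrm{TPM}_g = \dfrac{c_g/\ell_g}{\sum_{g'} c_{g'}/\ell_{g'}} \times 10^6$.
An all-zero sample is an error (naming the sample) rather than a silent
column of zeros.

**Promoters.** The promoter is −2000/+500 bp around the strand-aware TSS;
the window is truncated at coordinate 0 and is an exact mirror image under
strand reflection. Promoter methylation is the unweighted mean of CpG
methylation fractions inside the window, missing when no CpG falls there.
Copy number is the length-weighted mean of (non-overlapping) segments over
the gene span.

**Peak annotation.** Each peak is classified from its midpoint with the
fixed precedence promoter > exon > intron > downstream > intergenic; the
downstream category extends 3 kb past the strand-aware gene end (the width
is our choice). A fixed precedence on the midpoint makes the assignment a
deterministic partition — category frequencies sum to one per sample by
construction.

**Variable genes and embedding.** The top 10% of genes by across-sample
variance of log2(TPM+1) are selected (ties broken lexicographically by gene
id; zero-variance genes excluded), then median-centered and scaled per gene
(standard deviation with denominator $n-1$; zero-variance genes set to
missing). PCA uses the singular value decomposition; clustering uses
Euclidean distance with Ward (ward.D2) linkage.

# Per-gene expression models

For each gene, scaled log2(TPM+1) expression is regressed by ordinary
least squares on scaled log2(TPM+1) gene-body 5hmC, promoter methylation,
copy number, and SNV/SV counts. Missing samples are removed listwise; a
gene needs at least $p+2$ complete samples. The added value of 5hmC is the
adjusted $R^2$ of the full model minus that of the model refit without the
5hmC term (all other coefficients re-estimated — the standard nested
comparison), and its significance is the partial F-test between the nested
fits, which for a single added regressor equals the squared-t test on the
coefficient (asserted numerically in the tests). Benjamini–Hochberg
correction is applied across genes.

Two numerical choices deserve note. First, z-scaling is computed on the
analysis cohort per gene. Second, predictor columns that are constant in
the complete-case samples (typically SNV/SV counts that are zero
everywhere) are removed before fitting and their coefficients reported as
missing — most genes carry no mutation in a cohort of this size, and
failing every such gene would discard the analysis; a design that remains
rank-deficient after this (true collinearity) flags the gene as missing
rather than silently dropping terms. SNV and SV enter as plain per-gene
counts; a signed activating/inactivating encoding would be a trivial
variant but is not the default since the direction labels are not part of
the data model here.

The synthetic generator builds expression on the log2(TPM+1) scale as
$y_g = \mu_g + \beta_h h_g + \beta_{cn}(CN_g - 2) + \beta_{pm} z(PM_g) +
\beta_{snv}\,SNV_g + \beta_{sv}\,SV_g + \varepsilon,\;
\varepsilon \sim N(0, \sigma^2)$,
with $h_g$ the per-gene z-scored log2(TPM+1) 5hmC signal. Because the
predictors are generated independently, the population $R^2$ gained by the
5hmC term has the closed form $\beta_h^2 / \mathrm{Var}(y)$;
`expected_delta_r2()` returns its average over the two gene classes (with
and without the planted methylation effect), and the recovery test checks
the empirical median against it.

# Pre-ranked GSEA

The enrichment score is the classic weighted Kolmogorov–Smirnov running
sum: walking the ranking in decreasing order of the statistic, set members
add $|s|^p / \sum_{hits}|s|^p$ and non-members subtract $1/(N - N_h)$; the
score is the signed maximum deviation, bounded in $[-1, 1]$. The weight
exponent defaults to 1 (the common default; exponent 0 gives the
unweighted statistic, which is antisymmetric under ranking reversal and
invariant to monotone rescaling — both asserted in tests).

The null is simple gene-label permutation: same-size random sets drawn
from the ranked universe. This estimates the same quantity as adaptive
multilevel samplers at desk scale with far less machinery; `n_perm` is
configurable (minimum 100). The normalized enrichment score divides by the
mean |null ES| of matching sign. The p-value is the standard two-sided
permutation p on |ES| over all permutations with a +1 pseudocount, so its
attainable minimum is exactly $1/(n_{perm}+1)$; conditioning the p-value on
matching-sign permutations would roughly double that floor, and the
package keeps sign-conditioning only for the NES normalization.
The implementation is cross-checked against an independent running-sum
enumeration and against `fgsea`'s score statistic.

# Tissue deconvolution and the GI score

Tissue composition is scored by nonnegative least squares (NNLS) of a
sample profile on a gene-by-tissue reference panel, with weights
normalized to the simplex. This is a stand-in with the same input/output
contract as published 5hmC tissue-map scoring, whose exact algorithm is
external to this package; all validation is against planted mixtures, not
published scores.

Both panel and profile are standardized per gene against the panel (row
mean and standard deviation). A per-gene *affine* transform commutes with
simplex mixtures — $\frac{Aw - m}{s} = \sum_j w_j \frac{A_j - m}{s}$ when
$\sum_j w_j = 1$ — so noise-free mixtures of panel columns are recovered
exactly (to solver tolerance). A log transform would break this
(the log of a mixture is not the mixture of logs), so `log2(x+1)` is
offered as an option for heavy-tailed raw-TPM inputs but is not the
default. Row-centering places the all-ones vector in the panel's null
space, making the mixture weights non-identifiable along the simplex
direction; the solver therefore augments the system with a sum-to-one
constraint row, which restores uniqueness. Collinear (duplicate) tissue
columns trigger a warning and a pseudo-inverse fallback.

The GI score is the sum of the colon, gastric, liver and pancreatic
weights; a sample is GI-positive at score ≥ 0.25 (boundary included).

# ctDNA fraction

Under the conservative assumption of loss of heterozygosity at every
somatic variant, tumor fraction $t$ and VAF are linked by
$\mathrm{VAF} = t/(2-t)$, inverted as $t = 2\,\mathrm{VAF}/(1+\mathrm{VAF})$
— zero at VAF 0, strictly increasing, bounded by 1. The surrogate variant
is the highest-VAF somatic variant excluding amplified genes (copy
log-ratio > 0.2) and allosomes, with ties broken by (chrom, pos). When no
somatic variant qualifies, heterozygous-SNP imbalance in regions of
one-copy loss gives $f = 1/(2-t)$, hence $t = 2 - 1/f$; this inversion is
our model-consistent reconstruction (verified by binomial simulation), not
a published formula. For multi-variant summaries,
`ct_fraction_from_variants()` takes the median of per-variant inversions:
the maximum of many binomial draws is upward-biased at finite depth, while
the median is not — the round-trip recovery test (depth 2000, 50 variants,
absolute error ≤ 0.03) uses the median route, while `estimate_ct()` keeps
the max-VAF surrogate rule for single-sample estimation.

The somatic filters are a pure conjunction (row-order independent): ≥10
unique reads, VAF ≥ 1%, mean mapping quality ≥ 10 for base substitutions
only, VAF ≥ 20× the same-position background error, VAF ≥ 3× the paired
germline allele frequency, leukocyte depth ≥ 20. Manual artifact review is
represented by optional boolean columns honored when present. Germline
variants require ≥8 reads, VAF ≥ 10%, population frequency < 0.5%, and a
frameshift/splice-site/stopgain consequence.

# cfDNA classifiers

**Gene selection.** Genes are tested for correlation between log2(TPM+1)
5hmC and tissue tumor purity; selection requires $p \le 0.05$ together
with Bonferroni $q = \min(1, pG) \le 10^{-5}$. Pearson is the default
(the downstream model is linear); Spearman is available by flag.

**Elastic net.** Tumor fraction is modeled as a penalized linear function
of the selected genes; the mixing parameter is searched over
$\{0.1, 0.5, 0.9\}$ along the glmnet λ path with 5-fold cross-validation
minimizing MSE, with fold assignment derived from the seed so training is
fully reproducible. Predictions are clipped to $[0,1]$; genes missing from
a profile are imputed at their training mean, up to 20%.

**Quartile scores.** Driver events are inferred per sample: an oncogene
(AR, MYC, NCOA2) is gained when its 5hmC count is ≥ the across-sample
upper quartile, a suppressor (RB1, PTEN, TP53, BRCA2, NKX3-1) lost when
≤ the lower quartile, with linear-interpolation quantiles and boundaries
included (both conventions are choices; the flags are invariant to any
strictly monotone per-gene transform, so the TPM/log scale question is
moot). Events sum to 0–8 and are binned 0–1 / 2–3 / >3. The TOP2A/EZH2
class counts top-quartile memberships (none/either/both). Quartile
boundaries are cohort-conditional: adding samples can change flags.

# Survival

Tertile splits use linear-interpolation quantiles with boundary values
assigned to the lower group. Kaplan–Meier curves come from the
product-limit estimator; Cox models use Efron tie handling (the standard
default), Wald confidence intervals and two-sided Wald tests. The
driver-event score enters as a linear term, unadjusted and adjusted for
ct-fraction plus the clinical covariate block.

The survival generator draws exponential event times with hazard
$\lambda_0 \exp(x^\top \beta)$ and uniform administrative censoring. The
hazard-ratio recovery experiments use two balanced arms of 150 samples
with near-complete follow-up (administrative window 360 months at a
baseline hazard of 1/30 per month), so replicate spread reflects the
estimator rather than censoring; at $n = 300$ the attainable coverage of
the interval $[1.6, 2.5]$ around a true hazard ratio of 2 is about 94%.

# What the simulations do and do not show

The generator reproduces the *structure* of the study data — negative
binomial 5hmC counts with length-proportional means and sample library
factors, TPM columns summing to $10^6$, Beta-distributed promoter
methylation anticorrelated with expression for a gene subset, copy-number
dosage, sparse mutation counts, reference-panel cfDNA mixtures with known
tumor fraction, binomial allele counts under LOH, and proportional-hazards
survival. Defaults (93 samples, 1000 genes, effect sizes 0.6/0.3/−0.3,
noise SD 0.5, depth 2000) mirror the cohort scale and moderate effect
sizes of tissue studies of this kind. It does **not** simulate raw reads,
alignment or peak calling, cfDNA fragment-length biology, GC or
mappability bias, correlated gene–gene structure, or clonal heterogeneity;
passing tests demonstrate correctness of the algorithms under the stated
models, not performance on real cohorts. The count distribution of 5hmC
enrichment data is itself a modeling choice (negative binomial), not an
established fact.

Problem sizes in the test-suite and acceptance runs (1000 genes × 93
samples for the integrative models, 200 permutations for null
calibrations, 100–200 survival replicates, 100 mixture draws) were chosen
as the smallest scales at which the Monte-Carlo error is comfortably below
each check's tolerance.

# Known limitations

- The tissue-map stand-in shares only the input/output contract with the
  published scorer; absolute scores are not comparable across methods.
- Peak annotation uses the midpoint only; peaks spanning category borders
  are assigned to one category.
- The somatic filters encode the printed thresholds; site-specific error
  models and manual review are reduced to optional boolean flags.
- `estimate_ct()`'s max-VAF surrogate is upward-biased at low depth; use
  the median combiner when several confident variants are available.
- The elastic-net classifier assumes the training and prediction profiles
  share a common normalization; no cross-platform calibration is applied.
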