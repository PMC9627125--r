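# hmcseq

Analysis toolkit for 5-hydroxymethylcytosine (5hmC) enrichment sequencing
in prostate cancer — from gene-body quantification of tumor tissue to
liquid-biopsy scoring of cell-free DNA (cfDNA).

5hmC is an oxidized cytosine modification enriched in the gene bodies of
actively transcribed genes and highly tissue-specific, which makes it both
a readout of epigenomic activation (which oncogenic programs are switched
on) and a lineage tracer in cfDNA (which tissue the DNA came from). This
package is for computational biologists who want to quantify gene-body
5hmC, ask how much it explains of gene expression beyond methylation and
copy number, and build prognostic cfDNA scores from it.

## What it computes

- **Quantification** — multioverlap fragment counting over gene bodies,
  TPM normalization (`TPM_g = (c_g/ℓ_g) / Σ(c/ℓ) × 10⁶`), −2000/+500 bp
  strand-aware promoter windows, promoter CpG methylation, length-weighted
  gene copy number, midpoint peak annotation (promoter > exon > intron >
  downstream > intergenic), variable-gene selection, PCA and Ward
  clustering.
- **Integration** — per-gene OLS of scaled log₂(TPM+1) expression on
  scaled 5hmC, promoter methylation, copy number and SNV/SV counts; the
  value added by 5hmC is Δ(adjusted R²) between nested fits, tested by
  partial F with Benjamini–Hochberg correction; Spearman correlations per
  data layer.
- **Enrichment** — pre-ranked GSEA (weighted Kolmogorov–Smirnov running
  sum, gene-permutation null, NES, BH FDR).
- **Lineage** — nonnegative-least-squares tissue scores of cfDNA 5hmC
  profiles against a reference panel (simplex-normalized) and the
  gastrointestinal (GI) score = colon + gastric + liver + pancreatic,
  flagged at ≥ 0.25.
- **ctDNA fraction** — somatic/germline variant filters as printed
  (reads ≥ 10, VAF ≥ 1%, ≥ 20× background error, ≥ 3× germline, MAPQ ≥ 10
  for substitutions, leukocyte depth ≥ 20), max-VAF surrogate selection
  excluding amplified genes and allosomes, and the LOH inversion
  `t = 2·VAF/(1+VAF)`, with a heterozygous-loss fallback `t = 2 − 1/f`.
- **cfDNA classifiers** — purity-gene selection (p ≤ 0.05 and Bonferroni
  q ≤ 10⁻⁵), elastic-net tumor-fraction regression, the 8-gene
  driver-event score (AR/MYC/NCOA2 gained at upper quartile; RB1/PTEN/
  TP53/BRCA2/NKX3-1 lost at lower quartile; binned 0–1 / 2–3 / >3) and the
  TOP2A/EZH2 none/either/both class.
- **Survival** — tertile splits, Kaplan–Meier curves, Cox models (Efron
  ties, Wald tests), per-event hazard ratios adjusted for ct-fraction and
  clinical covariates.
- **Synthetic cohorts** — a generator with known ground truth (negative
  binomial 5hmC counts, planted expression effects, tissue-mixture cfDNA,
  binomial allele counts under LOH, proportional-hazards survival) so the
  whole pipeline is testable without patient data.

## Worked example

```r
library(hmcseq)

## a synthetic cohort: 500 genes x 93 samples, half with a planted 5hmC
## effect (beta = 0.6 on the scaled log2 scale)
cfg <- cohort_config(n_genes = 500, n_samples = 93, seed = 42)
coh <- generate_cohort(cfg)

res <- fit_all_genes(coh$bundle)
res$summary
#> $median_adj_r2_with      0.46
#> $median_adj_r2_without   0.0617
#> $n_tested                500
#> $n_significant           253
```

Half the genes were planted, and 253/500 reach FDR < 0.05; the median
adjusted R² rises from 0.06 to 0.46 when 5hmC enters the model. The
planted genes' median Δ(adjusted R²) is 0.561 versus the generator's
closed-form value 0.554 (`expected_delta_r2(cfg)`), and unplanted genes
sit at −0.006 (the adjustment penalty for a useless regressor).

```r
## tissue deconvolution of a noisy cfDNA mixture (true prostate weight 0.55)
panel <- generate_tissue_panel(seed = 1)
prof  <- generate_cfdna_mixture(panel, c(0.55, 0.15, 0.10, 0.10, 0.05, 0.05),
                                noise_sd = 0.5, seed = 2)
sc <- tissue_scores(prof, panel)
round(sc, 3)
#> prostate bone_marrow liver colon gastric pancreatic
#>    0.549       0.149 0.105 0.098   0.051      0.048
gi_score(sc)            # 0.302 -> GI-positive (threshold 0.25)

## ctDNA fraction from simulated targeted sequencing at true ct = 0.4
v <- generate_variant_reads(true_ct = 0.4, depth = 2000, n_variants = 20, seed = 3)
estimate_ct(v)$ct_fraction
#> 0.416   (method "vaf_formula": surrogate max-VAF variant, t = 2*VAF/(1+VAF))
```

The recovered tissue weights are within 0.01 of the truth, the GI score is
the exact four-tissue sum, and the ctDNA fraction lands within 0.02 of the
planted value.

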