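#' Somatic variant filters for targeted cfDNA sequencing
#'
#' Applies the somatic calling rules as a pure conjunction, recording a
#' pass/fail flag per rule and per row: at least 10 unique supporting
#' reads; VAF of at least 1%; for base substitutions, mean mapping quality
#' of at least 10; VAF at least 20-fold above the same-position background
#' error rate; VAF at least 3-fold above the paired germline allele
#' frequency; paired leukocyte depth of at least 20. Optional boolean
#' artifact columns (`artifact_strand_imbalance`, `artifact_end_clustering`,
#' `artifact_low_complexity`), standing in for manual review, fail a row
#' when `TRUE`.
#'
#' @param variants variant data.frame (see [read_variant_table()]) with
#'   columns `unique_read_support`, `vaf`, `mapq_mean`, `background_error`,
#'   `germline_vaf`, `leukocyte_depth`, `ref`, `alt`.
#' @return the input with per-rule `pass_*` columns and a combined `pass`
#'   flag; attribute `"passing"` holds the passing subset.
#' @export
filter_somatic <- function(variants) {
  required <- c("unique_read_support", "vaf", "mapq_mean", "background_error",
                "germline_vaf", "leukocyte_depth", "ref", "alt")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop_format("variant table is missing filter column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  v <- variants
  is_sub <- nchar(v$ref) == 1L & nchar(v$alt) == 1L
  v$pass_reads <- v$unique_read_support >= 10
  v$pass_vaf <- v$vaf >= 0.01
  v$pass_mapq <- !is_sub | v$mapq_mean >= 10
  v$pass_background <- v$vaf >= 20 * v$background_error
  v$pass_germline <- v$vaf >= 3 * v$germline_vaf
  v$pass_leukocyte_depth <- v$leukocyte_depth >= 20
  v$pass_artifact <- TRUE
  for (col in c("artifact_strand_imbalance", "artifact_end_clustering",
                "artifact_low_complexity")) {
    if (col %in% names(v)) v$pass_artifact <- v$pass_artifact & !v[[col]]
  }
  v$pass <- v$pass_reads & v$pass_vaf & v$pass_mapq & v$pass_background &
    v$pass_germline & v$pass_leukocyte_depth & v$pass_artifact
  attr(v, "passing") <- v[v$pass, , drop = FALSE]
  v
}

#' Deleterious germline variant filter
#'
#' Keeps variants with at least 8 unique supporting reads, VAF of at least
#' 10%, population frequency below 0.5%, and a putatively deleterious
#' consequence (frameshift, splice-site or stopgain). Rows with an unknown
#' consequence string are excluded with a warning.
#'
#' @param variants variant data.frame with `unique_read_support`, `vaf`,
#'   `population_freq` and `consequence` columns.
#' @return the deleterious passing subset.
#' @export
filter_germline <- function(variants) {
  required <- c("unique_read_support", "vaf", "population_freq", "consequence")
  missing_cols <- setdiff(required, names(variants))
  if (length(missing_cols) > 0L) {
    stop_format("variant table is missing column(s): %s",
                paste(missing_cols, collapse = ", "))
  }
  known <- c("frameshift", "splice_site", "stopgain", "missense", "synonymous",
             "nonframeshift", "intronic", "utr", "intergenic")
  unknown <- !(variants$consequence %in% known)
  if (any(unknown)) {
    warning(sprintf("excluding %d variant(s) with unknown consequence", sum(unknown)))
    variants <- variants[!unknown, , drop = FALSE]
  }
  keep <- variants$unique_read_support >= 8 &
    variants$vaf >= 0.10 &
    variants$population_freq < 0.005 &
    variants$consequence %in% c("frameshift", "splice_site", "stopgain")
  variants[keep, , drop = FALSE]
}

#' Select the surrogate variant for ctDNA-fraction estimation
#'
#' The surrogate for total ctDNA content is the sample's highest-VAF
#' somatic variant, excluding variants on amplified genes (copy log-ratio
#' > 0.2) and on allosomes. Ties at the maximum VAF break
#' deterministically by (chrom, pos) order.
#'
#' @param variants passing somatic subset with `chrom`, `pos`, `vaf`,
#'   `copy_log_ratio` columns.
#' @return one-row data.frame, or `NULL` if no variant qualifies.
#' @export
select_surrogate <- function(variants) {
  if (is.null(variants) || nrow(variants) == 0L) return(NULL)
  ok <- is_autosome(variants$chrom) & variants$copy_log_ratio <= 0.2
  cand <- variants[ok, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  cand <- cand[order(-cand$vaf, cand$chrom, cand$pos), , drop = FALSE]
  cand[1L, , drop = FALSE]
}

#' ctDNA fraction from a somatic variant allele fraction
#'
#' Assuming loss of heterozygosity at the variant locus (the conservative
#' copy model for a clonal somatic variant), the tumor fraction `t` and the
#' variant allele fraction are related by `VAF = t / (2 - t)`, inverted as
#' `t = 2 / (1 + 1 / VAF) = 2 * VAF / (1 + VAF)`.
#'
#' @param vaf variant allele fraction(s) in `[0, 1]`.
#' @return ctDNA fraction(s) in `[0, 1]`; 0 at `vaf = 0`, strictly
#'   increasing.
#' @export
ct_fraction_from_vaf <- function(vaf) {
  assert_that(is.numeric(vaf) && all(!is.na(vaf)) && all(vaf >= 0 & vaf <= 1),
              "vaf must lie in [0, 1]")
  2 * vaf / (1 + vaf)
}

#' ctDNA fraction from heterozygous-SNP imbalance under one-copy loss
#'
#' In a gene with apparent heterozygous loss in the tumor, the major allele
#' of a germline heterozygous SNP is observed at frequency
#' `f = 1 / (2 - t)` in cfDNA with tumor fraction `t`, giving
#' `t = 2 - 1 / f`, clipped to `[0, 1]`.
#'
#' @param major_allele_freq observed major-allele frequency(ies),
#'   `0.5 <= f < 1`.
#' @return ctDNA fraction(s); 0 at `f = 0.5` (no imbalance).
#' @export
ct_fraction_from_het_loss <- function(major_allele_freq) {
  f <- major_allele_freq
  assert_that(is.numeric(f) && all(!is.na(f)) && all(f >= 0.5 & f < 1),
              "major allele frequency must lie in [0.5, 1)")
  pmin(pmax(2 - 1 / f, 0), 1)
}

#' Combine per-variant ctDNA-fraction estimates
#'
#' Inverts the LOH VAF formula for each variant and takes the median — an
#' estimator robust to the upward bias of the single maximum-VAF variant
#' when many variants are available.
#'
#' @param vafs observed somatic VAFs.
#' @return median ctDNA fraction.
#' @export
ct_fraction_from_variants <- function(vafs) {
  stats::median(ct_fraction_from_vaf(vafs))
}

#' Estimate the ctDNA fraction of a sample
#'
#' Applies the somatic filters, selects the surrogate variant and inverts
#' the LOH VAF formula. Samples without a qualifying somatic variant fall
#' back to heterozygous-SNP imbalance in regions of apparent heterozygous
#' loss when `het_snp_maf` is supplied; otherwise the method is `none` and
#' the fraction is missing.
#'
#' @param variants variant data.frame for one sample (unfiltered).
#' @param het_snp_maf optional major-allele frequencies of heterozygous
#'   SNPs in het-loss genes (fallback route).
#' @return list with `ct_fraction`, `method` (one of `vaf_formula`,
#'   `het_loss_snp`, `none`) and `surrogate` (row or `NULL`).
#' @export
estimate_ct <- function(variants, het_snp_maf = NULL) {
  surrogate <- NULL
  if (!is.null(variants) && nrow(variants) > 0L) {
    flt <- filter_somatic(variants)
    surrogate <- select_surrogate(attr(flt, "passing"))
  }
  if (!is.null(surrogate)) {
    return(list(ct_fraction = ct_fraction_from_vaf(surrogate$vaf),
                method = "vaf_formula", surrogate = surrogate))
  }
  if (!is.null(het_snp_maf) && length(het_snp_maf) > 0L) {
    est <- stats::median(ct_fraction_from_het_loss(het_snp_maf))
    return(list(ct_fraction = est, method = "het_loss_snp", surrogate = NULL))
  }
  list(ct_fraction = NA_real_, method = "none", surrogate = NULL)
}

#' Prostate-cancer driver gene panels reported by targeted cfDNA sequencing
#'
#' The mutation panel (`"mutation"`) and copy-number panel (`"copy_number"`)
#' of driver genes whose somatic or germline status is reported.
#'
#' @param panel which panel to return.
#' @return character vector of gene symbols.
#' @export
driver_gene_panel <- function(panel = c("mutation", "copy_number")) {
  panel <- match.arg(panel)
  switch(panel,
    mutation = c("AKT1", "APC", "AR", "ATM", "BRCA1", "BRCA2", "CDK12",
                 "CTNNB1", "FOXA1", "KMT2C", "KMT2D", "MSH2", "MSH6",
                 "PIK3CA", "PMS2", "PTEN", "RB1", "SPOP", "TP53", "ZFHX3"),
    copy_number = c("AR", "ATM", "BRCA1", "BRCA2", "CCND1", "CDK12", "CHD1",
                    "CLU", "MSH2", "MSH6", "MYC", "NCOA2", "NKX3-1", "PTEN",
                    "RB1", "TP53", "MLH1"))
}
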