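#' Per-gene Spearman correlations of expression with each data layer
#'
#' For every gene, the Spearman rank correlation of expression with gene-body
#' 5hmC, gene copy number and promoter methylation across samples
#' (pairwise-complete). Genes with fewer than `min_n` complete sample pairs,
#' or without variable expression, are reported missing.
#'
#' @param bundle an `omics_bundle` (see [generate_cohort()]): aligned
#'   gene-by-sample matrices `expr`, `tpm_5hmc`, `copy_number`,
#'   `promoter_meth`.
#' @param min_n minimum complete samples per gene (default 3).
#' @return data.frame with `gene_id`, `rho_5hmc`, `rho_cn`, `rho_pm`.
#' @export
per_gene_correlations <- function(bundle, min_n = 3L) {
  genes <- rownames(bundle$expr)
  layer_rho <- function(layer) {
    vapply(seq_along(genes), function(g) {
      x <- bundle$expr[g, ]
      y <- layer[g, ]
      ok <- stats::complete.cases(x, y)
      if (sum(ok) < min_n) return(NA_real_)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok], method = "spearman")
    }, numeric(1L))
  }
  data.frame(gene_id = genes,
             rho_5hmc = layer_rho(bundle$tpm_5hmc),
             rho_cn = layer_rho(bundle$copy_number),
             rho_pm = layer_rho(bundle$promoter_meth),
             stringsAsFactors = FALSE)
}

# OLS of y on X=[1, h, pm, cn, snv, sv]; returns coefficients, adjusted
# R-squared with and without the 5hmC column, and the partial-F p-value of
# the 5hmC term.  Constant non-5hmC predictor columns are removed before
# fitting (their coefficients reported NA); a design still rank-deficient
# after that (true collinearity) flags the gene as missing.
fit_one_gene <- function(y, h, pm, cn, snv, sv) {
  empty <- list(beta_5hmc = NA_real_, beta_pm = NA_real_, beta_cn = NA_real_,
                beta_snv = NA_real_, beta_sv = NA_real_,
                adj_r2_with = NA_real_, adj_r2_without = NA_real_,
                p_5hmc = NA_real_, n = 0L)
  X_all <- cbind(h = h, pm = pm, cn = cn, snv = snv, sv = sv)
  ok <- stats::complete.cases(y, X_all)
  n <- sum(ok)
  if (n < ncol(X_all) + 2L) return(empty)
  y <- y[ok]; X_all <- X_all[ok, , drop = FALSE]
  if (stats::sd(y) == 0 || stats::sd(X_all[, "h"]) == 0) return(empty)
  keep <- c(TRUE, apply(X_all[, -1L, drop = FALSE], 2L,
                        function(v) stats::sd(v) > 0))
  X <- cbind(`(Intercept)` = 1, X_all[, keep, drop = FALSE])
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(empty)

  fit_r2 <- function(Xm) {
    q <- qr(Xm)
    res <- qr.resid(q, y)
    rss <- sum(res^2)
    tss <- sum((y - mean(y))^2)
    list(coef = qr.coef(q, y), rss = rss, r2 = 1 - rss / tss, p = ncol(Xm))
  }
  full <- fit_r2(X)
  red <- fit_r2(X[, colnames(X) != "h", drop = FALSE])
  adj <- function(r2, p) 1 - (1 - r2) * (n - 1) / (n - p)
  f_stat <- (red$rss - full$rss) / (full$rss / (n - full$p))
  p_5hmc <- stats::pf(f_stat, 1, n - full$p, lower.tail = FALSE)
  cf <- stats::setNames(rep(NA_real_, 5L), c("h", "pm", "cn", "snv", "sv"))
  cf[names(full$coef)[-1L]] <- full$coef[-1L]
  list(beta_5hmc = unname(cf["h"]), beta_pm = unname(cf["pm"]),
       beta_cn = unname(cf["cn"]), beta_snv = unname(cf["snv"]),
       beta_sv = unname(cf["sv"]),
       adj_r2_with = adj(full$r2, full$p), adj_r2_without = adj(red$r2, red$p),
       p_5hmc = p_5hmc, n = n)
}

#' Fit the per-gene expression model for one gene
#'
#' Ordinary least squares of scaled `log2(TPM + 1)` expression on scaled
#' `log2(TPM + 1)` gene-body 5hmC, promoter methylation, copy number and
#' SNV/SV counts, with listwise deletion of incomplete samples. The added
#' explanatory value of 5hmC is the adjusted R-squared of the full model
#' versus the model refit without the 5hmC term; its significance is the
#' partial F-test between the two nested fits (equal to the squared-t test
#' on the 5hmC coefficient).
#'
#' @param bundle an `omics_bundle`.
#' @param gene_id gene to fit.
#' @return one-row data.frame with coefficients, `adj_r2_with`,
#'   `adj_r2_without`, `p_5hmc`, `n`.
#' @export
fit_expression_model <- function(bundle, gene_id) {
  assert_that(gene_id %in% rownames(bundle$expr), "unknown gene '%s'", gene_id)
  fits <- fit_all_genes(bundle, genes = gene_id)
  fits$fits
}

#' Fit per-gene expression models across the cohort
#'
#' Runs [fit_expression_model()] for every gene, applies
#' Benjamini-Hochberg correction to the 5hmC partial-F p-values across all
#' tested genes, and summarizes the cohort: median adjusted R-squared with
#' and without 5hmC and the number of genes whose fit 5hmC significantly
#' improves at FDR 0.05.
#'
#' @param bundle an `omics_bundle`.
#' @param genes optional subset of gene ids (default all).
#' @param fdr FDR threshold for the significant-gene count.
#' @return list with `fits` (one row per gene, including `q_5hmc`) and
#'   `summary` (medians and `n_significant`).
#' @export
fit_all_genes <- function(bundle, genes = NULL, fdr = 0.05) {
  genes <- genes %||% rownames(bundle$expr)
  y_all <- zscore_rows(log2p1(bundle$expr[genes, , drop = FALSE]))
  h_all <- zscore_rows(log2p1(bundle$tpm_5hmc[genes, , drop = FALSE]))
  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    fit_one_gene(y_all[i, ], h_all[i, ],
                 bundle$promoter_meth[g, ], bundle$copy_number[g, ],
                 bundle$snv_count[g, ], bundle$sv_count[g, ])
  })
  fits <- do.call(rbind, lapply(rows, as.data.frame))
  fits <- cbind(gene_id = genes, fits, stringsAsFactors = FALSE)
  fits$q_5hmc <- NA_real_
  tested <- !is.na(fits$p_5hmc)
  fits$q_5hmc[tested] <- stats::p.adjust(fits$p_5hmc[tested], method = "BH")
  summary <- list(
    median_adj_r2_with = stats::median(fits$adj_r2_with, na.rm = TRUE),
    median_adj_r2_without = stats::median(fits$adj_r2_without, na.rm = TRUE),
    n_tested = sum(tested),
    n_significant = sum(fits$q_5hmc < fdr, na.rm = TRUE))
  list(fits = fits, summary = summary)
}

#' Compare scaled 5hmC coefficients between a gene set and the rest
#'
#' Two-sided Wilcoxon rank-sum test of the fitted 5hmC coefficients of the
#' genes in `gene_set` against all other fitted genes.
#'
#' @param fits the `fits` table from [fit_all_genes()].
#' @param gene_set character vector of gene ids.
#' @return list with `median_in`, `median_out`, `n_in`, `n_out`, `p`.
#' @export
coefficient_group_test <- function(fits, gene_set) {
  assert_that(length(gene_set) > 0, "gene_set must be nonempty")
  ok <- !is.na(fits$beta_5hmc)
  in_set <- ok & fits$gene_id %in% gene_set
  out_set <- ok & !fits$gene_id %in% gene_set
  if (!any(in_set)) stop_format("gene_set does not overlap fitted genes")
  if (!any(out_set)) stop_format("gene_set leaves no complement genes")
  w <- stats::wilcox.test(fits$beta_5hmc[in_set], fits$beta_5hmc[out_set],
                          alternative = "two.sided", exact = FALSE)
  list(median_in = stats::median(fits$beta_5hmc[in_set]),
       median_out = stats::median(fits$beta_5hmc[out_set]),
       n_in = sum(in_set), n_out = sum(out_set), p = w$p.value)
}
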