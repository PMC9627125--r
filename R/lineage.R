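#' Tissue-composition scores of a 5hmC profile
#'
#' Scores the similarity of a sample 5hmC profile to each tissue of a
#' reference panel by nonnegative least squares: after per-gene affine
#' standardization against the panel (subtracting the panel row mean and
#' dividing by the panel row standard deviation — a transform that commutes
#' with simplex mixtures, so noise-free mixtures of panel columns are
#' recovered exactly), the profile is regressed on the panel columns under
#' a nonnegativity constraint and the weights are normalized to the
#' simplex. `log2p1 = TRUE` additionally applies `log2(x + 1)` to panel and
#' profile first, for heavy-tailed raw-TPM inputs.
#'
#' @param profile named numeric vector (one sample) or gene-by-sample
#'   matrix of 5hmC levels on the panel's scale.
#' @param panel gene-by-tissue reference matrix.
#' @param min_genes minimum shared genes required (default 50).
#' @param log2p1 apply `log2(x + 1)` to both inputs before standardizing.
#' @return named score vector over tissues (simplex), or a
#'   sample-by-tissue matrix for matrix input.
#' @export
tissue_scores <- function(profile, panel, min_genes = 50L, log2p1 = FALSE) {
  if (is.matrix(profile)) {
    out <- t(apply(profile, 2L, tissue_scores, panel = panel,
                   min_genes = min_genes, log2p1 = log2p1))
    colnames(out) <- colnames(panel)
    return(out)
  }
  shared <- intersect(names(profile), rownames(panel))
  assert_that(length(shared) >= min_genes,
              "profile and panel share only %d genes (need >= %d)",
              length(shared), min_genes)
  A <- panel[shared, , drop = FALSE]
  b <- profile[shared]
  if (log2p1) {
    A <- log2(A + 1)
    b <- log2(b + 1)
  }
  mu <- rowMeans(A)
  sdv <- apply(A, 1L, stats::sd)
  keep <- sdv > 0
  A <- (A[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  b <- (b[keep] - mu[keep]) / sdv[keep]
  # Row-centering makes the all-ones direction a null vector of A (simplex
  # mixtures are consistent but non-identifiable); a sum-to-one constraint
  # row pins that direction, making noise-free mixtures uniquely recoverable.
  lambda <- sqrt(nrow(A))
  A_aug <- rbind(A, lambda)
  b_aug <- c(as.numeric(b), lambda)
  if (qr(A_aug)$rank < ncol(A_aug)) {
    warning("degenerate tissue panel (collinear columns); pseudo-inverse fallback")
    w <- pmax(as.numeric(pracma::pinv(A_aug) %*% b_aug), 0)
  } else {
    w <- pracma::lsqnonneg(A_aug, b_aug)$x
  }
  if (sum(w) == 0) w <- rep(1 / ncol(panel), ncol(panel))
  stats::setNames(w / sum(w), colnames(panel))
}

GI_TISSUES <- c("colon", "gastric", "liver", "pancreatic")

#' Gastrointestinal lineage score
#'
#' Sum of the tissue scores in colon, gastric, liver and pancreatic tissue —
#' a readout of gastrointestinal lineage plasticity in prostate cancer.
#'
#' @param scores named score vector (one sample) or sample-by-tissue matrix
#'   from [tissue_scores()].
#' @return numeric GI score(s) in `[0, 1]`.
#' @export
gi_score <- function(scores) {
  if (is.matrix(scores)) {
    missing_t <- setdiff(GI_TISSUES, colnames(scores))
    if (length(missing_t) > 0L) {
      stop_format("panel lacks GI tissue(s): %s", paste(missing_t, collapse = ", "))
    }
    return(rowSums(scores[, GI_TISSUES, drop = FALSE]))
  }
  missing_t <- setdiff(GI_TISSUES, names(scores))
  if (length(missing_t) > 0L) {
    stop_format("panel lacks GI tissue(s): %s", paste(missing_t, collapse = ", "))
  }
  sum(scores[GI_TISSUES])
}

#' Classify samples as GI-positive
#'
#' A sample is flagged GI-positive when its GI score reaches the threshold
#' (boundary included: score >= threshold).
#'
#' @param score GI score(s) from [gi_score()].
#' @param threshold classification threshold (default 0.25).
#' @return logical flag(s).
#' @export
classify_gi <- function(score, threshold = 0.25) {
  assert_that(is_fraction(score), "GI scores must lie in [0, 1]")
  score >= threshold
}

#' Enrichment of a gene set among genes tracking the GI score
#'
#' Ranks genes by the Spearman correlation of their expression with the
#' per-sample GI score and tests a gene set for enrichment in that ranking
#' with [gsea_preranked()].
#'
#' @param gi_scores named per-sample GI scores.
#' @param expr gene-by-sample expression matrix on the same samples.
#' @param gene_set character vector of genes (e.g. a GI transcriptional
#'   signature).
#' @param n_perm,seed passed to [gsea_preranked()].
#' @return list with `rho` (named per-gene correlations) and `enrichment`
#'   (one-row GSEA result).
#' @export
gi_expression_concordance <- function(gi_scores, expr, gene_set,
                                      n_perm = 1000L, seed = 1L) {
  shared <- intersect(names(gi_scores), colnames(expr))
  assert_that(length(shared) >= 3L, "need >= 3 shared samples")
  g <- gi_scores[shared]
  if (stats::sd(g) == 0) stop_format("GI score is constant; correlations undefined")
  e <- expr[, shared, drop = FALSE]
  rho <- apply(e, 1L, function(x) {
    if (stats::sd(x) == 0) return(NA_real_)
    stats::cor(x, g, method = "spearman")
  })
  rho <- rho[!is.na(rho)]
  enr <- gsea_preranked(rho, list(gi_set = gene_set), n_perm = n_perm,
                        seed = seed)
  list(rho = rho, enrichment = enr)
}
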