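#' Select genes correlated with tumor cell content
#'
#' Per-gene correlation test of `log2(TPM + 1)` 5hmC gene-body counts
#' against tissue tumor purity; genes pass at p <= 0.05 together with a
#' Bonferroni-adjusted q <= 1e-5 (`q = min(1, p * G)`).
#'
#' @param tpm_5hmc gene-by-sample 5hmC TPM matrix.
#' @param purity per-sample tumor purity fractions (aligned with columns).
#' @param method correlation test: `"pearson"` (default; the downstream
#'   model is linear) or `"spearman"`.
#' @param p_threshold,q_threshold selection thresholds.
#' @return character vector of selected gene ids.
#' @export
select_ct_genes <- function(tpm_5hmc, purity, method = c("pearson", "spearman"),
                            p_threshold = 0.05, q_threshold = 1e-5) {
  method <- match.arg(method)
  assert_that(length(purity) == ncol(tpm_5hmc),
              "purity must have one value per sample")
  assert_that(sum(!is.na(purity)) >= 10L, "need >= 10 samples with purity")
  if (stats::sd(purity, na.rm = TRUE) == 0) {
    stop_format("purity is constant; correlation undefined")
  }
  x <- log2p1(tpm_5hmc)
  G <- nrow(x)
  p <- apply(x, 1L, function(row) {
    if (stats::sd(row, na.rm = TRUE) == 0) return(NA_real_)
    stats::cor.test(row, purity, method = method, exact = FALSE)$p.value
  })
  q <- pmin(1, p * G)
  rownames(tpm_5hmc)[which(p <= p_threshold & q <= q_threshold)]
}

#' Train the elastic-net ctDNA-fraction classifier
#'
#' Linear model with elastic-net regularization of tumor purity on
#' `log2(TPM + 1)` 5hmC counts of the selected genes. The penalty mix
#' `alpha` and strength `lambda` are chosen by k-fold cross-validation
#' (minimum CV mean-squared error) over `alpha_grid` and the glmnet lambda
#' path; fold assignment is derived from `seed`, so training is
#' deterministic.
#'
#' @param tpm_5hmc gene-by-sample TPM matrix restricted to selected genes
#'   (see [select_ct_genes()]).
#' @param purity per-sample training target in `[0, 1]`.
#' @param folds number of CV folds.
#' @param seed integer RNG seed.
#' @param alpha_grid elastic-net mixing values to search.
#' @return object of class `ct_classifier`: `genes`, `coefficients`,
#'   `intercept`, `gene_means` (for imputation), `alpha`, `lambda`, `seed`.
#' @export
train_ct_model <- function(tpm_5hmc, purity, folds = 5L, seed = 1L,
                           alpha_grid = c(0.1, 0.5, 0.9)) {
  assert_that(nrow(tpm_5hmc) >= 1L, "no selected genes to train on")
  n <- ncol(tpm_5hmc)
  assert_that(n >= folds, "fewer samples than folds")
  x <- t(log2p1(tpm_5hmc))
  set.seed(seed)
  foldid <- sample(rep(seq_len(folds), length.out = n))
  best <- NULL
  for (a in alpha_grid) {
    cv <- glmnet::cv.glmnet(x, purity, alpha = a, foldid = foldid,
                            family = "gaussian")
    cvm <- min(cv$cvm)
    if (is.null(best) || cvm < best$cvm) {
      best <- list(cv = cv, alpha = a, cvm = cvm)
    }
  }
  cf <- as.numeric(stats::coef(best$cv, s = "lambda.min"))
  model <- list(genes = rownames(tpm_5hmc),
                coefficients = stats::setNames(cf[-1L], rownames(tpm_5hmc)),
                intercept = cf[1L],
                gene_means = rowMeans(log2p1(tpm_5hmc)),
                alpha = best$alpha,
                lambda = best$cv$lambda.min,
                folds = folds, seed = seed)
  class(model) <- "ct_classifier"
  model
}

#' Predict the ctDNA fraction of a cfDNA 5hmC profile
#'
#' Linear prediction from a trained [train_ct_model()] classifier, clipped
#' to `[0, 1]`. Model genes missing from the profile are imputed at their
#' training mean; more than 20% missing is an error.
#'
#' @param model a `ct_classifier`.
#' @param profile named vector (TPM scale) or gene-by-sample matrix.
#' @return predicted fraction(s) in `[0, 1]`.
#' @export
predict_ct <- function(model, profile) {
  if (is.matrix(profile)) {
    return(apply(profile, 2L, predict_ct, model = model))
  }
  x <- stats::setNames(model$gene_means, model$genes)
  present <- intersect(model$genes, names(profile))
  frac_missing <- 1 - length(present) / length(model$genes)
  if (frac_missing > 0.2) {
    stop_format("%.0f%% of model genes missing from profile (max 20%%)",
                100 * frac_missing)
  }
  x[present] <- log2p1(profile[present])
  pred <- model$intercept + sum(model$coefficients * x)
  min(max(pred, 0), 1)
}

#' Serialize / load a ctDNA-fraction classifier as JSON
#'
#' @param model a `ct_classifier`.
#' @param path JSON file path.
#' @return `write_ct_model` returns `path` invisibly; `read_ct_model`
#'   returns the `ct_classifier`.
#' @export
write_ct_model <- function(model, path) {
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ct_model
#' @export
read_ct_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$coefficients <- stats::setNames(as.numeric(raw$coefficients), raw$genes)
  raw$gene_means <- stats::setNames(as.numeric(raw$gene_means), raw$genes)
  class(raw) <- "ct_classifier"
  raw
}

ONCOGENES <- c("AR", "MYC", "NCOA2")
SUPPRESSORS <- c("RB1", "PTEN", "TP53", "BRCA2", "NKX3-1")

quartile_flags <- function(mat, upper) {
  apply(mat, 1L, function(x) {
    q <- stats::quantile(x, probs = if (upper) 0.75 else 0.25, names = FALSE)
    if (upper) x >= q else x <= q
  })  # sample-by-gene logical matrix
}

#' Driver-event score from cfDNA 5hmC gene-body counts
#'
#' Infers gain/loss events of the eight most commonly altered prostate
#' cancer driver genes from 5hmC levels: an oncogene (AR, MYC, NCOA2)
#' counts as gained when its 5hmC gene-body count is in the upper quartile
#' across samples, a tumor-suppressor gene (RB1, PTEN, TP53, BRCA2,
#' NKX3-1) as lost when in the lowest quartile (boundaries included;
#' linear-interpolation quantiles). Events are summed per sample (0-8) and
#' binned 0-1 / 2-3 / >3.
#'
#' @param tpm_5hmc gene-by-sample 5hmC matrix containing all eight genes.
#' @return data.frame with `sample_id`, per-gene event flags, `events` and
#'   `bin`.
#' @export
driver_event_score <- function(tpm_5hmc) {
  need <- c(ONCOGENES, SUPPRESSORS)
  missing_g <- setdiff(need, rownames(tpm_5hmc))
  if (length(missing_g) > 0L) {
    stop_format("matrix lacks driver gene(s): %s", paste(missing_g, collapse = ", "))
  }
  up <- quartile_flags(tpm_5hmc[ONCOGENES, , drop = FALSE], upper = TRUE)
  lo <- quartile_flags(tpm_5hmc[SUPPRESSORS, , drop = FALSE], upper = FALSE)
  flags <- cbind(up, lo)
  events <- rowSums(flags)
  bin <- cut(events, breaks = c(-Inf, 1, 3, Inf),
             labels = c("0-1", "2-3", ">3"), right = TRUE)
  data.frame(sample_id = colnames(tpm_5hmc), flags, events = events,
             bin = bin, check.names = FALSE, stringsAsFactors = FALSE)
}

#' TOP2A/EZH2 activity class from cfDNA 5hmC
#'
#' Classifies each sample by top-quartile membership (across samples,
#' boundary included) of the 5hmC gene-body levels of TOP2A and EZH2:
#' `none`, `either` or `both`.
#'
#' @param tpm_5hmc gene-by-sample matrix containing `TOP2A` and `EZH2`.
#' @param genes the two classifier genes.
#' @return factor of class labels per sample.
#' @export
top2a_ezh2_class <- function(tpm_5hmc, genes = c("TOP2A", "EZH2")) {
  missing_g <- setdiff(genes, rownames(tpm_5hmc))
  if (length(missing_g) > 0L) {
    stop_format("matrix lacks gene(s): %s", paste(missing_g, collapse = ", "))
  }
  up <- quartile_flags(tpm_5hmc[genes, , drop = FALSE], upper = TRUE)
  n_top <- rowSums(up)
  stats::setNames(factor(c("none", "either", "both")[n_top + 1L],
                         levels = c("none", "either", "both")),
                  colnames(tpm_5hmc))
}
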