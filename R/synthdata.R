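#' Configuration for a synthetic multi-omic cohort
#'
#' Bundles the generative parameters for [generate_cohort()]. Expression is
#' produced on the `log2(TPM + 1)` scale as a linear combination of the
#' per-gene z-scored 5hmC signal, copy-number dosage, z-scored promoter
#' methylation and mutation indicators, plus Gaussian noise.
#'
#' @param n_genes number of genes (>= 10).
#' @param n_samples number of samples.
#' @param frac_5hmc_coupled fraction of genes with a planted 5hmC effect.
#' @param frac_pm_coupled fraction of genes with a planted (negative)
#'   promoter-methylation effect.
#' @param beta_5hmc,beta_cn,beta_pm,beta_snv,beta_sv planted effect sizes on
#'   the scaled predictors (`beta_pm` is conventionally negative:
#'   promoter methylation represses expression).
#' @param nb_dispersion negative-binomial dispersion of the raw 5hmC counts
#'   (variance = mu + dispersion * mu^2); must be > 0.
#' @param cn_sd standard deviation of copy number around the diploid 2.
#' @param snv_rate,sv_rate Poisson rates of per-gene mutation counts.
#' @param noise_sd residual standard deviation of expression on the
#'   `log2(TPM + 1)` scale.
#' @param survival_baseline_hazard baseline event rate per month for
#'   [generate_survival()].
#' @param planted_log_hr named numeric vector of log hazard ratios per
#'   covariate for [generate_survival()].
#' @param seed integer RNG seed; every generated object is deterministic
#'   given the seed.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_genes = 1000, n_samples = 93,
                          frac_5hmc_coupled = 0.5, frac_pm_coupled = 0.3,
                          beta_5hmc = 0.6, beta_cn = 0.3, beta_pm = -0.3,
                          beta_snv = 0.2, beta_sv = -0.2,
                          nb_dispersion = 0.5, cn_sd = 0.4,
                          snv_rate = 0.02, sv_rate = 0.01,
                          noise_sd = 0.5,
                          survival_baseline_hazard = 1 / 30,
                          planted_log_hr = c(ct_fraction = log(2)),
                          seed = 1L) {
  assert_that(is_count(n_genes, min = 10L), "n_genes must be an integer >= 10")
  assert_that(is_count(n_samples, min = 3L), "n_samples must be an integer >= 3")
  assert_that(is_fraction(frac_5hmc_coupled) && length(frac_5hmc_coupled) == 1L,
              "frac_5hmc_coupled must be a fraction in [0, 1]")
  assert_that(is_fraction(frac_pm_coupled) && length(frac_pm_coupled) == 1L,
              "frac_pm_coupled must be a fraction in [0, 1]")
  assert_that(is.numeric(nb_dispersion) && nb_dispersion > 0,
              "nb_dispersion must be > 0")
  assert_that(is.numeric(noise_sd) && noise_sd >= 0, "noise_sd must be >= 0")
  cfg <- list(n_genes = as.integer(n_genes), n_samples = as.integer(n_samples),
              frac_5hmc_coupled = frac_5hmc_coupled,
              frac_pm_coupled = frac_pm_coupled,
              beta_5hmc = beta_5hmc, beta_cn = beta_cn, beta_pm = beta_pm,
              beta_snv = beta_snv, beta_sv = beta_sv,
              nb_dispersion = nb_dispersion, cn_sd = cn_sd,
              snv_rate = snv_rate, sv_rate = sv_rate, noise_sd = noise_sd,
              survival_baseline_hazard = survival_baseline_hazard,
              planted_log_hr = planted_log_hr, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' Analytic added explained variance of the 5hmC term
#'
#' Under the generative model of [generate_cohort()] with independent
#' predictors, the population R-squared gained by adding the (unit-variance)
#' 5hmC term equals `beta_5hmc^2` divided by the total expression variance.
#' Used as the closed-form reference for recovery checks of the per-gene
#' expression models.
#'
#' A gene carrying the planted methylation effect (a random
#' `frac_pm_coupled` subset) has a larger total variance, hence a smaller
#' 5hmC share; the returned value is the mixture average over the two gene
#' classes, the expectation for a random 5hmC-coupled gene.
#'
#' @param config a [cohort_config()].
#' @return expected delta R-squared for a 5hmC-coupled gene.
#' @export
expected_delta_r2 <- function(config) {
  base <- config$beta_5hmc^2 +
    config$beta_cn^2 * config$cn_sd^2 +
    config$beta_snv^2 * config$snv_rate +
    config$beta_sv^2 * config$sv_rate +
    config$noise_sd^2
  with_pm <- config$beta_5hmc^2 / (base + config$beta_pm^2)  # meth enters z-scored
  without_pm <- config$beta_5hmc^2 / base
  config$frac_pm_coupled * with_pm +
    (1 - config$frac_pm_coupled) * without_pm
}

#' Generate a synthetic multi-omic cohort with known ground truth
#'
#' Draws raw gene-body 5hmC counts from a negative binomial with
#' length-proportional means and sample-specific library size factors,
#' normalizes to TPM, and builds expression on the `log2(TPM + 1)` scale as
#' a linear model of the per-gene z-scored 5hmC signal, copy-number dosage,
#' z-scored promoter methylation (Beta-distributed) and Poisson SNV/SV
#' counts, plus Gaussian noise. A configurable gene subset carries the
#' planted 5hmC effect; a second subset carries the negative methylation
#' effect. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return list with `genes` (a `gene_model`), `bundle` (an `omics_bundle`
#'   list of aligned matrices `tpm_5hmc`, `expr`, `promoter_meth`,
#'   `copy_number`, `snv_count`, `sv_count` plus `sample_meta`) and `truth`
#'   (per-gene planted coefficients, coupled gene ids, the analytic delta
#'   R-squared, and per-sample tumor purity).
#' @export
generate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"), "config must be a cohort_config")
  set.seed(config$seed)
  G <- config$n_genes
  N <- config$n_samples
  gene_id <- sprintf("G%05d", seq_len(G))
  sample_id <- sprintf("S%03d", seq_len(N))

  lengths <- round(10^stats::runif(G, 3.2, 5))      # ~1.6 kb .. 100 kb spans
  chrom <- sample(AUTOSOMES, G, replace = TRUE)
  start <- round(stats::runif(G, 1e4, 1e8))
  strand <- sample(c("+", "-"), G, replace = TRUE)
  genes <- as_gene_model(data.frame(
    gene_id = gene_id, chrom = chrom, start = start, end = start + lengths,
    strand = strand, biotype = "protein_coding", stringsAsFactors = FALSE))

  # raw 5hmC counts: NB, mean proportional to span and library size factor
  size_factor <- exp(stats::rnorm(N, 0, 0.2))
  gene_rate <- exp(stats::rnorm(G, 0, 0.7))         # biological enrichment level
  mu <- outer(gene_rate * lengths / 1000, size_factor) * 20
  counts <- matrix(stats::rnbinom(G * N, mu = mu, size = 1 / config$nb_dispersion),
                   nrow = G, dimnames = list(gene_id, sample_id))
  tpm_5hmc <- tpm_normalize(counts, genes$length)
  h <- zscore_rows(log2p1(tpm_5hmc))
  h[is.na(h)] <- 0

  copy_number <- matrix(pmax(0, 2 + stats::rnorm(G * N, 0, config$cn_sd)),
                        nrow = G, dimnames = list(gene_id, sample_id))
  pm <- matrix(stats::rbeta(G * N, 2, 5), nrow = G,
               dimnames = list(gene_id, sample_id))
  pm_z <- zscore_rows(pm)
  snv <- matrix(stats::rpois(G * N, config$snv_rate), nrow = G,
                dimnames = list(gene_id, sample_id))
  sv <- matrix(stats::rpois(G * N, config$sv_rate), nrow = G,
               dimnames = list(gene_id, sample_id))

  n_coupled <- round(config$frac_5hmc_coupled * G)
  coupled <- gene_id[seq_len(n_coupled)]
  beta_h <- ifelse(gene_id %in% coupled, config$beta_5hmc, 0)
  n_pm <- round(config$frac_pm_coupled * G)
  pm_coupled <- if (n_pm > 0) sample(gene_id, n_pm) else character(0)
  beta_pm_g <- ifelse(gene_id %in% pm_coupled, config$beta_pm, 0)

  baseline <- stats::runif(G, 3, 8)
  expr_log <- baseline +
    beta_h * h +
    config$beta_cn * (copy_number - 2) +
    beta_pm_g * pm_z +
    config$beta_snv * snv + config$beta_sv * sv +
    matrix(stats::rnorm(G * N, 0, config$noise_sd), nrow = G)
  expr_tpm <- pmax(2^expr_log - 1, 0)
  expr_tpm <- sweep(expr_tpm, 2L, colSums(expr_tpm), "/") * 1e6
  dimnames(expr_tpm) <- list(gene_id, sample_id)

  purity <- stats::runif(N, 0.1, 0.9)
  sample_meta <- data.frame(
    sample_id = sample_id,
    state = sample(c("mCRPC", "localized"), N, replace = TRUE, prob = c(0.7, 0.3)),
    tumor_purity = purity,
    t2e = stats::runif(N) < 0.45,
    t_scnc = stats::runif(N) < 0.05,
    stringsAsFactors = FALSE)

  bundle <- structure(list(
    tpm_5hmc = tpm_5hmc, expr = expr_tpm, promoter_meth = pm,
    copy_number = copy_number, snv_count = snv, sv_count = sv,
    sample_meta = sample_meta), class = "omics_bundle")

  truth <- list(beta_5hmc = stats::setNames(beta_h, gene_id),
                beta_pm = stats::setNames(beta_pm_g, gene_id),
                coupled_genes = coupled, pm_coupled_genes = pm_coupled,
                delta_r2 = expected_delta_r2(config),
                tumor_purity = stats::setNames(purity, sample_id))
  list(genes = genes, bundle = bundle, truth = truth)
}

#' Generate a synthetic cfDNA 5hmC profile from tissue mixtures
#'
#' Mixes reference tissue columns with the given simplex weights and adds
#' truncated Gaussian noise: `profile = panel %*% weights + noise`, floored
#' at zero. Deterministic given `seed`.
#'
#' @param panel gene-by-tissue reference matrix.
#' @param weights nonnegative weights, one per tissue, summing to 1.
#' @param noise_sd Gaussian noise standard deviation (same units as panel).
#' @param seed integer RNG seed.
#' @return named numeric profile vector over panel genes.
#' @export
generate_cfdna_mixture <- function(panel, weights, noise_sd = 0, seed = 1L) {
  assert_that(length(weights) == ncol(panel),
              "weights length must equal panel tissue count")
  assert_that(all(weights >= 0), "weights must be nonnegative")
  assert_that(abs(sum(weights) - 1) <= 1e-9, "weights must sum to 1")
  set.seed(seed)
  profile <- as.numeric(panel %*% weights)
  if (noise_sd > 0) profile <- profile + stats::rnorm(nrow(panel), 0, noise_sd)
  stats::setNames(pmax(profile, 0), rownames(panel))
}

#' Simulate targeted-sequencing read support at somatic variants
#'
#' Draws alt read counts binomially at the expected variant allele fraction
#' under the stated copy model: with loss of heterozygosity (LOH) the
#' expected VAF of a clonal somatic variant at tumor fraction `t` is
#' `t / (2 - t)`; without LOH it is `t / 2`. Besides the true somatic
#' variants, the table carries decoys that the surrogate-selection rule must
#' exclude: variants on amplified genes (copy log-ratio > 0.2, inflated VAF)
#' and on allosomes. All filter columns required by [filter_somatic()] are
#' populated. Deterministic given `seed`.
#'
#' @param true_ct true circulating-tumor fraction in `[0, 1]`.
#' @param depth sequencing depth per variant (>= 1).
#' @param loh logical; assume LOH at every variant.
#' @param n_variants number of true somatic variants.
#' @param seed integer RNG seed.
#' @param background_error per-position background error rate.
#' @return variant data.frame with a `truth` column marking
#'   `somatic` / `decoy_amplified` / `decoy_allosome` rows.
#' @export
generate_variant_reads <- function(true_ct, depth, loh = TRUE,
                                   n_variants = 50L, seed = 1L,
                                   background_error = 5e-4) {
  assert_that(is_fraction(true_ct) && length(true_ct) == 1L,
              "true_ct must be a fraction in [0, 1]")
  assert_that(is_count(depth), "depth must be a positive integer")
  set.seed(seed)
  exp_vaf <- if (loh) true_ct / (2 - true_ct) else true_ct / 2
  n_dec <- 4L
  n <- n_variants + n_dec
  truth <- c(rep("somatic", n_variants), "decoy_amplified", "decoy_amplified",
             "decoy_allosome", "decoy_allosome")
  p <- c(rep(exp_vaf, n_variants),
         rep(min(1, exp_vaf * 1.6 + 0.05), 2L),   # amplification inflates VAF
         rep(min(1, exp_vaf * 1.4 + 0.05), 2L))   # single-X allosome inflates VAF
  p <- pmin(1, p + background_error)
  alt <- stats::rbinom(n, depth, p)
  chrom <- c(sample(AUTOSOMES, n_variants + 2L, replace = TRUE),
             rep("chrX", 2L))
  data.frame(
    chrom = chrom,
    pos = sort(sample.int(1e8, n)),
    ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    alt = sample(c("A", "C", "G", "T"), n, replace = TRUE),
    unique_read_support = alt,
    vaf = alt / depth,
    depth = depth,
    mapq_mean = 60,
    background_error = background_error,
    germline_vaf = 0,
    leukocyte_depth = 100L,
    gene = sprintf("GENE%03d", seq_len(n)),
    copy_log_ratio = c(rep(0, n_variants), 0.5, 0.5, 0, 0),
    consequence = "missense",
    population_freq = 0,
    truth = truth,
    sample_id = "S001",
    stringsAsFactors = FALSE)
}

#' Simulate survival times under a proportional-hazards model
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(X %*% log_hr)`; censoring is uniform over an
#' administrative window `[0, admin_months]`.
#'
#' @param covariates data.frame or matrix of per-sample covariates.
#' @param log_hr named log hazard ratios for (a subset of) the covariate
#'   columns.
#' @param baseline_hazard events per month at covariates zero.
#' @param admin_months administrative censoring window in months.
#' @param seed integer RNG seed.
#' @return data.frame with `time` (months), `event` (1 = death,
#'   0 = censored) and the covariates, plus a `true_hazard` column.
#' @export
generate_survival <- function(covariates, log_hr,
                              baseline_hazard = 1 / 30,
                              admin_months = 120, seed = 1L) {
  covariates <- as.data.frame(covariates)
  assert_that(all(names(log_hr) %in% names(covariates)),
              "log_hr names must match covariate columns")
  set.seed(seed)
  n <- nrow(covariates)
  lp <- as.matrix(covariates[, names(log_hr), drop = FALSE]) %*% log_hr
  hazard <- baseline_hazard * exp(as.numeric(lp))
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, admin_months)
  data.frame(time = pmin(t_event, t_cens),
             event = as.integer(t_event <= t_cens),
             true_hazard = hazard, covariates,
             stringsAsFactors = FALSE)
}

#' Generate a tissue reference panel for mixture experiments
#'
#' Log-normal reference profiles over a default six tissues with a planted
#' block of tissue-specific marker genes per tissue so columns are well
#' separated (as tissue-specific 5hmC profiles are).
#'
#' @param n_genes number of panel genes.
#' @param tissues tissue labels.
#' @param seed integer RNG seed.
#' @return gene-by-tissue nonnegative matrix.
#' @export
generate_tissue_panel <- function(n_genes = 200L,
                                  tissues = c("prostate", "bone_marrow",
                                              "liver", "colon", "gastric",
                                              "pancreatic"),
                                  seed = 1L) {
  set.seed(seed)
  k <- length(tissues)
  panel <- matrix(exp(stats::rnorm(n_genes * k, 2, 0.5)), nrow = n_genes,
                  dimnames = list(sprintf("G%05d", seq_len(n_genes)), tissues))
  marker_block <- split(seq_len(n_genes),
                        rep(seq_len(k), length.out = n_genes))
  for (j in seq_len(k)) {
    panel[marker_block[[j]], j] <- panel[marker_block[[j]], j] * 8
  }
  panel
}

#' Generate 5hmC profiles coupled to tumor purity
#'
#' Training data for the circulating-tumor-fraction classifier: a planted
#' subset of genes tracks tumor purity linearly on the `log2(TPM + 1)`
#' scale, the remainder is independent noise.
#'
#' @param n_genes total genes; the first `n_coupled` are purity-coupled.
#' @param n_coupled number of purity-coupled genes.
#' @param n_samples number of samples.
#' @param coupling slope of the purity effect (log2 units per unit purity).
#' @param noise_sd residual standard deviation.
#' @param seed integer RNG seed.
#' @return list with `tpm` (gene-by-sample matrix, TPM-like scale),
#'   `purity` (per-sample fraction) and `coupled_genes`.
#' @export
generate_ct_cohort <- function(n_genes = 1000L, n_coupled = 50L,
                               n_samples = 90L, coupling = 4,
                               noise_sd = 0.5, seed = 1L) {
  set.seed(seed)
  gene_id <- sprintf("G%05d", seq_len(n_genes))
  sample_id <- sprintf("S%03d", seq_len(n_samples))
  purity <- stats::runif(n_samples, 0, 1)
  base <- stats::runif(n_genes, 2, 8)
  logm <- matrix(base, n_genes, n_samples) +
    matrix(stats::rnorm(n_genes * n_samples, 0, noise_sd), n_genes)
  coupled <- gene_id[seq_len(n_coupled)]
  logm[seq_len(n_coupled), ] <- logm[seq_len(n_coupled), ] +
    coupling * matrix(purity, n_coupled, n_samples, byrow = TRUE)
  tpm <- pmax(2^logm - 1, 0)
  dimnames(tpm) <- list(gene_id, sample_id)
  list(tpm = tpm, purity = stats::setNames(purity, sample_id),
       coupled_genes = coupled)
}
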