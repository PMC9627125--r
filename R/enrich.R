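#' Enrichment score of a gene set in a ranked list
#'
#' Classic weighted Kolmogorov-Smirnov running sum: genes are walked in rank
#' order (decreasing statistic); set members increment the sum by
#' `|stat|^exponent` (normalized over set members), non-members decrement by
#' a uniform step. The enrichment score is the maximum deviation from zero,
#' signed; it is bounded in `[-1, 1]`.
#'
#' @param stats named numeric vector of ranking statistics (names = genes).
#' @param set character vector of member genes.
#' @param exponent hit-weight exponent; 0 gives the unweighted statistic,
#'   1 the standard weighted form.
#' @return the enrichment score.
#' @export
enrichment_score <- function(stats, set, exponent = 1) {
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  hit <- names(s) %in% set
  es_from_hits(s, hit, exponent)
}

es_from_hits <- function(sorted_stats, hit, exponent) {
  n <- length(sorted_stats)
  nh <- sum(hit)
  if (nh == 0L || nh == n) return(NA_real_)
  w <- abs(sorted_stats)^exponent
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - nh)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Pre-ranked gene set enrichment with a permutation null
#'
#' For each gene set the enrichment score ([enrichment_score()]) is compared
#' against a null distribution obtained by permuting gene labels (drawing
#' random same-size sets from the ranked universe). The normalized
#' enrichment score divides by the mean absolute null score of matching
#' sign; the two-sided p-value counts permutations with `|null ES|` at
#' least as large as the observed `|ES|` (with a +1 pseudocount, so the
#' attainable minimum is `1 / (n_perm + 1)`); Benjamini-Hochberg correction
#' is applied across sets. Sets overlapping fewer than `min_size` ranked genes are skipped.
#'
#' @param stats named numeric vector of ranking statistics; unique gene
#'   names, no missing values.
#' @param sets named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param n_perm number of label permutations (>= 100).
#' @param seed integer RNG seed.
#' @param exponent hit-weight exponent (default 1).
#' @param min_size minimum overlap with the ranked universe (default 3).
#' @return data.frame with `set_name`, `size`, `ES`, `NES`, `p`, `q`.
#' @export
gsea_preranked <- function(stats, sets, n_perm = 1000L, seed = 1L,
                           exponent = 1, min_size = 3L) {
  assert_that(is_count(n_perm, min = 100L), "n_perm must be >= 100")
  assert_that(!is.null(names(stats)) && !anyDuplicated(names(stats)),
              "stats must be named with unique gene ids")
  assert_that(!anyNA(stats), "stats must not contain missing values")
  set.seed(seed)
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]
  universe <- names(s)
  n <- length(s)

  res <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    k <- length(members)
    if (k < min_size) return(NULL)
    es <- es_from_hits(s, universe %in% members, exponent)
    null_es <- vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, k)
      hit <- logical(n); hit[idx] <- TRUE
      es_from_hits(s, hit, exponent)
    }, numeric(1L))
    same_sign <- null_es[sign(null_es) == sign(es)]
    nes <- if (length(same_sign) > 0) es / mean(abs(same_sign)) else NA_real_
    p <- (1 + sum(abs(null_es) >= abs(es))) / (1 + n_perm)
    data.frame(set_name = nm, size = k, ES = es, NES = nes, p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res)) {
    return(data.frame(set_name = character(0), size = integer(0),
                      ES = numeric(0), NES = numeric(0), p = numeric(0),
                      q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  res
}
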