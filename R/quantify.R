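#' Count fragments over gene bodies
#'
#' Counts aligned fragments (or peaks) over the entire gene body, from gene
#' start to gene end. A fragment overlapping several gene bodies by at least
#' one base pair increments every one of them when `multioverlap = TRUE`
#' (the default, matching enrichment-sequencing practice where overlapping
#' gene annotations are common); with `multioverlap = FALSE` ambiguous
#' fragments are discarded.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end` (BED,
#'   0-based half-open) and `sample_id`.
#' @param genes a `gene_model` (see [read_gene_model()]).
#' @param multioverlap logical; count fragments into every overlapped gene.
#' @return integer gene-by-sample count matrix.
#' @export
gene_body_counts <- function(fragments, genes, multioverlap = TRUE) {
  assert_that(all(c("chrom", "start", "end", "sample_id") %in% names(fragments)),
              "fragments need chrom/start/end/sample_id columns")
  if (!any(fragments$chrom %in% genes$chrom)) {
    stop_format("fragments and gene model share no chromosome names")
  }
  samples <- unique(fragments$sample_id)
  counts <- matrix(0L, nrow = nrow(genes), ncol = length(samples),
                   dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    fr <- fragments[fragments$sample_id == s, , drop = FALSE]
    if (!multioverlap) {
      nhit <- overlap_counts(genes, fr)   # per-fragment gene hits
      fr <- fr[nhit <= 1L, , drop = FALSE]
    }
    counts[, s] <- overlap_counts(fr, genes)
  }
  counts
}

# for each query interval, number of subject intervals overlapping by >= 1 bp
# (half-open coordinates).  Sorted-sweep: #(subject.start < q.end) minus
# #(subject.end <= q.start), per chromosome.
overlap_counts <- function(subject, query) {
  out <- integer(nrow(query))
  for (chr in unique(query$chrom)) {
    qi <- which(query$chrom == chr)
    si <- which(subject$chrom == chr)
    if (length(si) == 0L) next
    starts <- sort(subject$start[si])
    ends <- sort(subject$end[si])
    n_start_before <- findInterval(query$end[qi] - 0.5, starts)
    n_end_before <- findInterval(query$start[qi] + 0.5, ends)
    out[qi] <- n_start_before - n_end_before
  }
  out
}

#' Normalize counts to transcripts per million
#'
#' Standardizes gene-body counts for sequencing depth and gene length:
#' per sample, each gene's count is divided by its length in kilobases, and
#' the resulting rates are rescaled to sum to one million.
#'
#' @param counts gene-by-sample count matrix.
#' @param lengths gene lengths in bp, aligned with `counts` rows.
#' @return TPM matrix; every column sums to 1e6.
#' @export
tpm_normalize <- function(counts, lengths) {
  assert_that(length(lengths) == nrow(counts), "lengths must match count rows")
  assert_that(all(lengths > 0), "gene lengths must be positive")
  rate <- counts / (lengths / 1000)
  colsum <- colSums(rate)
  zero <- which(colsum == 0)
  if (length(zero) > 0L) {
    stop_format("sample '%s' has all-zero counts; TPM undefined",
                colnames(counts)[zero[1L]] %||% as.character(zero[1L]))
  }
  sweep(rate, 2L, colsum, "/") * 1e6
}

#' Promoter window around the transcription start site
#'
#' The promoter is defined as -2000/+500 bp around the strand-aware TSS:
#' for a + strand gene `[TSS - 2000, TSS + 500)`, for a - strand gene the
#' mirror image `[TSS - 500, TSS + 2000)`. Windows are truncated at
#' coordinate 0.
#'
#' @param genes a `gene_model` (or any data.frame with `tss` and `strand`).
#' @param upstream,downstream window extents in bp relative to transcription
#'   direction.
#' @return data.frame with `gene_id`, `chrom`, `start`, `end`.
#' @export
promoter_region <- function(genes, upstream = 2000, downstream = 500) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, start), end = pmax(0, end),
             stringsAsFactors = FALSE)
}

#' Average promoter CpG methylation per gene
#'
#' Unweighted mean of the CpG methylation fractions falling inside the
#' promoter window of each gene; `NA` where the window holds no CpG.
#'
#' @param cpg data.frame with `chrom`, `pos`, `meth` (fraction in `[0,1]`)
#'   and `sample_id`.
#' @param genes a `gene_model`.
#' @return gene-by-sample matrix of mean promoter methylation.
#' @export
promoter_methylation <- function(cpg, genes) {
  assert_that(is_fraction(cpg$meth), "methylation fractions must lie in [0, 1]")
  prom <- promoter_region(genes)
  samples <- unique(cpg$sample_id)
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    cs <- cpg[cpg$sample_id == s, , drop = FALSE]
    for (g in seq_len(nrow(prom))) {
      sel <- cs$chrom == prom$chrom[g] & cs$pos >= prom$start[g] &
        cs$pos < prom$end[g]
      if (any(sel)) out[g, s] <- mean(cs$meth[sel])
    }
  }
  out
}

#' Average copy number over gene bodies
#'
#' Length-weighted mean of segment copy number over each gene's genomic
#' span; `NA` where no segment covers the gene.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `cn`,
#'   `sample_id`; segments must not overlap within a sample.
#' @param genes a `gene_model`.
#' @return gene-by-sample copy-number matrix.
#' @export
gene_copy_number <- function(segments, genes) {
  samples <- unique(segments$sample_id)
  out <- matrix(NA_real_, nrow = nrow(genes), ncol = length(samples),
                dimnames = list(genes$gene_id, samples))
  for (s in samples) {
    seg <- segments[segments$sample_id == s, , drop = FALSE]
    seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
    by_chr <- split(seq_len(nrow(seg)), seg$chrom)
    for (idx in by_chr) {
      if (any(seg$end[idx][-length(idx)] > seg$start[idx][-1L])) {
        stop_format("overlapping copy-number segments in sample '%s'", s)
      }
    }
    for (g in seq_len(nrow(genes))) {
      sel <- which(seg$chrom == genes$chrom[g] & seg$start < genes$end[g] &
                     seg$end > genes$start[g])
      if (length(sel) == 0L) next
      w <- pmin(seg$end[sel], genes$end[g]) - pmax(seg$start[sel], genes$start[g])
      out[g, s] <- sum(w * seg$cn[sel]) / sum(w)
    }
  }
  out
}

#' Annotate peaks to genomic regions and closest gene
#'
#' Each peak is assigned a single category from its midpoint with fixed
#' precedence promoter > exon > intron > downstream > intergenic, where the
#' promoter is the -2000/+500 bp TSS window, downstream extends
#' `downstream_bp` past the strand-aware gene end, and intron is any gene
#' body position outside annotated exons. The closest gene is the one whose
#' TSS is nearest to the peak midpoint. Per-sample category frequencies sum
#' to one.
#'
#' @param peaks data.frame with `chrom`, `start`, `end`, `sample_id`.
#' @param genes a `gene_model`.
#' @param exons optional data.frame (`gene_id`, `chrom`, `start`, `end`)
#'   giving exon blocks; when omitted every gene body counts as exonic.
#' @param downstream_bp width of the downstream category in bp.
#' @return list with `peaks` (input plus `category`, `closest_gene`) and
#'   `frequencies` (sample-by-category matrix).
#' @export
annotate_peaks <- function(peaks, genes, exons = NULL, downstream_bp = 3000) {
  categories <- c("promoter", "exon", "intron", "downstream", "intergenic")
  mid <- floor((peaks$start + peaks$end) / 2)
  prom <- promoter_region(genes)
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = genes$start, end = genes$end,
                        stringsAsFactors = FALSE)
  }
  plus <- genes$strand == "+"
  down_start <- ifelse(plus, genes$end, pmax(0, genes$start - downstream_bp))
  down_end <- ifelse(plus, genes$end + downstream_bp, genes$start)

  in_any <- function(chrom, pos, tab) {
    vapply(seq_along(pos), function(i) {
      any(tab$chrom == chrom[i] & tab$start <= pos[i] & pos[i] < tab$end)
    }, logical(1L))
  }
  body_tab <- data.frame(chrom = genes$chrom, start = genes$start,
                         end = genes$end)
  down_tab <- data.frame(chrom = genes$chrom, start = down_start,
                         end = down_end)
  category <- rep("intergenic", nrow(peaks))
  category[in_any(peaks$chrom, mid, down_tab)] <- "downstream"
  category[in_any(peaks$chrom, mid, body_tab)] <- "intron"
  category[category == "intron" &
             in_any(peaks$chrom, mid, exons)] <- "exon"
  category[in_any(peaks$chrom, mid, prom)] <- "promoter"

  closest <- vapply(seq_len(nrow(peaks)), function(i) {
    same <- genes$chrom == peaks$chrom[i]
    if (!any(same)) return(NA_character_)
    d <- abs(genes$tss[same] - mid[i])
    genes$gene_id[same][which.min(d)]
  }, character(1L))

  peaks$category <- factor(category, levels = categories)
  peaks$closest_gene <- closest
  samples <- unique(peaks$sample_id)
  freq <- t(vapply(samples, function(s) {
    tab <- table(peaks$category[peaks$sample_id == s])
    as.numeric(tab / sum(tab))
  }, numeric(length(categories))))
  dimnames(freq) <- list(samples, categories)
  list(peaks = peaks, frequencies = freq)
}

#' Select the most variable genes
#'
#' Ranks genes by across-sample variance (denominator n-1) of an already
#' log-transformed matrix and returns the top `ceiling(fraction * G)`.
#' Zero-variance genes are excluded from the ranking; ties are broken by
#' gene id, lexicographically.
#'
#' @param mat gene-by-sample matrix, typically `log2(TPM + 1)`.
#' @param fraction fraction of genes to keep (default top 10%).
#' @return character vector of gene ids, most variable first.
#' @export
top_variable_genes <- function(mat, fraction = 0.10) {
  v <- apply(mat, 1L, stats::var, na.rm = TRUE)
  keep <- which(!is.na(v) & v > 0)
  ord <- keep[order(-v[keep], rownames(mat)[keep])]
  n <- min(ceiling(fraction * nrow(mat)), length(ord))
  rownames(mat)[ord[seq_len(n)]]
}

#' Median-center and scale a matrix per gene
#'
#' Subtracts the per-gene median and divides by the per-gene standard
#' deviation (n-1). Zero-variance genes are set to missing.
#'
#' @param mat gene-by-sample matrix.
#' @return matrix of the same shape; rows have median 0.
#' @export
median_center_scale <- function(mat) {
  med <- apply(mat, 1L, stats::median, na.rm = TRUE)
  sdv <- apply(mat, 1L, stats::sd, na.rm = TRUE)
  out <- sweep(sweep(mat, 1L, med, "-"), 1L, sdv, "/")
  out[sdv == 0 | is.na(sdv), ] <- NA_real_
  out
}

#' Principal component embedding of samples
#'
#' Singular value decomposition of the samples-by-genes matrix (genes are
#' expected to be pre-selected and scaled); components are ordered by
#' decreasing variance.
#'
#' @param mat gene-by-sample matrix (e.g. output of
#'   [median_center_scale()] restricted to [top_variable_genes()]).
#' @return list with `scores` (sample-by-component), `sdev` and
#'   `var_explained`.
#' @export
pca_embed <- function(mat) {
  x <- t(mat[stats::complete.cases(mat), , drop = FALSE])
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  list(scores = p$x, sdev = p$sdev,
       var_explained = p$sdev^2 / sum(p$sdev^2))
}

#' Hierarchical clustering of samples
#'
#' Euclidean distance between sample profiles with Ward (ward.D2) linkage,
#' cut into `k` groups.
#'
#' @param mat gene-by-sample matrix (pre-selected and scaled).
#' @param k number of clusters.
#' @return named integer vector of cluster labels per sample.
#' @export
hier_cluster <- function(mat, k) {
  x <- t(mat[stats::complete.cases(mat), , drop = FALSE])
  assert_that(is_count(k) && k <= nrow(x),
              "k must be a positive integer <= number of samples")
  hc <- stats::hclust(stats::dist(x, method = "euclidean"), method = "ward.D2")
  stats::cutree(hc, k = k)
}
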