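# shared fixture builders and independent oracles

toy_gene_model <- function() {
  as_gene_model(data.frame(
    gene_id = c("GA", "GB", "GC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000, 4500, 2000),
    end = c(5000, 9000, 8000),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE))
}

# quadratic all-pairs overlap scan (>=1 bp, half-open)
brute_force_counts <- function(fragments, genes) {
  sapply(seq_len(nrow(genes)), function(g) {
    sum(fragments$chrom == genes$chrom[g] &
          fragments$start < genes$end[g] &
          fragments$end > genes$start[g])
  })
}

# independent weighted-KS running-sum enumeration
brute_force_es <- function(stats, set, exponent = 1) {
  s <- stats[order(stats, decreasing = TRUE)]
  running <- 0
  best <- 0
  hit_w <- sum(abs(s[names(s) %in% set])^exponent)
  miss_step <- 1 / (length(s) - sum(names(s) %in% set))
  for (g in names(s)) {
    if (g %in% set) {
      running <- running + abs(s[[g]])^exponent / hit_w
    } else {
      running <- running - miss_step
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

random_fragments <- function(n, chroms = c("chr1", "chr2"), span = 1e4,
                             sample_id = "S1") {
  start <- sample.int(span, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + sample.int(500, n, replace = TRUE),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# small aligned omics bundle built directly from matrices
manual_bundle <- function(expr, hmc, pm = NULL, cn = NULL, snv = NULL,
                          sv = NULL) {
  G <- nrow(expr); N <- ncol(expr)
  zeros <- matrix(0, G, N, dimnames = dimnames(expr))
  named <- function(m) { dimnames(m) <- dimnames(expr); m }
  structure(list(
    tpm_5hmc = named(hmc), expr = expr,
    promoter_meth = named(pm %||% matrix(stats::runif(G * N), G, N)),
    copy_number = named(cn %||% matrix(2, G, N)),
    snv_count = if (is.null(snv)) zeros else named(snv),
    sv_count = if (is.null(sv)) zeros else named(sv),
    sample_meta = data.frame(sample_id = colnames(expr))),
    class = "omics_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# constructed 10-row somatic fixture: pass/fail pattern enumerable by hand
somatic_fixture <- function() {
  data.frame(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chr7", "chr8",
              "chr9", "chr10"),
    pos = 1:10 * 1000,
    ref = "A", alt = "T",
    #                 pass  reads  vaf    bg     germ   mapq  leuko
    unique_read_support = c(12,    9,     15,    20,    30,   11,   50,
                            14,    25,    10),
    vaf =               c(0.02,  0.05,  0.008, 0.04,  0.30, 0.02, 0.015,
                          0.05,  0.10,  0.012),
    background_error =  c(5e-4,  5e-4,  1e-4,  3e-3,  1e-3, 5e-4, 5e-4,
                          5e-4,  1e-3,  5e-4),
    germline_vaf =      c(0.005, 0,     0,     0,     0.15, 0,    0,
                          0.01,  0,     0),
    mapq_mean =         c(30,    40,    50,    60,    30,   5,    25,
                          35,    45,    55),
    leukocyte_depth =   c(50,    80,    90,    70,    60,   50,   10,
                          40,    30,    100),
    copy_log_ratio = 0,
    stringsAsFactors = FALSE)
}
# hand enumeration:
#  1: all rules pass                                   -> PASS
#  2: reads 9 < 10                                     -> fail reads only
#  3: vaf 0.008 < 0.01                                 -> fail vaf only
#  4: vaf 0.04 < 20 * 0.003 = 0.06                     -> fail background
#  5: vaf 0.30 < 3 * 0.15 = 0.45                       -> fail germline
#  6: mapq 5 < 10 (substitution)                       -> fail mapq
#  7: leukocyte depth 10 < 20                          -> fail leukocyte
#  8: vaf 0.05 >= 3*0.01, >= 20*5e-4                   -> PASS
#  9: all pass (vaf 0.10 >= 20*1e-3 = 0.02)            -> PASS
# 10: boundary vaf exactly 0.012 >= 0.01, reads 10>=10 -> PASS
# survivors: rows 1, 8, 9, 10 (count 4)
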