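test_that("gene-body counting honors multioverlap and matches brute force", {
  gm <- toy_gene_model()   # GA [1000,5000) and GB [4500,9000) overlap on chr1
  fr <- data.frame(chrom = "chr1", start = 2000, end = 2100, sample_id = "S1")
  counts <- gene_body_counts(fr, gm)
  expect_equal(unname(counts[, "S1"]), c(1L, 0L, 0L))

  # a fragment spanning the GA/GB overlap increments both genes
  fr2 <- data.frame(chrom = "chr1", start = 4600, end = 4900, sample_id = "S1")
  expect_equal(unname(gene_body_counts(fr2, gm)[, "S1"]), c(1L, 1L, 0L))
  # without multioverlap the ambiguous fragment is dropped
  expect_equal(unname(gene_body_counts(fr2, gm, multioverlap = FALSE)[, "S1"]),
               c(0L, 0L, 0L))

  set.seed(42)
  frags <- random_fragments(1000)
  counts <- gene_body_counts(frags, gm)
  expect_equal(unname(counts[, "S1"]), brute_force_counts(frags, gm))

  bad <- data.frame(chrom = "chrZ", start = 1, end = 10, sample_id = "S1")
  expect_error(gene_body_counts(bad, gm), "chromosome")
})

test_that("TPM normalization conserves one million per sample", {
  counts <- matrix(c(10, 20), 2, 1, dimnames = list(c("g1", "g2"), "S1"))
  tpm <- tpm_normalize(counts, c(1000, 2000))
  expect_equal(unname(tpm[, 1]), c(5e5, 5e5))  # equal per-kb rates

  single <- matrix(7, 1, 1, dimnames = list("g1", "S1"))
  expect_equal(unname(tpm_normalize(single, 1234)[1, 1]), 1e6)

  set.seed(2)
  counts <- matrix(rpois(250, 20), 50, 5,
                   dimnames = list(paste0("g", 1:50), paste0("S", 1:5)))
  tpm <- tpm_normalize(counts, sample(500:5000, 50))
  expect_equal(unname(colSums(tpm)), rep(1e6, 5), tolerance = 1e-6)

  counts[, 3] <- 0
  expect_error(tpm_normalize(counts, rep(1000, 50)), "S3")
})

test_that("promoter windows are strand-aware and clamped at zero", {
  gp <- as_gene_model(data.frame(gene_id = "G1", chrom = "chr1",
                                 start = 10000, end = 20000, strand = "+"))
  w <- promoter_region(gp)
  expect_equal(c(w$start, w$end), c(8000, 10500))

  gn <- as_gene_model(data.frame(gene_id = "G2", chrom = "chr1",
                                 start = 3000, end = 10000, strand = "-"))
  w <- promoter_region(gn)
  expect_equal(c(w$start, w$end), c(9500, 12000))

  gc <- as_gene_model(data.frame(gene_id = "G3", chrom = "chr1",
                                 start = 1000, end = 5000, strand = "+"))
  w <- promoter_region(gc)
  expect_equal(c(w$start, w$end), c(0, 1500))
})

test_that("promoter windows are exact strand-mirror images", {
  # reflecting coordinates about R and flipping strand must map windows
  # onto each other: [a, b) -> [R - b, R - a)
  R <- 1e6
  set.seed(3)
  for (i in 1:20) {
    s <- sample.int(9e5, 1) + 10000
    e <- s + sample.int(5e4, 1)
    g_plus <- as_gene_model(data.frame(gene_id = "gp", chrom = "chr1",
                                       start = s, end = e, strand = "+"))
    g_mirror <- as_gene_model(data.frame(gene_id = "gm", chrom = "chr1",
                                         start = R - e, end = R - s,
                                         strand = "-"))
    wp <- promoter_region(g_plus)
    wm <- promoter_region(g_mirror)
    expect_equal(wm$start, R - wp$end)
    expect_equal(wm$end, R - wp$start)
  }
})

test_that("promoter methylation averages CpGs in the window", {
  gm <- toy_gene_model()
  cpg <- data.frame(chrom = "chr1", pos = c(500, 1200), meth = c(0.2, 0.8),
                    sample_id = "S1")
  # GA is + strand with TSS 1000: window [0, 1500) catches both CpGs
  m <- promoter_methylation(cpg, gm)
  expect_equal(m["GA", "S1"], 0.5)
  expect_true(is.na(m["GC", "S1"]))

  set.seed(4)
  cpg <- data.frame(chrom = "chr1", pos = sample.int(12000, 20),
                    meth = runif(20), sample_id = "S1")
  m <- promoter_methylation(cpg, gm)
  prom <- promoter_region(gm)
  for (g in 1:3) {
    sel <- cpg$chrom == prom$chrom[g] & cpg$pos >= prom$start[g] &
      cpg$pos < prom$end[g]
    expected <- if (any(sel)) mean(cpg$meth[sel]) else NA_real_
    expect_equal(unname(m[g, 1]), expected)
  }
})

test_that("gene copy number is the length-weighted segment mean", {
  gm <- toy_gene_model()
  seg <- data.frame(chrom = "chr1", start = 0, end = 10000, cn = 3,
                    sample_id = "S1")
  cn <- gene_copy_number(seg, gm)
  expect_equal(cn["GA", "S1"], 3)

  seg2 <- data.frame(chrom = "chr1", start = c(0, 3000), end = c(3000, 10000),
                     cn = c(2, 4), sample_id = "S1")
  cn <- gene_copy_number(seg2, gm)  # GA [1000,5000): 2 kb at cn 2, 2 kb at cn 4
  expect_equal(cn["GA", "S1"], 3)

  overlapping <- data.frame(chrom = "chr1", start = c(0, 2000),
                            end = c(3000, 5000), cn = c(2, 4),
                            sample_id = "S1")
  expect_error(gene_copy_number(overlapping, gm), "overlapping")

  # random segmentation vs per-bp brute force
  set.seed(5)
  cuts <- sort(sample(1:9999, 6))
  seg3 <- data.frame(chrom = "chr1", start = c(0, cuts),
                     end = c(cuts, 10000),
                     cn = sample(0:5, 7, replace = TRUE), sample_id = "S1")
  cn <- gene_copy_number(seg3, gm)
  bp <- rep(NA_real_, 10000)
  for (i in seq_len(nrow(seg3))) {
    bp[(seg3$start[i] + 1):seg3$end[i]] <- seg3$cn[i]
  }
  expect_equal(cn["GA", "S1"], mean(bp[1001:5000]), tolerance = 1e-9)
})

test_that("peak annotation assigns one category with fixed precedence", {
  gm <- toy_gene_model()
  exons <- data.frame(gene_id = "GA", chrom = "chr1",
                      start = c(1000, 3000), end = c(1500, 3500))
  # GA promoter window is [0, 1500): a peak midpoint at 1200 is inside both
  # the promoter and the first exon -> promoter wins
  peaks <- data.frame(chrom = c("chr1", "chr1", "chr9", "chr1"),
                      start = c(1100, 3100, 100, 2000),
                      end = c(1300, 3300, 200, 2200),
                      sample_id = "S1")
  ann <- annotate_peaks(peaks, gm, exons)
  expect_equal(as.character(ann$peaks$category),
               c("promoter", "exon", "intergenic", "intron"))
  expect_equal(sum(ann$frequencies["S1", ]), 1)
  # every peak is assigned exactly one category
  expect_false(anyNA(ann$peaks$category))
  expect_equal(ann$peaks$closest_gene[1], "GA")
})

test_that("variable-gene selection and scaling behave as specified", {
  set.seed(6)
  mat <- matrix(rnorm(200), 20, 10,
                dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:10)))
  mat["g01", ] <- mat["g01", ] * 10
  mat["g02", ] <- mat["g02", ] * 5
  mat["g03", ] <- 7            # constant: excluded from ranking
  top <- top_variable_genes(mat, fraction = 0.10)
  expect_length(top, 2L)
  expect_setequal(top, c("g01", "g02"))

  scaled <- median_center_scale(mat)
  expect_equal(unname(apply(scaled[c("g01", "g02"), ], 1, median)), c(0, 0))
  expect_true(all(is.na(scaled["g03", ])))
})

test_that("PCA and Ward clustering recover planted sample groups", {
  set.seed(7)
  G <- 40; N <- 20
  mat <- matrix(rnorm(G * N), G, N,
                dimnames = list(paste0("g", 1:G), paste0("s", 1:N)))
  grp <- rep(c(0, 6), each = N / 2)
  mat <- sweep(mat, 2L, grp, "+")
  p <- pca_embed(mat)
  expect_true(all(diff(p$sdev) <= 1e-12))       # non-increasing variances
  pc1_split <- split(p$scores[, 1], rep(1:2, each = N / 2))
  expect_true(max(pc1_split[[1]]) < min(pc1_split[[2]]) ||
                min(pc1_split[[1]]) > max(pc1_split[[2]]))
  cl <- hier_cluster(mat, k = 2)
  expect_equal(length(unique(cl[1:(N / 2)])), 1L)
  expect_equal(length(unique(cl[(N / 2 + 1):N])), 1L)
  expect_false(cl[1] == cl[N])
  expect_error(hier_cluster(mat, k = 50), "k must be")

  # duplicated sample merges first (distance zero)
  mat2 <- cbind(mat, dup = mat[, 1])
  hc <- stats::hclust(stats::dist(t(mat2)), method = "ward.D2")
  first_pair <- sort(abs(hc$merge[1, ]))
  expect_equal(sort(colnames(mat2)[first_pair]), sort(c("s1", "dup")))
})
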