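test_that("somatic filter matches exhaustive hand enumeration of the rules", {
  v <- filter_somatic(somatic_fixture())
  expect_equal(which(v$pass), c(1L, 8L, 9L, 10L))
  expect_equal(nrow(attr(v, "passing")), 4L)
  expect_false(v$pass_reads[2]);  expect_true(all(v$pass[2] == FALSE))
  expect_false(v$pass_vaf[3])
  expect_true(v$pass_reads[3] && v$pass_mapq[3] && v$pass_background[3] &&
                v$pass_germline[3] && v$pass_leukocyte_depth[3])
  expect_false(v$pass_background[4])
  expect_false(v$pass_germline[5])
  expect_false(v$pass_mapq[6])
  expect_false(v$pass_leukocyte_depth[7])
})

test_that("somatic filter boundary conventions and worked example hold", {
  row <- data.frame(chrom = "chr1", pos = 1, ref = "A", alt = "G",
                    unique_read_support = 12, vaf = 0.02,
                    background_error = 5e-4, germline_vaf = 0.005,
                    mapq_mean = 30, leukocyte_depth = 50)
  expect_true(filter_somatic(row)$pass)   # 0.02 >= 0.01, >= 20*5e-4, >= 3*0.005
  # vaf exactly at the 1% boundary passes (>= convention)
  row$vaf <- 0.01; row$germline_vaf <- 0; row$background_error <- 5e-4
  expect_true(filter_somatic(row)$pass)
  # mapping-quality rule applies only to substitutions
  indel <- row; indel$alt <- "GT"; indel$mapq_mean <- 5
  expect_true(filter_somatic(indel)$pass)
  # artifact review columns fail a row when present and TRUE
  art <- row; art$artifact_strand_imbalance <- TRUE
  expect_false(filter_somatic(art)$pass)
  expect_error(filter_somatic(row[, -5]), "missing filter column")
})

test_that("somatic filter is a pure conjunction (row-order independent)", {
  v <- somatic_fixture()
  set.seed(1)
  perm <- sample(nrow(v))
  a <- filter_somatic(v)$pass
  b <- filter_somatic(v[perm, ])$pass
  expect_equal(b, a[perm])
})

test_that("germline filter keeps only deleterious rare variants", {
  g <- data.frame(chrom = "chr1", pos = 1:4, ref = "A", alt = "T",
                  unique_read_support = c(9, 9, 20, 9),
                  vaf = c(0.48, 0.48, 0.5, 0.48),
                  population_freq = c(1e-4, 1e-4, 0.005, 1e-4),
                  consequence = c("frameshift", "missense", "stopgain",
                                  "splice_site"),
                  stringsAsFactors = FALSE)
  kept <- filter_germline(g)
  # row 1 kept; row 2 missense excluded; row 3 popfreq exactly 0.5% excluded;
  # row 4 kept
  expect_equal(kept$pos, c(1L, 4L))
  low <- g[1, ]; low$vaf <- 0.09
  expect_equal(nrow(filter_germline(low)), 0L)
  odd <- g[1, ]; odd$consequence <- "mystery"
  expect_warning(res <- filter_germline(odd), "unknown consequence")
  expect_equal(nrow(res), 0L)
})

test_that("surrogate selection excludes allosomes and amplified genes", {
  v <- data.frame(chrom = c("chrX", "chr5", "chr7"), pos = c(1, 2, 3),
                  vaf = c(0.30, 0.25, 0.20),
                  copy_log_ratio = c(0, 0.5, 0))
  s <- select_surrogate(v)
  expect_equal(s$vaf, 0.20)
  expect_null(select_surrogate(v[0, ]))
  expect_null(select_surrogate(NULL))
  # deterministic tie-break by (chrom, pos)
  tie <- data.frame(chrom = c("chr2", "chr1"), pos = c(5, 9),
                    vaf = c(0.2, 0.2), copy_log_ratio = 0)
  expect_equal(select_surrogate(tie)$chrom, "chr1")
})

test_that("the ctDNA-fraction formula matches its printed values", {
  expect_equal(ct_fraction_from_vaf(0), 0)
  expect_equal(ct_fraction_from_vaf(1 / 3), 0.5)
  expect_equal(ct_fraction_from_vaf(0.5), 2 / 3)
  grid <- seq(0.001, 1, length.out = 1000)
  ct <- ct_fraction_from_vaf(grid)
  expect_true(all(diff(ct) > 0))          # strictly increasing
  expect_true(all(ct >= 0 & ct <= 1))
  expect_error(ct_fraction_from_vaf(1.2), "0, 1")
  # algebraic round trip: t -> VAF = t/(2-t) -> formula -> t
  t <- seq(0.05, 0.95, 0.05)
  expect_equal(ct_fraction_from_vaf(t / (2 - t)), t, tolerance = 1e-12)
})

test_that("het-loss inversion matches the one-copy-loss mixture model", {
  expect_equal(ct_fraction_from_het_loss(0.5), 0)
  expect_equal(ct_fraction_from_het_loss(2 / 3), 0.5)
  expect_error(ct_fraction_from_het_loss(0.4), "0.5")
  # binomial simulation oracle: t = 0.3, depth 5000, 20 SNPs
  set.seed(2)
  t_true <- 0.3
  f_expected <- 1 / (2 - t_true)
  f_hat <- rbinom(20, 5000, f_expected) / 5000
  est <- median(ct_fraction_from_het_loss(pmax(f_hat, 0.5)))
  expect_lt(abs(est - t_true), 0.03)
})

test_that("ct estimation picks the right route per sample", {
  v <- generate_variant_reads(0.25 * 2 / (1 + 0.25) , depth = 100,
                              n_variants = 5, seed = 3)
  # direct worked example: surrogate vaf 0.25 -> ct 0.4
  one <- data.frame(chrom = "chr3", pos = 10, ref = "A", alt = "G",
                    unique_read_support = 50, vaf = 0.25,
                    background_error = 1e-4, germline_vaf = 0, mapq_mean = 60,
                    leukocyte_depth = 100, copy_log_ratio = 0)
  est <- estimate_ct(one)
  expect_equal(est$ct_fraction, 0.4)
  expect_equal(est$method, "vaf_formula")

  est2 <- estimate_ct(one[0, ], het_snp_maf = 0.6)
  expect_equal(est2$method, "het_loss_snp")
  expect_equal(est2$ct_fraction, 2 - 1 / 0.6, tolerance = 1e-12)

  est3 <- estimate_ct(one[0, ])
  expect_equal(est3$method, "none")
  expect_true(is.na(est3$ct_fraction))
})

test_that("simulated reads round-trip to the true tumor fraction", {
  errs <- sapply(seq(0.1, 0.9, by = 0.2), function(t) {
    v <- generate_variant_reads(t, depth = 2000, n_variants = 50,
                                seed = round(1000 * t))
    som <- attr(filter_somatic(v), "passing")
    som <- som[som$truth == "somatic", ]
    abs(ct_fraction_from_variants(som$vaf) - t)
  })
  expect_lte(median(errs), 0.03)
})

test_that("reported driver panels carry the expected genes", {
  expect_true(all(c("AR", "TP53", "SPOP", "FOXA1") %in%
                    driver_gene_panel("mutation")))
  expect_true(all(c("MYC", "NCOA2", "NKX3-1") %in%
                    driver_gene_panel("copy_number")))
})
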