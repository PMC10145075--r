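# Per-locus diversity statistics against closed-form and brute-force
# expectations.

test_that("allele frequencies count alleles over called genotypes", {
  gm <- gm_from_codes(matrix(c(0L, 0L, 1L, 2L), 4, 1))
  af <- allele_freq(gm, 1)
  expect_equal(af$p_alt, 3 / 8)
  expect_equal(af$maf, 0.375)

  gm2 <- gm_from_codes(matrix(c(1L, 1L), 2, 1))
  expect_equal(allele_freq(gm2, 1)$maf, 0.5)
})

test_that("allele counts match an explicit per-allele tally", {
  set.seed(42)
  for (rep in 1:5) {
    g <- sample(c(0:2, NA), 50, replace = TRUE)
    gm <- gm_from_codes(matrix(g, 50, 1))
    # independent tally: expand each genotype into two alleles and count
    alleles <- unlist(lapply(g[!is.na(g)], function(x) {
      switch(x + 1L, c(0, 0), c(0, 1), c(1, 1))
    }))
    expect_equal(allele_freq(gm, 1)$p_alt, mean(alleles))
  }
})

test_that("observed heterozygosity is the called-het fraction", {
  gm <- gm_from_codes(matrix(c(1L, 1L, 0L, NA), 4, 1))
  expect_equal(observed_het(gm, 1), 2 / 3)
  expect_equal(observed_het(gm_from_codes(matrix(0L, 5, 1)), 1), 0)
  expect_equal(observed_het(gm_from_codes(matrix(1L, 5, 1)), 1), 1)
})

test_that("gene diversity follows 1 - sum(f^2) under both conventions", {
  # p = q = 0.5 via two hets -> allele-convention maximum 0.5
  gm <- gm_from_codes(matrix(c(1L, 1L), 2, 1))
  expect_equal(gene_diversity(gm, 1, "allele"), 0.5)
  # monomorphic locus is 0 under both conventions
  mono <- gm_from_codes(matrix(2L, 6, 1))
  expect_equal(gene_diversity(mono, 1, "allele"), 0)
  expect_equal(gene_diversity(mono, 1, "genotype"), 0)
  # genotype-class plug-in arithmetic
  g <- c(rep(0L, 17), rep(1L, 166), rep(2L, 17))
  gm3 <- gm_from_codes(matrix(g, length(g), 1))
  f <- c(17, 166, 17) / 200
  expect_equal(gene_diversity(gm3, 1, "genotype"), 1 - sum(f^2))
})

test_that("PIC attains the known biallelic and three-class values", {
  gm <- gm_from_codes(matrix(c(1L, 1L), 2, 1))
  expect_equal(pic(gm, 1, "allele"), 0.375)
  expect_equal(pic(gm_from_codes(matrix(0L, 4, 1)), 1, "allele"), 0)
  # three equal genotype classes: 1 - 3/9 - 6/81 = 16/27
  gm3 <- gm_from_codes(matrix(c(0L, 1L, 2L), 3, 1))
  expect_equal(pic(gm3, 1, "genotype"), 16 / 27)
  expect_equal(pic_from_freqs(c(1 / 3, 1 / 3, 1 / 3)), 16 / 27)
})

test_that("an all-missing locus yields flagged NA statistics", {
  gm <- gm_from_codes(matrix(c(NA_integer_, NA_integer_, 0L, 1L), 2, 2))
  expect_warning(af <- allele_freq(gm, 1), "no called")
  expect_true(is.na(af$maf))
  expect_warning(expect_true(is.na(observed_het(gm, 1))))
  st <- locus_stats(gm)
  expect_false(st$defined[1])
  expect_true(all(is.na(st[1, c("maf", "ho", "gd_allele", "pic_allele")])))
  expect_true(st$defined[2])
})

test_that("locus_stats agrees with the scalar operations locus by locus", {
  gm <- random_gm(30, 15, miss = 0.2, seed = 7)
  st <- locus_stats(gm)
  for (j in c(1, 5, 15)) {
    expect_equal(st$maf[j], allele_freq(gm, j)$maf)
    expect_equal(st$ho[j], observed_het(gm, j))
    expect_equal(st$gd_allele[j], gene_diversity(gm, j, "allele"))
    expect_equal(st$gd_genotype[j], gene_diversity(gm, j, "genotype"))
    expect_equal(st$pic_allele[j], pic(gm, j, "allele"))
    expect_equal(st$pic_genotype[j], pic(gm, j, "genotype"))
  }
})

test_that("PIC never exceeds gene diversity and both respect their bounds", {
  gm <- random_gm(40, 60, miss = 0.1, seed = 11)
  st <- locus_stats(gm)
  expect_true(all(st$pic_allele <= st$gd_allele + 1e-12))
  expect_true(all(st$pic_genotype <= st$gd_genotype + 1e-12))
  expect_true(all(st$maf <= 0.5 + 1e-12))
  expect_true(all(st$gd_allele <= 0.5 + 1e-12))
  expect_true(all(st$pic_allele <= 0.375 + 1e-12))
  expect_true(all(st$gd_genotype <= 2 / 3 + 1e-12))
})

test_that("statistics are invariant to sample order and allele relabeling", {
  gm <- random_gm(25, 10, miss = 0.1, seed = 3)
  st <- locus_stats(gm)
  perm <- sample(nrow(gm$calls))
  gm_p <- geno_matrix(gm$calls[perm, ], gm$loci)
  expect_equal(locus_stats(gm_p)[c("maf", "ho", "gd_allele", "pic_genotype")],
               st[c("maf", "ho", "gd_allele", "pic_genotype")])
  # swapping ref/alt flips hom codes but leaves MAF/GD/PIC unchanged
  flipped <- gm$calls
  flipped[gm$calls == 0L] <- 2L
  flipped[gm$calls == 2L] <- 0L
  loci_f <- gm$loci; loci_f$ref <- gm$loci$alt; loci_f$alt <- gm$loci$ref
  st_f <- locus_stats(geno_matrix(flipped, loci_f))
  for (col in c("maf", "ho", "gd_allele", "gd_genotype", "pic_allele",
                "pic_genotype")) {
    expect_equal(st_f[[col]], st[[col]], info = col)
  }
})

test_that("cohort summaries average statistics and count threshold exceedance", {
  gm <- gm_from_codes(matrix(c(0L, 1L, 2L, 1L), 4, 1))
  st <- locus_stats(gm)
  sm <- summarize_locus_stats(st, thresholds = 0.3)
  expect_equal(unname(sm$means["ho"]), st$ho[1])
  expect_equal(sm$n_loci, 1L)
  gm2 <- random_gm(20, 30, seed = 5)
  st2 <- locus_stats(gm2)
  sm2 <- summarize_locus_stats(st2, thresholds = c(0.3, 0.45))
  expect_equal(unname(sm2$prop_above["ho", ">0.3"]), mean(st2$ho > 0.3))
  expect_equal(sum(sm2$chrom_counts), 30L)
  expect_error(summarize_locus_stats(st2[0, ]), "empty")
})
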