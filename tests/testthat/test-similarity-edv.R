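# Genetic similarity, threshold calibration and EDV classification.

test_that("GS tallies agreeing and differing co-called genotype classes", {
  codes <- rbind(a = rep(c(0L, 1L, 2L), length.out = 10),
                 b = rep(c(0L, 1L, 2L), length.out = 10))
  gm <- gm_from_codes(codes)
  r <- gs_pair(gm, "a", "b")
  expect_equal(r[c("ns", "nd", "gs")], list(ns = 10L, nd = 0L, gs = 1))

  codes2 <- codes
  codes2["b", 10] <- (codes2["b", 10] + 1L) %% 3L
  r2 <- gs_pair(gm_from_codes(codes2), 1, 2)
  expect_equal(r2$gs, 0.9)
  expect_error(gs_pair(gm, 1, 1), "distinct")
})

test_that("GS with missing data matches a locus-by-locus hand tally", {
  set.seed(13)
  for (rep in 1:5) {
    ga <- sample(c(0:2, NA), 30, replace = TRUE)
    gb <- sample(c(0:2, NA), 30, replace = TRUE)
    gm <- gm_from_codes(rbind(ga, gb))
    r <- gs_pair(gm, 1, 2)
    ns <- nd <- 0L
    for (l in 1:30) {
      if (is.na(ga[l]) || is.na(gb[l])) next
      if (ga[l] == gb[l]) ns <- ns + 1L else nd <- nd + 1L
    }
    expect_equal(r$ns, ns)
    expect_equal(r$nd, nd)
    expect_equal(r$gs, ns / (ns + nd))
  }
})

test_that("a pair with no co-called loci is flagged undefined", {
  gm <- gm_from_codes(rbind(c(0L, NA), c(NA, 1L)))
  expect_warning(r <- gs_pair(gm, 1, 2), "no co-called")
  expect_true(is.na(r$gs))
})

test_that("the GS matrix is symmetric, complete and order-invariant", {
  clone <- rep(c(0L, 1L, 2L, 1L), 5)
  gm <- gm_from_codes(rbind(a = clone, b = clone, c = clone))
  gsr <- gs_matrix(gm)
  expect_equal(gsr$n_pairs, 3L)
  expect_true(all(gsr$gs[upper.tri(gsr$gs)] == 1))

  gm2 <- random_gm(12, 40, miss = 0.1, seed = 17)
  gsr2 <- gs_matrix(gm2)
  expect_equal(gsr2$gs, t(gsr2$gs))
  expect_equal(nrow(gs_pairs_table(gsr2)), choose(12, 2))
  # gs_pair and gs_matrix agree entry by entry
  for (p in list(c(1, 2), c(3, 11), c(5, 9))) {
    r <- gs_pair(gm2, p[1], p[2])
    expect_equal(gsr2$gs[p[1], p[2]], r$gs)
    expect_equal(gsr2$nd[p[1], p[2]], r$nd)
  }
  perm <- sample(12)
  gsr3 <- gs_matrix(geno_matrix(gm2$calls[perm, ], gm2$loci))
  expect_equal(sort(gsr3$gs[upper.tri(gsr3$gs)]),
               sort(gsr2$gs[upper.tri(gsr2$gs)]))
  expect_error(gs_matrix(gm_from_codes(matrix(0L, 1, 3))), "two samples")
})

test_that("GS is invariant to locus order and allele relabeling, monotone in updates", {
  gm <- random_gm(6, 25, miss = 0.1, seed = 29)
  base <- gs_pair(gm, 1, 2)
  perm <- sample(25)
  gm_p <- geno_matrix(gm$calls[, perm], gm$loci[perm, ])
  expect_equal(gs_pair(gm_p, 1, 2)$gs, base$gs)
  flipped <- gm$calls
  flipped[gm$calls == 0L] <- 2L
  flipped[gm$calls == 2L] <- 0L
  loci_f <- gm$loci; loci_f$ref <- gm$loci$alt; loci_f$alt <- gm$loci$ref
  expect_equal(gs_pair(geno_matrix(flipped, loci_f), 1, 2)$gs, base$gs)
  # appending an agreeing locus never lowers GS; a disagreeing one never raises it
  agree <- cbind(gm$calls, extra = 1L)
  disagree <- cbind(gm$calls, extra = c(0L, 2L, rep(1L, 4)))
  loci_x <- rbind(gm$loci,
                  data.frame(chrom = "Chr9", pos = 1L, ref = "A", alt = "G",
                             id = "Chr9_1"))
  expect_gte(gs_pair(geno_matrix(agree, loci_x), 1, 2)$gs, base$gs)
  expect_lte(gs_pair(geno_matrix(disagree, loci_x), 1, 2)$gs, base$gs)
})

test_that("threshold calibration floors the minimum control GS at two decimals", {
  expect_equal(calibrate_threshold(c(0.9764, 0.9846))$threshold, 0.97)
  expect_equal(calibrate_threshold(0.995)$threshold, 0.99)
  expect_equal(calibrate_threshold(0.97)$threshold, 0.97)
  r <- calibrate_threshold(c(0.9805, 0.9764, 0.9846))
  expect_equal(r$min_gs, 0.9764)
  expect_equal(r$n_controls, 3L)
  expect_error(calibrate_threshold(numeric()), "no positive-control")
})

test_that("pairs are categorized by the two thresholds and roles by year", {
  pairs <- data.frame(id_a = c("IV1", "IV2", "L1", "E1"),
                      id_b = c("ED1", "ED2", "L2", "E2"),
                      gs = c(0.9928, 0.9344, 0.85, 0.975),
                      stringsAsFactors = FALSE)
  meta <- validate_sample_meta(data.frame(
    sample_id = c("IV1", "ED1", "IV2", "ED2", "L1", "L2", "E1", "E2"),
    grade = c("national", "provincial", "national", "national",
              "landrace", "landrace", "national", "national"),
    registration_year = c(1984L, 2018L, 1985L, 2010L, NA, NA, 1990L, 1990L),
    stringsAsFactors = FALSE))
  calls <- classify_pairs(pairs, meta, putative = 0.9, indisputable = 0.97)
  expect_equal(calls$category, c("indisputable", "putative", "none", "indisputable"))
  expect_equal(calls$iv[1], "IV1")
  expect_equal(calls$edv[1], "ED1")
  expect_equal(calls$basis[2], "registration_year")
  # equal years cannot resolve roles
  expect_equal(calls$basis[4], "unresolved")
  expect_true(is.na(calls$edv[4]))
  expect_error(classify_pairs(pairs, meta, putative = 0.98, indisputable = 0.97),
               "thresholds")
  s <- edv_summary(calls)
  expect_equal(s$n_above_putative, 3L)
  expect_equal(s$n_indisputable, 2L)
  expect_equal(s$edv_samples, c("ED1", "ED2"))
})
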