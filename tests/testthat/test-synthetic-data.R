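# Structured-population simulator: determinism, clone similarity, HWE and
# Balding-Nichols calibration.

small_cfg <- function(seed = 101L, ...) {
  sim_config(n_pops = 3L, pop_sizes = c(30L, 20L, 15L), n_loci = 400L,
             n_chromosomes = 5L, edv_pairs = 3L, control_pairs = 2L,
             close_pairs = 4L, seed = seed, ...)
}

test_that("configuration validation catches inconsistent settings", {
  expect_error(sim_config(n_pops = 2, pop_sizes = c(10, 10, 10)), "n_pops")
  expect_error(sim_config(miss_rate = 1.5), "rates")
  expect_error(sim_config(n_loci = 5, n_chromosomes = 15), "n_loci")
  expect_error(sim_config(pop_sizes = c(5L, 5L), n_pops = 2L,
                          edv_pairs = 4L, control_pairs = 2L),
               "not enough samples")
})

test_that("the same seed reproduces the cohort exactly", {
  s1 <- simulate_cohort(small_cfg())
  s2 <- simulate_cohort(small_cfg())
  expect_identical(s1$geno$calls, s2$geno$calls)
  expect_identical(s1$meta, s2$meta)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_cohort(small_cfg(seed = 102L))
  expect_false(identical(s1$geno$calls, s3$geno$calls))
})

test_that("cohort structure matches the configuration", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$geno$calls), 65L)
  expect_equal(ncol(sim$geno$calls), 400L)
  expect_equal(as.vector(table(sim$meta$population)), c(30L, 20L, 15L))
  expect_equal(sum(sim$truth$relation == "edv"), 3L)
  expect_equal(sum(sim$truth$relation == "control_copy"), 2L)
  expect_equal(sum(sim$truth$relation == "admixed"), floor(0.06 * 65))
  expect_equal(nrow(control_pairs(sim$meta)), 2L)
  # admixed samples carry depressed membership coefficients
  adm <- sim$truth$sample_id[sim$truth$relation == "admixed"]
  expect_true(all(sim$meta$membership[sim$meta$sample_id %in% adm] < 0.8))
  # planted close pairs are visible to the flanking filter
  expect_lte(length(flank_unique(sim$geno$loci, 150L)), 400L - 4L)
  # derived children are registered later than their parents
  edv_rows <- sim$truth[sim$truth$relation == "edv", ]
  yr <- function(id) sim$meta$registration_year[match(id, sim$meta$sample_id)]
  expect_true(all(yr(edv_rows$sample_id) > yr(edv_rows$parent_id)))
})

test_that("unmutated clones have GS exactly 1 with their parent", {
  sim <- simulate_cohort(small_cfg(edv_mutation_rate = 0,
                                   control_mutation_rate = 0, miss_rate = 0))
  clones <- sim$truth[!is.na(sim$truth$parent_id), ]
  for (i in seq_len(nrow(clones))) {
    r <- gs_pair(sim$geno, clones$sample_id[i], clones$parent_id[i])
    expect_equal(r$gs, 1)
  }
})

test_that("clone GS concentrates at 1 - mutation_rate (binomial bound)", {
  cfg <- sim_config(n_pops = 2L, pop_sizes = c(40L, 40L), n_loci = 1000L,
                    n_chromosomes = 5L, edv_pairs = 8L, control_pairs = 0L,
                    edv_mutation_rate = 0.02, miss_rate = 0,
                    close_pairs = 0L, seed = 103L)
  sim <- simulate_cohort(cfg)
  clones <- sim$truth[sim$truth$relation == "edv", ]
  band <- 3 * sqrt(0.02 * 0.98 / 1000)
  for (i in seq_len(nrow(clones))) {
    r <- gs_pair(sim$geno, clones$sample_id[i], clones$parent_id[i])
    expect_lt(abs(r$gs - 0.98), band)
  }
})

test_that("founders are near Hardy-Weinberg within populations", {
  cfg <- sim_config(n_pops = 1L, pop_sizes = 200L, n_loci = 500L,
                    n_chromosomes = 5L, edv_pairs = 0L, control_pairs = 0L,
                    admixed_fraction = 0, miss_rate = 0, close_pairs = 0L,
                    seed = 104L)
  sim <- simulate_cohort(cfg)
  st <- locus_stats(sim$geno)
  # per-locus Ho tracks expected heterozygosity on average
  expect_lt(abs(mean(st$ho) - mean(st$gd_allele)), 0.01)
})

test_that("across-population frequency variance tracks the Fst parameter", {
  f <- 0.15
  cfg <- sim_config(n_pops = 5L, pop_sizes = rep(150L, 5), n_loci = 300L,
                    n_chromosomes = 3L, edv_pairs = 0L, control_pairs = 0L,
                    admixed_fraction = 0, miss_rate = 0, fst = f,
                    close_pairs = 0L, seed = 105L)
  sim <- simulate_cohort(cfg)
  # recover each population's allele frequency from its founders, then
  # compare the across-population variance to the Balding-Nichols
  # prediction F * p_anc * (1 - p_anc), averaged over loci
  pops <- split(sim$meta$sample_id, sim$meta$population)
  p_hat <- sapply(pops, function(ids) {
    sub <- subset_geno(sim$geno, samples = ids)
    colMeans(sub$calls) / 2
  })
  v_obs <- apply(p_hat, 1, stats::var)
  p_bar <- rowMeans(p_hat)
  ratio <- mean(v_obs) / mean(f * p_bar * (1 - p_bar))
  expect_lt(abs(ratio - 1), 0.25)
})

test_that("truth evaluation scores clone recovery and founder separation", {
  sim <- simulate_cohort(small_cfg())
  gsr <- gs_matrix(sim$geno)
  calls <- classify_pairs(gs_pairs_table(gsr), sim$meta)
  ev <- truth_eval(calls, sim$truth)
  expect_equal(ev$n_clone_pairs, 5L)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$false_positive_rate, 0)
  empty <- truth_eval(calls, sim$truth[0, ])
  expect_true(is.na(empty$sensitivity))
  expect_equal(empty$n_clone_pairs, 0L)
})

test_that("threshold calibration recovers the floored control minimum", {
  sim <- simulate_cohort(small_cfg())
  cp <- control_pairs(sim$meta)
  gsr <- gs_matrix(sim$geno)
  ctrl_gs <- mapply(function(a, b) gsr$gs[a, b], cp$id_a, cp$id_b)
  thr <- calibrate_threshold(ctrl_gs)
  expect_equal(thr$threshold, floor(min(ctrl_gs) * 100 + 1e-9) / 100)
  expect_equal(thr$min_gs, min(ctrl_gs))
})

test_that("a cohort written to disk reloads identically", {
  sim <- simulate_cohort(small_cfg())
  dir <- tempfile()
  paths <- write_cohort(sim, dir)
  back <- read_vcf(paths[["vcf"]])
  expect_identical(back$calls, sim$geno$calls)
  meta <- read_sample_meta(paths[["meta"]])
  expect_equal(meta$sample_id, sim$meta$sample_id)
  expect_equal(meta$registration_year, sim$meta$registration_year)
  expect_equal(nrow(control_pairs(meta)), 2L)
})
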