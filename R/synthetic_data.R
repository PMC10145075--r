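# Structured-population genotype simulator used to validate the pipeline
# end to end without external data.
#
# The model: ancestral allele frequencies are Uniform(0.05, 0.95);
# subpopulation frequencies follow the Balding-Nichols model,
# Beta(p(1-F)/F, (1-p)(1-F)/F), so the across-population variance of the
# frequency at a locus is F p (1-p); founders draw genotypes
# Binomial(2, p_pop) independently per locus (Hardy-Weinberg within
# populations).  A configurable slice of samples is replaced by (a) 50/50
# admixed individuals drawing from the mean frequency of two populations,
# (b) clonal derivatives of named founders with a per-locus genotype-class
# mutation probability (essentially derived varieties), and (c)
# same-variety positive-control duplicates at a lower mutation rate.
# Genotypes are then masked missing-completely-at-random.

#' Simulation configuration
#'
#' Defaults reproduce the cohort structure the analysis is designed for:
#' five subpopulations of 159/72/51/50/17 samples (349 total) typed at
#' 1000 SNPs on 15 chromosomes, moderate differentiation (Fst 0.15), ~6%
#' admixed individuals, twelve derived-variety pairs mutated at 2% of loci,
#' six positive-control pairs at 1%, and 2% missing calls.
#'
#' @param n_pops Number of subpopulations.
#' @param pop_sizes Integer sizes per subpopulation (sum = total samples).
#' @param n_loci Number of SNP loci.
#' @param n_chromosomes Number of chromosomes loci are spread over.
#' @param fst Balding-Nichols differentiation parameter in (0, 1).
#' @param admixed_fraction Fraction of samples given 50/50 two-population
#'   admixed ancestry (their membership coefficient drops below 0.8).
#' @param edv_pairs Number of founder/derived-variety pairs.
#' @param edv_mutation_rate Per-locus probability a derived copy switches
#'   to a different genotype class.
#' @param control_pairs Number of same-variety positive-control pairs.
#' @param control_mutation_rate Per-locus mutation probability for control
#'   duplicates.
#' @param miss_rate I.i.d. probability a call is masked missing.
#' @param close_pairs Number of deliberately close locus pairs (< 150 bp
#'   apart) planted to exercise flanking-uniqueness filtering.
#' @param seed Integer seed; all randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_pops = 5L, pop_sizes = c(159L, 72L, 51L, 50L, 17L),
                       n_loci = 1000L, n_chromosomes = 15L, fst = 0.15,
                       admixed_fraction = 0.06, edv_pairs = 12L,
                       edv_mutation_rate = 0.02, control_pairs = 6L,
                       control_mutation_rate = 0.01, miss_rate = 0.02,
                       close_pairs = 10L, seed = 1L) {
  cfg <- list(n_pops = as.integer(n_pops), pop_sizes = as.integer(pop_sizes),
              n_loci = as.integer(n_loci),
              n_chromosomes = as.integer(n_chromosomes), fst = fst,
              admixed_fraction = admixed_fraction,
              edv_pairs = as.integer(edv_pairs),
              edv_mutation_rate = edv_mutation_rate,
              control_pairs = as.integer(control_pairs),
              control_mutation_rate = control_mutation_rate,
              miss_rate = miss_rate, close_pairs = as.integer(close_pairs),
              seed = as.integer(seed))
  if (length(cfg$pop_sizes) != cfg$n_pops) {
    stop("pop_sizes must have n_pops entries")
  }
  rates <- c(cfg$fst, cfg$admixed_fraction, cfg$edv_mutation_rate,
             cfg$control_mutation_rate, cfg$miss_rate)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$n_loci < cfg$n_chromosomes) stop("n_loci must be >= n_chromosomes")
  n <- sum(cfg$pop_sizes)
  if (2L * (cfg$edv_pairs + cfg$control_pairs) +
      ceiling(cfg$admixed_fraction * n) > n) {
    stop("not enough samples for the requested derived/control/admixed slots")
  }
  structure(cfg, class = "sim_config")
}

# random locus map: positions >= 400 bp apart per chromosome, plus
# `close_pairs` planted neighbors 40-150 bp from an existing locus
.sim_loci <- function(cfg) {
  n_base <- cfg$n_loci - cfg$close_pairs
  chrom_of <- sort(rep_len(seq_len(cfg$n_chromosomes), n_base))
  pos <- integer(n_base)
  for (c in seq_len(cfg$n_chromosomes)) {
    k <- sum(chrom_of == c)
    pos[chrom_of == c] <- cumsum(400L + sample.int(5000L, k, replace = TRUE))
  }
  chrom <- paste0("Chr", chrom_of)
  if (cfg$close_pairs > 0L) {
    host <- sample.int(n_base, cfg$close_pairs)
    near_pos <- pos[host] + sample(40:150, cfg$close_pairs, replace = TRUE)
    chrom <- c(chrom, chrom[host])
    pos <- c(pos, near_pos)
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  loci <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                     stringsAsFactors = FALSE)
  loci <- loci[order(loci$chrom, loci$pos), , drop = FALSE]
  rownames(loci) <- NULL
  loci
}

# length-safe single draw (sample() would misread a scalar as 1:x)
.pick1 <- function(x) x[sample.int(length(x), 1L)]

# mutate a genotype vector: each locus flips to one of the other two
# classes with probability `rate`
.mutate_calls <- function(g, rate) {
  hit <- which(stats::runif(length(g)) < rate & !is.na(g))
  if (length(hit)) {
    g[hit] <- vapply(g[hit], function(x) .pick1(setdiff(0:2, x)), integer(1))
  }
  g
}

#' Simulate a structured cohort with derived varieties and controls
#'
#' Generates a genotype matrix, sample metadata and a truth table under the
#' model described in [sim_config()].  Same config (including seed) always
#' yields identical output.
#'
#' @param cfg A [sim_config()].
#' @return List with `geno` (a [geno_matrix()]), `meta` (validated sample
#'   metadata: sample_id, province, grade, registration_year, population,
#'   membership, control_group) and `truth` (sample_id, relation in
#'   `founder`/`admixed`/`edv`/`control_copy`, parent_id, population).
#' @export
simulate_cohort <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  n <- sum(cfg$pop_sizes)
  m <- cfg$n_loci
  loci <- .sim_loci(cfg)
  p_anc <- stats::runif(m, 0.05, 0.95)
  f <- cfg$fst
  p_pop <- vapply(seq_len(cfg$n_pops), function(k) {
    stats::rbeta(m, p_anc * (1 - f) / f, (1 - p_anc) * (1 - f) / f)
  }, numeric(m))
  pop_of <- rep(seq_len(cfg$n_pops), cfg$pop_sizes)
  ids <- sprintf("S%03d", seq_len(n))
  calls <- matrix(NA_integer_, n, m)
  for (i in seq_len(n)) {
    calls[i, ] <- stats::rbinom(m, 2L, p_pop[, pop_of[i]])
  }
  relation <- rep("founder", n)
  parent <- rep(NA_character_, n)
  membership <- stats::runif(n, 0.85, 1.0)

  # admixed individuals: genotypes from the mean of two populations'
  # frequencies, own-population membership ~ 0.5
  n_adm <- floor(cfg$admixed_fraction * n)
  free <- seq_len(n)
  adm <- sort(sample(free, n_adm))
  for (i in adm) {
    other <- .pick1(setdiff(seq_len(cfg$n_pops), pop_of[i]))
    p_mix <- (p_pop[, pop_of[i]] + p_pop[, other]) / 2
    calls[i, ] <- stats::rbinom(m, 2L, p_mix)
    membership[i] <- stats::runif(1, 0.40, 0.70)
  }
  relation[adm] <- "admixed"
  free <- setdiff(free, adm)

  # derived-variety pairs: child is a mutated clone of a founder from the
  # same population
  take_pairs <- function(free, k) {
    parents <- children <- integer(k)
    for (j in seq_len(k)) {
      par <- .pick1(free)
      free <- setdiff(free, par)
      same_pop <- free[pop_of[free] == pop_of[par]]
      chl <- if (length(same_pop)) .pick1(same_pop) else .pick1(free)
      free <- setdiff(free, chl)
      parents[j] <- par; children[j] <- chl
    }
    list(parents = parents, children = children, free = free)
  }
  edv <- take_pairs(free, cfg$edv_pairs)
  free <- edv$free
  for (j in seq_len(cfg$edv_pairs)) {
    calls[edv$children[j], ] <- .mutate_calls(calls[edv$parents[j], ],
                                              cfg$edv_mutation_rate)
  }
  relation[edv$children] <- "edv"
  parent[edv$children] <- ids[edv$parents]

  # positive controls: same variety grown elsewhere, near-identical copies
  ctl <- take_pairs(free, cfg$control_pairs)
  for (j in seq_len(cfg$control_pairs)) {
    calls[ctl$children[j], ] <- .mutate_calls(calls[ctl$parents[j], ],
                                              cfg$control_mutation_rate)
  }
  relation[ctl$children] <- "control_copy"
  parent[ctl$children] <- ids[ctl$parents]
  control_group <- rep(NA_character_, n)
  control_group[ctl$parents] <- paste0("CG", seq_len(cfg$control_pairs))
  control_group[ctl$children] <- paste0("CG", seq_len(cfg$control_pairs))

  # MCAR missingness
  if (cfg$miss_rate > 0) {
    calls[matrix(stats::runif(n * m) < cfg$miss_rate, n, m)] <- NA_integer_
  }

  # registration metadata: elite cultivars get grades and years, the rest
  # are landraces; a derived child is always registered later than its
  # parent; controls are landraces (same variety, no separate registration)
  provinces <- c("Fujian", "Zhejiang", "Sichuan", "Anhui", "Hunan",
                 "Yunnan", "Guizhou", "Guangdong", "Jiangxi", "Chongqing",
                 "Hubei", "Shaanxi")
  grade <- sample(c("national", "provincial", "landrace"), n, replace = TRUE,
                  prob = c(0.18, 0.17, 0.65))
  grade[c(ctl$parents, ctl$children)] <- "landrace"
  year <- ifelse(grade %in% c("national", "provincial"),
                 sample(1975:2015, n, replace = TRUE), NA_integer_)
  for (j in seq_len(cfg$edv_pairs)) {
    par <- edv$parents[j]; chl <- edv$children[j]
    if (!grade[par] %in% c("national", "provincial")) {
      grade[par] <- .pick1(c("national", "provincial"))
    }
    if (!grade[chl] %in% c("national", "provincial")) {
      grade[chl] <- .pick1(c("national", "provincial"))
    }
    year[par] <- .pick1(1975:2005)
    year[chl] <- year[par] + .pick1(1:15)
  }
  meta <- data.frame(sample_id = ids,
                     province = sample(provinces, n, replace = TRUE),
                     grade = grade,
                     registration_year = as.integer(year),
                     population = pop_of,
                     membership = round(membership, 3),
                     control_group = control_group,
                     stringsAsFactors = FALSE)
  truth <- data.frame(sample_id = ids, relation = relation,
                      parent_id = parent, population = pop_of,
                      stringsAsFactors = FALSE)
  list(geno = geno_matrix(calls, loci, sample_ids = ids),
       meta = validate_sample_meta(meta), truth = truth)
}

#' Evaluate EDV classification against simulation truth
#'
#' Sensitivity is the fraction of true clone pairs (derived varieties and
#' control duplicates, paired with their parent) classified putative or
#' indisputable; the false-positive rate is the fraction of
#' founder-founder pairs from different populations called putative or
#' above.
#'
#' @param calls Classified pair table from [classify_pairs()].
#' @param truth Truth table from [simulate_cohort()].
#' @return List with `sensitivity`, `false_positive_rate`, `n_clone_pairs`
#'   and `n_cross_founder_pairs` (rates are `NA` when no pair of that kind
#'   exists).
#' @export
truth_eval <- function(calls, truth) {
  if (!nrow(truth)) {
    return(list(sensitivity = NA_real_, false_positive_rate = NA_real_,
                n_clone_pairs = 0L, n_cross_founder_pairs = 0L))
  }
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  clone <- truth[!is.na(truth$parent_id), , drop = FALSE]
  clone_keys <- key(clone$sample_id, clone$parent_id)
  pair_keys <- key(calls$id_a, calls$id_b)
  hit <- calls$category[match(clone_keys, pair_keys)]
  sens <- if (length(clone_keys)) {
    mean(hit %in% c("putative", "indisputable"), na.rm = FALSE)
  } else NA_real_
  founders <- truth$sample_id[truth$relation == "founder"]
  pop_of <- truth$population[match(calls$id_a, truth$sample_id)]
  pop_of_b <- truth$population[match(calls$id_b, truth$sample_id)]
  cross <- calls$id_a %in% founders & calls$id_b %in% founders &
    pop_of != pop_of_b
  fpr <- if (any(cross)) {
    mean(calls$category[cross] %in% c("putative", "indisputable"))
  } else NA_real_
  list(sensitivity = sens, false_positive_rate = fpr,
       n_clone_pairs = length(clone_keys),
       n_cross_founder_pairs = sum(cross))
}

#' Write a simulated cohort to standard files
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three written paths (`vcf`,
#'   `meta`, `truth`), invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "genotypes.vcf"),
             meta = file.path(dir, "samples.csv"),
             truth = file.path(dir, "truth.tsv"))
  write_vcf(sim$geno, paths["vcf"])
  utils::write.csv(sim$meta, paths["meta"], row.names = FALSE, na = "")
  utils::write.table(sim$truth, paths["truth"], sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  invisible(paths)
}
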