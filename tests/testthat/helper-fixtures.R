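# Fixture builders shared across the suite.  Genotype codes: 0 hom-ref,
# 1 het, 2 hom-alt, NA missing.

# genotype matrix from a code matrix (samples x loci); loci spaced 1 kb
# apart on one chromosome unless positions are supplied
gm_from_codes <- function(codes, chrom = NULL, pos = NULL) {
  codes <- as.matrix(codes)
  m <- ncol(codes)
  if (is.null(chrom)) chrom <- rep("Chr1", m)
  if (is.null(pos)) {
    pos <- stats::ave(seq_len(m), chrom, FUN = seq_along) * 1000L
  }
  loci <- data.frame(chrom = chrom, pos = pos,
                     ref = rep("A", m), alt = rep("G", m),
                     stringsAsFactors = FALSE)
  if (is.null(rownames(codes))) {
    rownames(codes) <- sprintf("S%02d", seq_len(nrow(codes)))
  }
  geno_matrix(codes, loci)
}

# random genotype matrix with i.i.d. uniform classes and MCAR missingness
random_gm <- function(n, m, miss = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  codes <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  if (miss > 0) codes[matrix(runif(n * m) < miss, n, m)] <- NA_integer_
  gm_from_codes(codes)
}

# minimal metadata table for a genotype matrix
meta_for <- function(gm, population = 1L, membership = 1,
                     year = NA_integer_, grade = NULL) {
  ids <- rownames(gm$calls)
  n <- length(ids)
  if (is.null(grade)) {
    grade <- ifelse(is.na(rep_len(year, n)), "landrace", "national")
  }
  validate_sample_meta(data.frame(
    sample_id = ids, province = "Fujian",
    grade = rep_len(grade, n),
    registration_year = rep_len(as.integer(year), n),
    population = rep_len(as.integer(population), n),
    membership = rep_len(membership, n),
    control_group = NA_character_, stringsAsFactors = FALSE))
}

extdata <- function(f) {
  system.file("extdata", f, package = "snpEDV", mustWork = TRUE)
}
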