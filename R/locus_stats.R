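# Per-locus diversity statistics: MAF, missing rate, observed
# heterozygosity, gene diversity and Botstein's polymorphic information
# content.  All denominators use called genotypes only; a locus with zero
# calls yields NA statistics (flagged, never silently zero).
#
# GD and PIC are exposed under two conventions.  The "allele" convention
# plugs the two allele frequencies into the formulas, bounding GD at 0.5
# and PIC at 0.375 for a biallelic SNP.  The "genotype" convention plugs in
# the three genotype-class frequencies instead, which raises the attainable
# maxima (PIC up to ~0.59) and matches reporting styles that treat each
# diploid class as a distinct state.

.check_locus <- function(gm, locus) {
  if (is.character(locus)) locus <- match(locus, gm$loci$id)
  if (is.na(locus) || locus < 1L || locus > ncol(gm$calls)) {
    stop("locus index out of range")
  }
  locus
}

.called <- function(g) g[!is.na(g)]

#' Alternate-allele frequency and MAF at one locus
#'
#' Counts alleles over called genotypes: `p_alt = (#het + 2 #alt_hom) /
#' (2 #called)`.  The minor allele frequency is `min(p_alt, 1 - p_alt)`.
#'
#' @param gm A [geno_matrix()].
#' @param locus Locus index or id.
#' @return List with `p_alt`, `maf` and `n_called`.  An all-missing locus
#'   returns `NA` statistics with a warning.
#' @export
allele_freq <- function(gm, locus) {
  locus <- .check_locus(gm, locus)
  g <- .called(gm$calls[, locus])
  if (!length(g)) {
    warning("locus ", gm$loci$id[locus], " has no called genotypes")
    return(list(p_alt = NA_real_, maf = NA_real_, n_called = 0L))
  }
  p <- sum(g) / (2 * length(g))
  list(p_alt = p, maf = min(p, 1 - p), n_called = length(g))
}

#' Observed heterozygosity at one locus
#'
#' Fraction of called genotypes that are heterozygous.
#'
#' @inheritParams allele_freq
#' @return A fraction in `[0, 1]`, or `NA` (with a warning) if the locus has
#'   no called genotypes.
#' @export
observed_het <- function(gm, locus) {
  locus <- .check_locus(gm, locus)
  g <- .called(gm$calls[, locus])
  if (!length(g)) {
    warning("locus ", gm$loci$id[locus], " has no called genotypes")
    return(NA_real_)
  }
  mean(g == 1L)
}

#' Gene diversity (expected heterozygosity) at one locus
#'
#' `1 - sum(f^2)` over allele frequencies (`convention = "allele"`, the
#' default, maximum 0.5) or over the three genotype-class frequencies
#' (`convention = "genotype"`, maximum 2/3).
#'
#' @inheritParams allele_freq
#' @param convention `"allele"` or `"genotype"`.
#' @return A fraction, or `NA` with a warning for an all-missing locus.
#' @export
gene_diversity <- function(gm, locus, convention = c("allele", "genotype")) {
  convention <- match.arg(convention)
  locus <- .check_locus(gm, locus)
  g <- .called(gm$calls[, locus])
  if (!length(g)) {
    warning("locus ", gm$loci$id[locus], " has no called genotypes")
    return(NA_real_)
  }
  f <- .freqs(g, convention)
  1 - sum(f^2)
}

#' Polymorphic information content at one locus
#'
#' Botstein's PIC, `1 - sum(f_i^2) - sum_{i<j} 2 f_i^2 f_j^2`, over allele
#' frequencies (default; biallelic maximum 0.375) or genotype-class
#' frequencies (maximum ~0.593 at three equal classes).
#'
#' @inheritParams gene_diversity
#' @return A fraction, or `NA` with a warning for an all-missing locus.
#' @export
pic <- function(gm, locus, convention = c("allele", "genotype")) {
  convention <- match.arg(convention)
  locus <- .check_locus(gm, locus)
  g <- .called(gm$calls[, locus])
  if (!length(g)) {
    warning("locus ", gm$loci$id[locus], " has no called genotypes")
    return(NA_real_)
  }
  pic_from_freqs(.freqs(g, convention))
}

.freqs <- function(g, convention) {
  if (convention == "allele") {
    p <- sum(g) / (2 * length(g))
    c(p, 1 - p)
  } else {
    tabulate(g + 1L, nbins = 3L) / length(g)
  }
}

#' Botstein PIC from a frequency vector
#'
#' @param f Vector of state frequencies summing to 1.
#' @return `1 - sum(f^2) - sum_{i<j} 2 f_i^2 f_j^2`.
#' @export
pic_from_freqs <- function(f) {
  s2 <- sum(f^2)
  1 - s2 - (s2^2 - sum(f^4))
}

#' Per-locus statistics table
#'
#' Computes, for every locus, the missing rate, alternate-allele frequency,
#' MAF, observed heterozygosity, and gene diversity and PIC under both the
#' allele and genotype-class conventions.  Loci with no called genotypes get
#' `NA` in every statistic and `FALSE` in `defined`.
#'
#' @param gm A [geno_matrix()].
#' @return Data frame with columns `id`, `chrom`, `pos`, `n_called`,
#'   `miss_rate`, `p_alt`, `maf`, `ho`, `gd_allele`, `gd_genotype`,
#'   `pic_allele`, `pic_genotype`, `defined`.
#' @export
locus_stats <- function(gm) {
  calls <- gm$calls
  n <- nrow(calls)
  n_ref <- colSums(calls == 0L, na.rm = TRUE)
  n_het <- colSums(calls == 1L, na.rm = TRUE)
  n_alt <- colSums(calls == 2L, na.rm = TRUE)
  n_called <- n_ref + n_het + n_alt
  ok <- n_called > 0L
  p_alt <- ifelse(ok, (n_het + 2 * n_alt) / (2 * n_called), NA_real_)
  q <- 1 - p_alt
  g0 <- n_ref / n_called; g1 <- n_het / n_called; g2 <- n_alt / n_called
  s2g <- g0^2 + g1^2 + g2^2
  s4g <- g0^4 + g1^4 + g2^4
  s2a <- p_alt^2 + q^2
  s4a <- p_alt^4 + q^4
  out <- data.frame(
    id = gm$loci$id, chrom = gm$loci$chrom, pos = gm$loci$pos,
    n_called = n_called,
    miss_rate = (n - n_called) / n,
    p_alt = p_alt,
    maf = pmin(p_alt, q),
    ho = ifelse(ok, g1, NA_real_),
    gd_allele = 1 - s2a,
    gd_genotype = ifelse(ok, 1 - s2g, NA_real_),
    pic_allele = 1 - s2a - (s2a^2 - s4a),
    pic_genotype = ifelse(ok, 1 - s2g - (s2g^2 - s4g), NA_real_),
    defined = ok,
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Cohort summary of per-locus statistics
#'
#' Means of every numeric statistic, the fraction of loci exceeding each
#' requested threshold, and per-chromosome locus counts.  Loci flagged as
#' undefined are dropped before averaging.
#'
#' @param stats A data frame of per-locus statistics ([locus_stats()] output
#'   or any table with numeric statistic columns, e.g. a published per-SNP
#'   panel table).
#' @param thresholds Numeric vector; for each statistic and threshold `t`,
#'   the fraction of loci with value `> t` is reported.
#' @return List with `n_loci`, `means` (named numeric), `prop_above`
#'   (matrix statistic x threshold) and `chrom_counts` (named integer, or
#'   `NULL` when no `chrom` column is present).
#' @export
summarize_locus_stats <- function(stats, thresholds = 0.3) {
  stats <- as.data.frame(stats)
  if (!nrow(stats)) stop("empty statistics table")
  if (!is.null(stats$defined)) stats <- stats[stats$defined, , drop = FALSE]
  skip <- c("pos", "n_called", "registration_year", "population")
  num <- vapply(stats, is.numeric, logical(1)) & !(names(stats) %in% skip)
  if (!any(num)) stop("no numeric statistic columns to summarize")
  vals <- stats[num]
  means <- vapply(vals, mean, numeric(1), na.rm = TRUE)
  prop <- sapply(thresholds, function(t) {
    vapply(vals, function(v) mean(v > t, na.rm = TRUE), numeric(1))
  })
  prop <- matrix(prop, nrow = sum(num),
                 dimnames = list(names(vals), paste0(">", thresholds)))
  cc <- if (!is.null(stats$chrom)) table(stats$chrom) else NULL
  list(n_loci = nrow(stats), means = means, prop_above = prop,
       chrom_counts = cc)
}
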