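# Two-stage SNP filtering: a candidate stage (MAF > 0.1, missing < 20%,
# no other variant within 150 bp) followed by a core stage (MAF > 0.15,
# missing <= 5%, PIC > 0.15) with optional fixed-width binning that keeps
# the highest-PIC SNP per bin for uniform genome coverage.  Inequalities are
# deliberately strict or inclusive exactly as stated in each threshold's
# definition.

#' Filtering configuration for core-SNP selection
#'
#' @param candidate_maf_min Candidate stage keeps loci with MAF strictly
#'   above this (default 0.1).
#' @param candidate_miss_max Candidate stage keeps loci with missing rate
#'   strictly below this (default 0.20).
#' @param flank_bp Exclusion radius in bases: a candidate must have no other
#'   variant within this distance on the same chromosome (default 150).
#' @param core_maf_min Core stage keeps loci with MAF strictly above this
#'   (default 0.15).
#' @param core_miss_max Core stage keeps loci with missing rate at or below
#'   this (default 0.05, inclusive).
#' @param core_pic_min Core stage keeps loci with PIC strictly above this
#'   (default 0.15).
#' @param min_core_size Warn if the core set ends up smaller (default 300).
#' @param bin_width Bin width in bases for uniform-coverage thinning, or
#'   `NULL` to skip binning.
#' @param pic_convention Which PIC convention the core threshold and bin
#'   argmax use: `"allele"` (default) or `"genotype"`.
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(candidate_maf_min = 0.1, candidate_miss_max = 0.20,
                          flank_bp = 150L, core_maf_min = 0.15,
                          core_miss_max = 0.05, core_pic_min = 0.15,
                          min_core_size = 300L, bin_width = NULL,
                          pic_convention = c("allele", "genotype")) {
  cfg <- list(candidate_maf_min = candidate_maf_min,
              candidate_miss_max = candidate_miss_max,
              flank_bp = as.integer(flank_bp),
              core_maf_min = core_maf_min, core_miss_max = core_miss_max,
              core_pic_min = core_pic_min,
              min_core_size = as.integer(min_core_size),
              bin_width = if (is.null(bin_width)) NULL else as.integer(bin_width),
              pic_convention = match.arg(pic_convention))
  fr <- unlist(cfg[c("candidate_maf_min", "candidate_miss_max",
                     "core_maf_min", "core_miss_max", "core_pic_min")])
  if (any(fr < 0 | fr > 1)) stop("filter fractions must lie in [0, 1]")
  if (cfg$flank_bp < 0L) stop("flank_bp must be >= 0")
  if (cfg$min_core_size < 1L) stop("min_core_size must be >= 1")
  structure(cfg, class = "filter_config")
}

#' Loci with no neighboring variant within a flanking window
#'
#' Keeps exactly the loci whose nearest other variant on the same chromosome
#' is more than `flank_bp` bases away; both members of a close pair are
#' dropped.  This is the call-set proxy for requiring an invariant flanking
#' sequence around an assayable SNP.
#'
#' @param loci Locus table (`chrom`, `pos`), sorted by chromosome then
#'   position.
#' @param flank_bp Exclusion radius in bases.
#' @return Integer vector of kept row indices into `loci`.
#' @export
flank_unique <- function(loci, flank_bp = 150L) {
  loci <- as.data.frame(loci)
  n <- nrow(loci)
  if (n == 0L) return(integer())
  o <- order(loci$chrom, loci$pos)
  if (!identical(o, seq_len(n))) stop("loci must be sorted by (chrom, pos)")
  if (n == 1L) return(1L)
  same_next <- loci$chrom[-n] == loci$chrom[-1]
  gap_next <- c(ifelse(same_next, loci$pos[-1] - loci$pos[-n], NA_integer_), NA_integer_)
  gap_prev <- c(NA_integer_, gap_next[-n])
  crowded <- (!is.na(gap_next) & gap_next <= flank_bp) |
    (!is.na(gap_prev) & gap_prev <= flank_bp)
  which(!crowded)
}

#' Candidate-SNP filter
#'
#' First-stage screen: MAF strictly above `candidate_maf_min`, missing rate
#' strictly below `candidate_miss_max`, and flanking-unique within
#' `flank_bp`.
#'
#' @param gm A [geno_matrix()].
#' @param stats Per-locus statistics from [locus_stats()] (computed if
#'   omitted).
#' @param config A [filter_config()].
#' @return Integer vector of candidate locus indices (matrix column order).
#' @export
filter_candidates <- function(gm, stats = NULL, config = filter_config()) {
  if (is.null(stats)) stats <- locus_stats(gm)
  iso <- logical(nrow(stats))
  iso[flank_unique(gm$loci, config$flank_bp)] <- TRUE
  keep <- stats$defined &
    stats$maf > config$candidate_maf_min &
    stats$miss_rate < config$candidate_miss_max &
    iso
  which(keep)
}

#' Core-SNP selection
#'
#' Applies the core thresholds (MAF strictly above `core_maf_min`, missing
#' rate at or below `core_miss_max`, PIC strictly above `core_pic_min`) to
#' the candidate set, then — when `bin_width` is set — partitions each
#' chromosome into fixed-width bins and keeps the highest-PIC SNP per
#' occupied bin so the retained set covers the genome uniformly.  Warns when
#' fewer than `min_core_size` SNPs survive.
#'
#' @inheritParams filter_candidates
#' @param candidates Candidate indices from [filter_candidates()] (computed
#'   if omitted).
#' @return Integer vector of core locus indices, in genome order.
#' @export
select_core <- function(gm, stats = NULL, config = filter_config(),
                        candidates = NULL) {
  if (is.null(stats)) stats <- locus_stats(gm)
  if (is.null(candidates)) candidates <- filter_candidates(gm, stats, config)
  pic_col <- paste0("pic_", config$pic_convention)
  st <- stats[candidates, , drop = FALSE]
  keep <- st$maf > config$core_maf_min &
    st$miss_rate <= config$core_miss_max &
    st[[pic_col]] > config$core_pic_min
  core <- candidates[keep]
  if (!is.null(config$bin_width) && length(core)) {
    st <- stats[core, , drop = FALSE]
    bin <- paste(st$chrom, (st$pos - 1L) %/% config$bin_width)
    best <- tapply(seq_along(core), bin, function(i) i[which.max(st[[pic_col]][i])])
    core <- sort(core[unlist(best)])
  }
  if (length(core) == 0L) {
    warning("core SNP set is empty under the current thresholds")
  } else if (length(core) < config$min_core_size) {
    warning("core SNP set has ", length(core), " loci, fewer than min_core_size = ",
            config$min_core_size)
  }
  core
}

#' Core-SNP report table
#'
#' @param gm A [geno_matrix()].
#' @param core Core locus indices from [select_core()].
#' @param stats Per-locus statistics (computed if omitted).
#' @return Data frame (id, chrom, pos, maf, miss_rate, ho, pic) for the core
#'   set, suitable for TSV export.
#' @export
core_snp_table <- function(gm, core, stats = NULL) {
  if (is.null(stats)) stats <- locus_stats(gm)
  st <- stats[core, c("id", "chrom", "pos", "maf", "miss_rate", "ho",
                      "pic_allele", "pic_genotype"), drop = FALSE]
  rownames(st) <- NULL
  st
}
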