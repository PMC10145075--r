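# Canonical genotype container and standard-format I/O.
#
# Genotype calls are stored as an integer matrix (samples x loci) with the
# fixed encoding 0 = homozygous reference, 1 = heterozygous, 2 = homozygous
# alternate, NA = missing.  Every downstream statistic operates on genotype
# classes, so phase is discarded on input and half-calls are masked.

GENO_CODES <- c(REF_HOM = 0L, HET = 1L, ALT_HOM = 2L)

#' Construct a genotype matrix
#'
#' Bundles a samples-by-loci matrix of diploid genotype codes with its locus
#' table into the container used by every analysis stage.  Codes are
#' `0` (homozygous reference), `1` (heterozygous), `2` (homozygous
#' alternate) and `NA` (missing).
#'
#' @param calls Integer matrix, samples in rows, loci in columns; entries in
#'   `{0, 1, 2, NA}`.  Row names, if absent, are taken from `sample_ids`.
#' @param loci Data frame with one row per locus and columns `chrom`,
#'   `pos` (1-based), `ref`, `alt` and optionally `id`.  Missing ids default
#'   to `"<chrom>_<pos>"`.
#' @param sample_ids Character vector of unique sample identifiers; defaults
#'   to `rownames(calls)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `calls`
#'   (coded integer matrix with sample row names and locus-id column names)
#'   and `loci` (the locus table).
#' @export
geno_matrix <- function(calls, loci, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) {
    stop("sample_ids must be given (or calls must have row names)")
  }
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(calls)) {
    stop("length(sample_ids) does not match nrow(calls)")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  if (nrow(calls) == 0L) stop("a genotype matrix needs at least one sample")
  loci <- as.data.frame(loci, stringsAsFactors = FALSE)
  req <- c("chrom", "pos", "ref", "alt")
  miss <- setdiff(req, names(loci))
  if (length(miss)) stop("loci is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(loci) != ncol(calls)) {
    stop("nrow(loci) does not match ncol(calls)")
  }
  if (is.null(loci$id)) {
    loci$id <- if (nrow(loci)) paste0(loci$chrom, "_", loci$pos) else character()
  }
  loci$pos <- as.integer(loci$pos)
  if (nrow(loci)) {
    if (any(loci$pos < 1L)) stop("locus positions must be >= 1")
    key <- paste(loci$chrom, loci$pos)
    if (anyDuplicated(key)) {
      stop("duplicate loci at: ", paste(unique(key[duplicated(key)]), collapse = ", "))
    }
    bases <- c("A", "C", "G", "T")
    if (!all(loci$ref %in% bases) || !all(loci$alt %in% bases)) {
      stop("ref/alt alleles must be single bases A/C/G/T")
    }
    if (any(loci$ref == loci$alt)) stop("ref and alt alleles must differ")
    bad <- calls[!is.na(calls) & !(calls %in% 0:2)]
    if (length(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  }
  rownames(calls) <- sample_ids
  colnames(calls) <- loci$id
  structure(list(calls = calls, loci = loci), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d loci (%.1f%% missing)\n",
              nrow(x$calls), ncol(x$calls),
              if (length(x$calls)) 100 * mean(is.na(x$calls)) else 0))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$calls)

#' Sample identifiers of a genotype matrix
#' @param gm A `geno_matrix`.
#' @return Character vector of sample ids, in matrix order.
#' @export
sample_ids <- function(gm) rownames(gm$calls)

#' Subset a genotype matrix
#'
#' @param gm A `geno_matrix`.
#' @param samples Sample ids or indices to keep (default all).
#' @param loci Locus ids or indices to keep (default all).
#' @return A `geno_matrix` restricted to the requested samples and loci.
#' @export
subset_geno <- function(gm, samples = NULL, loci = NULL) {
  si <- if (is.null(samples)) seq_len(nrow(gm$calls)) else samples
  li <- if (is.null(loci)) seq_len(ncol(gm$calls)) else loci
  if (is.character(si)) si <- match(si, rownames(gm$calls))
  if (is.character(li)) li <- match(li, gm$loci$id)
  if (anyNA(si)) stop("unknown sample id in subset")
  if (anyNA(li)) stop("unknown locus id in subset")
  geno_matrix(gm$calls[si, li, drop = FALSE], gm$loci[li, , drop = FALSE])
}

# Map raw GT strings to genotype codes.  Phase separators are equivalent;
# any half-call or unparsable value is missing.
.gt_to_code <- function(gt) {
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- rep(NA_integer_, length(gt))
  code[gt %in% "0/0"] <- 0L
  code[gt %in% c("0/1", "1/0")] <- 1L
  code[gt %in% "1/1"] <- 2L
  code
}

#' Read a genotype matrix from VCF
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}) into the coded genotype matrix.
#' Only the GT field is used; `0/0` maps to 0, `0/1`/`1/0` to 1, `1/1` to 2,
#' and `./.` or any half-call to missing.  Phased and unphased separators
#' are treated identically.  Record order is preserved.
#'
#' @param path Path to an (optionally bgzipped) VCF file.
#' @param biallelic_only If `TRUE` (default) multi-allelic records are
#'   skipped with a message; if `FALSE` they raise an error.
#' @return A [geno_matrix()].
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(fix) == 0L) stop("VCF contains no variant records: ", path)
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE) |
    nchar(fix[, "REF"]) != 1L | nchar(fix[, "ALT"]) != 1L
  if (any(multi)) {
    if (!biallelic_only) {
      stop("multi-allelic or non-SNP record at ",
           fix[which(multi)[1], "CHROM"], ":", fix[which(multi)[1], "POS"])
    }
    message("skipping ", sum(multi), " multi-allelic/non-SNP record(s)")
  }
  keep <- !multi
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(gt) || ncol(gt) == 0L) stop("VCF has no sample genotype columns: ", path)
  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) stop("no biallelic SNP records left after filtering: ", path)
  key <- paste(fix[, "CHROM"], fix[, "POS"])
  if (anyDuplicated(key)) {
    stop("duplicate (chrom, pos) record: ", key[duplicated(key)][1])
  }
  calls <- t(apply(gt, 2, .gt_to_code))
  # a single-record VCF collapses to a vector under apply
  if (nrow(fix) == 1L) calls <- matrix(calls, ncol = 1L)
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- NA_character_
  loci <- data.frame(chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
                     ref = fix[, "REF"], alt = fix[, "ALT"],
                     stringsAsFactors = FALSE)
  loci$id <- ifelse(is.na(id), paste0(loci$chrom, "_", loci$pos), id)
  geno_matrix(calls, loci, sample_ids = colnames(gt))
}

#' Write a genotype matrix to VCF
#'
#' Emits minimal VCF 4.2 with a GT-only FORMAT; missing calls become `./.`.
#' `read_vcf(write_vcf(gm))` restores the sample ids, loci and calls exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  gt_str <- c("0/0", "0/1", "1/1")
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=snpEDV",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(gm$calls)), collapse = "\t")
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  if (ncol(gm$calls)) {
    body <- vapply(seq_len(ncol(gm$calls)), function(j) {
      g <- gm$calls[, j]
      s <- ifelse(is.na(g), "./.", gt_str[g + 1L])
      paste(c(gm$loci$chrom[j], gm$loci$pos[j], gm$loci$id[j],
              gm$loci$ref[j], gm$loci$alt[j], ".", "PASS", ".", "GT", s),
            collapse = "\t")
    }, character(1))
    writeLines(body, con)
  }
  invisible(path)
}

#' Read a sample metadata table
#'
#' Reads a CSV or TSV (auto-detected from the file extension) holding
#' per-sample identity and registration information.  Recognized columns are
#' `sample_id` (required), `province`, `grade` (one of `national`,
#' `provincial`, `landrace`, `unknown`), `registration_year`, `population`,
#' `membership` and `control_group`; others are preserved untouched.
#' Samples sharing a non-empty `control_group` form a known same-variety
#' positive-control pair.
#'
#' @param path Path to a delimited text file with a header row.
#' @return A data frame with one row per sample and all recognized columns
#'   present (absent ones filled with `NA`).
#' @export
read_sample_meta <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  meta <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                            stringsAsFactors = FALSE, na.strings = c("", "NA"),
                            check.names = FALSE)
  validate_sample_meta(meta)
}

#' Validate a sample metadata table
#'
#' @param meta Data frame with at least a `sample_id` column.
#' @return The metadata with recognized columns normalized; errors on
#'   duplicate ids, out-of-range membership coefficients, unknown grades,
#'   or a registration year attached to an unregistered grade.
#' @export
validate_sample_meta <- function(meta) {
  if (is.null(meta$sample_id)) stop("metadata must have a sample_id column")
  meta$sample_id <- as.character(meta$sample_id)
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(meta$sample_id[duplicated(meta$sample_id)]), collapse = ", "))
  }
  for (col in c("province", "grade", "control_group")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_character_
    meta[[col]] <- as.character(meta[[col]])
  }
  for (col in c("registration_year", "population")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA_integer_
    meta[[col]] <- as.integer(meta[[col]])
  }
  if (is.null(meta$membership)) meta$membership <- NA_real_
  meta$membership <- as.numeric(meta$membership)
  grades <- c("national", "provincial", "landrace", "unknown")
  bad <- !is.na(meta$grade) & !(meta$grade %in% grades)
  if (any(bad)) stop("unknown grade value(s): ", paste(unique(meta$grade[bad]), collapse = ", "))
  ok <- is.na(meta$membership) | (meta$membership >= 0 & meta$membership <= 1)
  if (!all(ok)) {
    stop("membership outside [0,1] for: ", paste(meta$sample_id[!ok], collapse = ", "))
  }
  reg <- !is.na(meta$registration_year)
  if (any(reg & !(meta$grade %in% c("national", "provincial")))) {
    stop("registration_year requires grade national or provincial: ",
         paste(meta$sample_id[reg & !(meta$grade %in% c("national", "provincial"))],
               collapse = ", "))
  }
  meta
}

#' Positive-control pairs declared in a metadata table
#'
#' @param meta Validated sample metadata.
#' @return Data frame with columns `id_a`, `id_b`, `control_group`, one row
#'   per declared same-variety pair.  Groups with other than two members are
#'   rejected.
#' @export
control_pairs <- function(meta) {
  grp <- meta$control_group
  keep <- !is.na(grp) & grp != ""
  if (!any(keep)) {
    return(data.frame(id_a = character(), id_b = character(),
                      control_group = character(), stringsAsFactors = FALSE))
  }
  sp <- split(meta$sample_id[keep], grp[keep])
  n <- lengths(sp)
  if (any(n != 2L)) {
    stop("control_group(s) without exactly two members: ",
         paste(names(sp)[n != 2L], collapse = ", "))
  }
  data.frame(id_a = vapply(sp, `[`, character(1), 1L),
             id_b = vapply(sp, `[`, character(1), 2L),
             control_group = names(sp), row.names = NULL,
             stringsAsFactors = FALSE)
}
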