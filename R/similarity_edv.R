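# Pairwise genetic similarity and EDV classification.
#
# GS = NS / (NS + ND), where NS and ND count co-called loci at which two
# samples carry identical / different genotype classes.  Classes are
# compared exactly (a heterozygote differs from either homozygote) and loci
# missing in either sample are excluded from both counts — pairwise-complete
# deletion.  The "indisputable" threshold is calibrated from same-variety
# positive controls by the tail principle: the minimum control GS, floored
# to two decimals.

# NS/ND/compared matrices via indicator cross-products: for code g the
# matrix I_g I_g' counts loci where both samples are called and equal to g.
.pair_counts <- function(calls) {
  called <- !is.na(calls)
  mode(called) <- "numeric"
  compared <- tcrossprod(called)
  ns <- matrix(0, nrow(calls), nrow(calls))
  for (g in 0:2) {
    ind <- !is.na(calls) & calls == g
    mode(ind) <- "numeric"
    ns <- ns + tcrossprod(ind)
  }
  list(ns = ns, nd = compared - ns, compared = compared)
}

#' Genetic similarity between one pair of samples
#'
#' Tallies NS (identical genotype classes), ND (differing classes) and
#' GS = NS/(NS+ND) over loci called in both samples.
#'
#' @param gm A [geno_matrix()].
#' @param a,b Sample ids or indices, `a != b`.
#' @param loci Optional locus ids/indices restricting the comparison.
#' @return List with `id_a`, `id_b`, `ns`, `nd`, `compared` and `gs`
#'   (`NA` with a warning when no locus is co-called).
#' @export
gs_pair <- function(gm, a, b, loci = NULL) {
  ids <- rownames(gm$calls)
  if (is.character(a)) a <- match(a, ids)
  if (is.character(b)) b <- match(b, ids)
  if (is.na(a) || is.na(b)) stop("unknown sample id")
  if (a == b) stop("gs_pair requires two distinct samples")
  ga <- gm$calls[a, ]
  gb <- gm$calls[b, ]
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, gm$loci$id)
    ga <- ga[loci]; gb <- gb[loci]
  }
  both <- !is.na(ga) & !is.na(gb)
  ns <- sum(ga[both] == gb[both])
  nd <- sum(both) - ns
  gs <- if (ns + nd == 0L) {
    warning("samples ", ids[a], " and ", ids[b], " share no co-called loci")
    NA_real_
  } else ns / (ns + nd)
  list(id_a = ids[a], id_b = ids[b], ns = ns, nd = nd,
       compared = ns + nd, gs = gs)
}

#' All-pairs genetic similarity matrix
#'
#' Computes NS, ND and GS for every unordered sample pair.
#'
#' @param gm A [geno_matrix()] with at least two samples.
#' @param loci Optional locus ids/indices restricting the comparison (e.g.
#'   the core SNP set).
#' @return Object of class `gs_result`: list of symmetric matrices `gs`,
#'   `ns`, `nd`, `compared` (diagonal of `gs` set to `NA`) plus `n_pairs`.
#' @export
gs_matrix <- function(gm, loci = NULL) {
  calls <- gm$calls
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, gm$loci$id)
    calls <- calls[, loci, drop = FALSE]
  }
  n <- nrow(calls)
  if (n < 2L) stop("gs_matrix needs at least two samples")
  pc <- .pair_counts(calls)
  gs <- ifelse(pc$compared > 0, pc$ns / pc$compared, NA_real_)
  diag(gs) <- NA_real_
  ids <- rownames(calls)
  dimnames(gs) <- dimnames(pc$ns) <- dimnames(pc$nd) <-
    dimnames(pc$compared) <- list(ids, ids)
  structure(list(gs = gs, ns = pc$ns, nd = pc$nd, compared = pc$compared,
                 n_pairs = n * (n - 1L) / 2L),
            class = "gs_result")
}

#' @export
print.gs_result <- function(x, ...) {
  cat(sprintf("gs_result: %d samples, %d unordered pairs\n",
              nrow(x$gs), x$n_pairs))
  v <- x$gs[upper.tri(x$gs)]
  cat(sprintf("  GS range %.4f-%.4f, median %.4f\n",
              min(v, na.rm = TRUE), max(v, na.rm = TRUE),
              stats::median(v, na.rm = TRUE)))
  invisible(x)
}

#' Long-format pair table of a GS matrix
#'
#' @param gsr A `gs_result` from [gs_matrix()].
#' @return Data frame (id_a, id_b, ns, nd, compared, gs), one row per
#'   unordered pair, in upper-triangle order.
#' @export
gs_pairs_table <- function(gsr) {
  ut <- which(upper.tri(gsr$gs), arr.ind = TRUE)
  ids <- rownames(gsr$gs)
  data.frame(id_a = ids[ut[, 1]], id_b = ids[ut[, 2]],
             ns = gsr$ns[ut], nd = gsr$nd[ut],
             compared = gsr$compared[ut], gs = gsr$gs[ut],
             stringsAsFactors = FALSE)
}

#' Calibrate the indisputable-derivation threshold from positive controls
#'
#' Applies the tail principle: the threshold is the minimum GS observed
#' among known same-variety positive-control pairs, rounded down to two
#' decimals.  Any pair at or above it is treated as indisputably derived.
#'
#' @param control_gs Numeric vector of positive-control GS values, or a
#'   data frame with a `gs` column (e.g. from [gs_pairs_table()]).
#' @return List with `threshold` (two-decimal floor), `min_gs` (raw
#'   minimum) and `n_controls`.
#' @export
calibrate_threshold <- function(control_gs) {
  if (is.data.frame(control_gs)) control_gs <- control_gs$gs
  control_gs <- control_gs[!is.na(control_gs)]
  if (!length(control_gs)) {
    stop("no positive-control GS values; supply a fixed threshold instead")
  }
  if (any(control_gs < 0 | control_gs > 1)) stop("GS values must lie in [0, 1]")
  m <- min(control_gs)
  # two-decimal floor; the epsilon guards against 0.97 representing as
  # 96.9999... x 10^-2
  list(threshold = floor(m * 100 + 1e-9) / 100, min_gs = m,
       n_controls = length(control_gs))
}

#' Classify sample pairs as putative or indisputable EDV pairs
#'
#' A pair with GS strictly above `putative` is a putative derivation; at or
#' above `indisputable` it is an indisputable one.  When both samples carry
#' distinct registration years, the earlier-registered sample is labelled
#' the initial variety (IV) and the later one the EDV; otherwise the roles
#' stay unresolved.
#'
#' @param pairs Pair table from [gs_pairs_table()] (columns `id_a`, `id_b`,
#'   `gs`).
#' @param meta Validated sample metadata (for registration years), or
#'   `NULL` to skip role assignment.
#' @param putative Lower GS threshold, exclusive (default 0.9).
#' @param indisputable Upper GS threshold, inclusive (e.g. from
#'   [calibrate_threshold()]; default 0.97).
#' @return The pair table with added columns `category` (`"none"`,
#'   `"putative"`, `"indisputable"`), `iv`, `edv` and `basis`
#'   (`"registration_year"` or `"unresolved"`).
#' @export
classify_pairs <- function(pairs, meta = NULL, putative = 0.9,
                           indisputable = 0.97) {
  if (!(putative > 0 && indisputable < 1 && putative < indisputable)) {
    stop("thresholds must satisfy 0 < putative < indisputable < 1")
  }
  gs <- pairs$gs
  category <- rep("none", nrow(pairs))
  category[!is.na(gs) & gs > putative] <- "putative"
  category[!is.na(gs) & gs >= indisputable] <- "indisputable"
  iv <- edv <- rep(NA_character_, nrow(pairs))
  basis <- rep("unresolved", nrow(pairs))
  if (!is.null(meta)) {
    yr <- meta$registration_year[match(pairs$id_a, meta$sample_id)]
    yr_b <- meta$registration_year[match(pairs$id_b, meta$sample_id)]
    derived <- category != "none"
    known <- derived & !is.na(yr) & !is.na(yr_b) & yr != yr_b
    iv[known] <- ifelse(yr[known] < yr_b[known], pairs$id_a[known], pairs$id_b[known])
    edv[known] <- ifelse(yr[known] < yr_b[known], pairs$id_b[known], pairs$id_a[known])
    basis[known] <- "registration_year"
  }
  pairs$category <- category
  pairs$iv <- iv
  pairs$edv <- edv
  pairs$basis <- basis
  pairs
}

#' Summary counts of an EDV classification
#'
#' @param calls Classified pair table from [classify_pairs()].
#' @return List with total pairs, putative-or-above count and percentage
#'   (2 dp), indisputable count, and the distinct samples labelled EDV.
#' @export
edv_summary <- function(calls) {
  above <- calls$category %in% c("putative", "indisputable")
  list(n_pairs = nrow(calls),
       n_above_putative = sum(above),
       pct_above_putative = round(100 * sum(above) / nrow(calls), 2),
       n_indisputable = sum(calls$category == "indisputable"),
       edv_samples = sort(unique(calls$edv[!is.na(calls$edv)])))
}
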