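# Greedy forward selection of a minimal SNP identification panel.
#
# A panel "distinguishes" a sample pair when it contains at least one locus
# where both samples are called and their genotype classes differ; a
# missing call can never distinguish (conservative).  Discernibility of a
# panel is the number of unordered pairs it distinguishes.  Selection adds,
# at each step, the locus distinguishing the most still-unresolved pairs,
# breaking ties by higher PIC and then lexicographic locus id, and stops
# when the panel's discernibility reaches that of the full candidate set.

# unordered pair index vectors (upper triangle, column-major order)
.pair_index <- function(n) {
  ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  list(a = ut[, 1], b = ut[, 2])
}

#' Is one sample pair distinguished by a panel?
#'
#' @param gm A [geno_matrix()].
#' @param panel Locus ids or indices forming the panel.
#' @param a,b Sample ids or indices, `a != b`.
#' @return `TRUE` iff some panel locus has both samples called with
#'   differing genotype classes.
#' @export
pair_distinguished <- function(gm, panel, a, b) {
  ids <- rownames(gm$calls)
  if (is.character(a)) a <- match(a, ids)
  if (is.character(b)) b <- match(b, ids)
  if (is.na(a) || is.na(b)) stop("unknown sample id")
  if (a == b) stop("a and b must differ")
  if (is.character(panel)) panel <- match(panel, gm$loci$id)
  ga <- gm$calls[a, panel]
  gb <- gm$calls[b, panel]
  any(!is.na(ga) & !is.na(gb) & ga != gb)
}

#' Discernibility of a panel
#'
#' Number of unordered sample pairs distinguished by the panel.  For a
#' single locus with genotype-class counts `n_j` over called samples this
#' equals `C(n_called, 2) - sum_j C(n_j, 2)`.
#'
#' @inheritParams pair_distinguished
#' @return Integer pair count.
#' @export
discernibility <- function(gm, panel) {
  if (!length(panel)) stop("panel must contain at least one locus")
  if (is.character(panel)) panel <- match(panel, gm$loci$id)
  n <- nrow(gm$calls)
  pi <- .pair_index(n)
  sum(.distinguished_mask(gm$calls, panel, pi$a, pi$b))
}

# logical vector over pairs (ia, ib): does any panel locus distinguish?
.distinguished_mask <- function(calls, panel, ia, ib) {
  res <- logical(length(ia))
  for (l in panel) {
    g <- calls[, l]
    d <- g[ia] != g[ib]
    d[is.na(d)] <- FALSE
    res <- res | d
    if (all(res)) break
  }
  res
}

#' Greedy minimal identification panel
#'
#' Forward selection: the first locus is the one with maximal single-locus
#' discernibility; each subsequent locus is the one that resolves the most
#' still-undistinguished pairs.  Ties are broken by higher PIC, then by
#' locus id, making the result deterministic.  Selection stops when the
#' panel distinguishes every pair the full candidate set can distinguish
#' (clone pairs, identical at every co-called candidate locus, remain
#' unresolved by construction and are reported).
#'
#' @param gm A [geno_matrix()] with at least two samples.
#' @param candidates Candidate locus ids/indices (default: all loci), e.g.
#'   the core SNP set.
#' @param stats Per-locus statistics supplying the PIC tie-break (computed
#'   on `gm` if omitted).
#' @param samples Optional sample ids/indices: restrict the discernibility
#'   objective to this subset (e.g. non-EDV samples only).
#' @param pic_convention PIC convention for the tie-break (default
#'   `"allele"`).
#' @return Object of class `snp_panel`: list with `selected` (ordered locus
#'   ids), `trace` (cumulative discernibility after each addition),
#'   `added` (per-step gains), `max_discernibility` (full candidate set),
#'   `n_pairs` (total unordered pairs), `unresolved` (data frame of pairs
#'   no candidate locus distinguishes) and `samples` (ids used).
#' @export
greedy_panel <- function(gm, candidates = NULL, stats = NULL, samples = NULL,
                         pic_convention = c("allele", "genotype")) {
  pic_convention <- match.arg(pic_convention)
  calls <- gm$calls
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(calls))
    calls <- calls[samples, , drop = FALSE]
  }
  if (nrow(calls) < 2L) stop("greedy_panel needs at least two samples")
  if (is.null(candidates)) candidates <- seq_len(ncol(calls))
  if (is.character(candidates)) candidates <- match(candidates, gm$loci$id)
  if (!length(candidates) || anyNA(candidates)) stop("invalid candidate loci")
  if (is.null(stats)) stats <- locus_stats(gm)
  pic_vals <- stats[[paste0("pic_", pic_convention)]][candidates]
  loc_ids <- gm$loci$id[candidates]
  n <- nrow(calls)
  pi <- .pair_index(n)
  full <- .distinguished_mask(calls, candidates, pi$a, pi$b)
  max_disc <- sum(full)
  unresolved_pairs <- data.frame(
    id_a = rownames(calls)[pi$a[!full]],
    id_b = rownames(calls)[pi$b[!full]], stringsAsFactors = FALSE)
  # greedy loop tracks only the pairs the full candidate set can resolve
  open_a <- pi$a[full]; open_b <- pi$b[full]
  remaining <- seq_along(candidates)
  selected <- integer()
  trace <- integer()
  added <- integer()
  resolved <- 0L
  while (resolved < max_disc && length(remaining)) {
    gains <- vapply(remaining, function(j) {
      g <- calls[, candidates[j]]
      d <- g[open_a] != g[open_b]
      sum(d, na.rm = TRUE)
    }, numeric(1))
    best_gain <- max(gains)
    if (best_gain == 0) break
    cand <- remaining[gains == best_gain]
    if (length(cand) > 1L) {
      top_pic <- pic_vals[cand]
      cand <- cand[top_pic == max(top_pic)]
      if (length(cand) > 1L) cand <- cand[order(loc_ids[cand])]
    }
    pick <- cand[1L]
    g <- calls[, candidates[pick]]
    d <- g[open_a] != g[open_b]
    d[is.na(d)] <- FALSE
    open_a <- open_a[!d]; open_b <- open_b[!d]
    resolved <- resolved + best_gain
    selected <- c(selected, pick)
    trace <- c(trace, resolved)
    added <- c(added, best_gain)
    remaining <- setdiff(remaining, pick)
  }
  structure(list(selected = loc_ids[selected],
                 trace = as.integer(trace), added = as.integer(added),
                 max_discernibility = as.integer(max_disc),
                 n_pairs = as.integer(n * (n - 1L) / 2L),
                 unresolved = unresolved_pairs,
                 samples = rownames(calls)),
            class = "snp_panel")
}

#' @export
print.snp_panel <- function(x, ...) {
  cat(sprintf("snp_panel: %d loci distinguishing %d of %d pairs (max attainable %d)\n",
              length(x$selected),
              if (length(x$trace)) x$trace[length(x$trace)] else 0L,
              x$n_pairs, x$max_discernibility))
  invisible(x)
}

#' Exhaustive minimal-panel search (small instances)
#'
#' Enumerates all non-empty locus subsets and returns the maximum attainable
#' discernibility and the smallest subset size achieving it.  Intended as an
#' independent check of [greedy_panel()] on instances small enough to
#' enumerate.
#'
#' @param gm A [geno_matrix()].
#' @param candidates Candidate locus indices (default all; at most 20).
#' @return List with `max_discernibility`, `min_panel_size` and
#'   `best_panel` (locus ids of one optimal minimal subset).
#' @export
exhaustive_panel <- function(gm, candidates = NULL) {
  if (is.null(candidates)) candidates <- seq_len(ncol(gm$calls))
  if (is.character(candidates)) candidates <- match(candidates, gm$loci$id)
  m <- length(candidates)
  if (m > 20L) stop("exhaustive search limited to 20 candidate loci")
  n <- nrow(gm$calls)
  pi <- .pair_index(n)
  per_locus <- lapply(candidates, function(l) {
    g <- gm$calls[, l]
    d <- g[pi$a] != g[pi$b]
    d[is.na(d)] <- FALSE
    d
  })
  best_disc <- -1L
  best_size <- m + 1L
  best_set <- integer()
  for (mask in seq_len(2^m - 1L)) {
    members <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(m) - 1L)) != 0L)
    d <- Reduce(`|`, per_locus[members])
    disc <- sum(d)
    if (disc > best_disc ||
        (disc == best_disc && length(members) < best_size)) {
      best_disc <- disc
      best_size <- length(members)
      best_set <- members
    }
  }
  list(max_discernibility = as.integer(best_disc),
       min_panel_size = as.integer(best_size),
       best_panel = gm$loci$id[candidates[best_set]])
}

#' Fingerprint strings over a panel
#'
#' One code string per sample over the panel loci: `0` homozygous
#' reference (class XX), `1` heterozygous (XY), `2` homozygous alternate
#' (YY), `N` missing.  Two samples distinguished by the panel always
#' receive distinct strings.
#'
#' @param gm A [geno_matrix()].
#' @param panel Locus ids/indices, or an `snp_panel` object.
#' @return Data frame (`sample_id`, `fingerprint`) with the class map
#'   attached as attribute `code_map`.
#' @export
fingerprint_table <- function(gm, panel) {
  if (inherits(panel, "snp_panel")) panel <- panel$selected
  if (is.character(panel)) panel <- match(panel, gm$loci$id)
  if (!length(panel) || anyNA(panel)) stop("invalid panel loci")
  sub <- gm$calls[, panel, drop = FALSE]
  chr <- matrix(as.character(sub), nrow = nrow(sub))
  chr[is.na(chr)] <- "N"
  fp <- apply(chr, 1, paste0, collapse = "")
  out <- data.frame(sample_id = rownames(gm$calls), fingerprint = fp,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "code_map") <- c(`0` = "XX (hom ref)", `1` = "XY (het)",
                             `2` = "YY (hom alt)", N = "missing")
  out
}
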