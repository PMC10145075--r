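# Core/backbone variety selection by least-distance stepwise sampling.
#
# Within each population, samples are ranked by the total number of
# differential genotype classes against all other members (missing calls
# contribute nothing); the smallest totals indicate the closest kinship to
# the rest of the population, and the top fraction of the ranking forms the
# core.  Heavily admixed samples are excluded up front, and a candidate
# that is the EDV of an already-selected sample (or the offspring of a
# selected parent) is skipped and replaced by the next rank.

#' Pairwise differential-genotype count matrix
#'
#' Counts, for every sample pair, the loci where both calls are present and
#' the genotype classes differ (the ND of [gs_pair()]).
#'
#' @param gm A [geno_matrix()].
#' @param samples Optional sample ids/indices restricting the matrix.
#' @param loci Optional locus ids/indices restricting the comparison.
#' @return Symmetric integer matrix of differential counts (diagonal 0).
#' @export
diff_matrix <- function(gm, samples = NULL, loci = NULL) {
  calls <- gm$calls
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(calls))
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, gm$loci$id)
    calls <- calls[, loci, drop = FALSE]
  }
  if (nrow(calls) < 2L) stop("diff_matrix needs at least two samples")
  pc <- .pair_counts(calls)
  nd <- pc$nd
  dimnames(nd) <- list(rownames(calls), rownames(calls))
  nd
}

.round_quota <- function(x, rounding) {
  switch(rounding,
         half_up = floor(x + 0.5),
         floor = floor(x),
         ceil = ceiling(x),
         stop("rounding must be one of half_up, floor, ceil"))
}

# How does candidate `cand` relate to the already-selected set?
#  "skip"     -- cand is the EDV (or unresolved-role partner) of a selected
#                sample, or the offspring of a selected parent
#  "displace" -- cand is the IV of one or more selected EDVs: those are
#                removed and replaced (returned in $drop)
#  "ok"       -- no conflict
.conflict_action <- function(cand, selected, edv_pairs, pedigree) {
  drop <- character()
  if (length(selected)) {
    if (!is.null(pedigree) && nrow(pedigree) &&
        any(pedigree$offspring == cand & pedigree$parent %in% selected)) {
      return(list(action = "skip", reason = "offspring", drop = drop))
    }
    if (!is.null(edv_pairs) && nrow(edv_pairs)) {
      hit <- (edv_pairs$id_a == cand & edv_pairs$id_b %in% selected) |
        (edv_pairs$id_b == cand & edv_pairs$id_a %in% selected)
      if (any(hit)) {
        h <- edv_pairs[hit, , drop = FALSE]
        if (any(is.na(h$edv) | h$edv == cand)) {
          return(list(action = "skip", reason = "edv", drop = drop))
        }
        # cand is the initial variety: its derived partner(s) give way
        drop <- intersect(h$edv, selected)
        return(list(action = "displace", reason = NA_character_, drop = drop))
      }
    }
  }
  list(action = "ok", reason = NA_character_, drop = drop)
}

#' Select core varieties per population
#'
#' Implements least-distance stepwise sampling.  Per population: (1) drop
#' samples whose own-population membership coefficient is below
#' `membership_min` (heavily admixed backgrounds); (2) rank the remainder
#' by ascending total differential-genotype count against the other members
#' (ties broken by sample id); (3) keep the top `fraction` of the
#' population's full size, with the quota rounded per `rounding`; (4) when
#' a candidate is the indisputable EDV of an already-selected sample, or
#' the offspring of a selected parent, it is skipped and the next rank
#' takes its place, cascading until the quota is filled or candidates run
#' out.  A candidate that turns out to be the initial variety of an
#' already-selected EDV instead displaces that EDV (derived varieties give
#' way to their initial variety regardless of rank order).
#'
#' @param gm A [geno_matrix()].
#' @param meta Validated sample metadata with a `population` column.
#' @param fraction Fraction of each population selected (default 0.20).
#' @param membership_min Minimum own-population membership coefficient;
#'   samples below it are excluded as admixed (default 0.8; `NA` membership
#'   is treated as non-admixed).
#' @param edv_calls Classified pair table from [classify_pairs()]; only
#'   pairs with category `"indisputable"` trigger replacement.  `NULL`
#'   disables the rule.
#' @param pedigree Optional data frame (`parent`, `offspring`) of known
#'   parent-offspring sample pairs.
#' @param rounding Quota rounding rule: `"half_up"` (default), `"floor"`
#'   or `"ceil"`.
#' @param loci Optional locus ids/indices used for the differential counts.
#' @return Object of class `core_selection`: list with `core` (named list
#'   of selected ids per population), `ranking` (data frame sample_id,
#'   population, diff_total, diff_mean, rank, selected, excluded_reason)
#'   and `summary` (population, size, core_count).
#' @export
select_core_varieties <- function(gm, meta, fraction = 0.20,
                                  membership_min = 0.8, edv_calls = NULL,
                                  pedigree = NULL,
                                  rounding = c("half_up", "floor", "ceil"),
                                  loci = NULL) {
  rounding <- match.arg(rounding)
  ids <- rownames(gm$calls)
  meta <- meta[match(ids, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) stop("metadata is missing samples present in the genotype matrix")
  if (all(is.na(meta$population))) stop("every sample needs a population label")
  edv_pairs <- NULL
  if (!is.null(edv_calls)) {
    edv_pairs <- edv_calls[edv_calls$category == "indisputable",
                           c("id_a", "id_b", "iv", "edv"), drop = FALSE]
  }
  pops <- sort(unique(meta$population[!is.na(meta$population)]))
  ranking <- list()
  core <- stats::setNames(vector("list", length(pops)), paste0("Pop", pops))
  for (k in seq_along(pops)) {
    p <- pops[k]
    members <- ids[!is.na(meta$population) & meta$population == p]
    admixed <- members[
      !is.na(meta$membership[match(members, ids)]) &
        meta$membership[match(members, ids)] < membership_min]
    eligible <- setdiff(members, admixed)
    quota <- .round_quota(fraction * length(members), rounding)
    rk <- data.frame(sample_id = members, population = p,
                     diff_total = NA_real_, diff_mean = NA_real_,
                     rank = NA_integer_, selected = FALSE,
                     excluded_reason = NA_character_,
                     stringsAsFactors = FALSE)
    rk$excluded_reason[rk$sample_id %in% admixed] <- "admixed"
    if (length(eligible) >= 2L) {
      nd <- diff_matrix(gm, samples = eligible, loci = loci)
      cmp <- diff_matrix_compared(gm, samples = eligible, loci = loci)
      tot <- rowSums(nd)
      mn <- rowSums(nd) / pmax(rowSums(cmp) - diag(cmp), 1)
      idx <- match(eligible, rk$sample_id)
      rk$diff_total[idx] <- tot
      rk$diff_mean[idx] <- mn
      ord <- eligible[order(tot, eligible)]
      rk$rank[match(ord, rk$sample_id)] <- seq_along(ord)
      selected <- character()
      for (cand in ord) {
        if (length(selected) >= quota) break
        act <- .conflict_action(cand, selected, edv_pairs, pedigree)
        if (act$action == "skip") {
          rk$excluded_reason[rk$sample_id == cand] <- act$reason
          next
        }
        if (act$action == "displace") {
          selected <- setdiff(selected, act$drop)
          rk$excluded_reason[rk$sample_id %in% act$drop] <- "edv"
        }
        selected <- c(selected, cand)
      }
      rk$selected[rk$sample_id %in% selected] <- TRUE
      core[[k]] <- selected
    } else {
      warning("population ", p, " has fewer than 2 eligible samples")
      core[[k]] <- utils::head(eligible, quota)
      rk$selected[rk$sample_id %in% core[[k]]] <- TRUE
    }
    ranking[[k]] <- rk
  }
  ranking <- do.call(rbind, ranking)
  summary <- data.frame(population = pops,
                        size = as.integer(table(factor(meta$population, levels = pops))),
                        core_count = lengths(core))
  structure(list(core = core, ranking = ranking, summary = summary),
            class = "core_selection")
}

# co-called counts companion to diff_matrix, used for the mean variant of
# the ranking key
diff_matrix_compared <- function(gm, samples = NULL, loci = NULL) {
  calls <- gm$calls
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, rownames(calls))
    calls <- calls[samples, , drop = FALSE]
  }
  if (!is.null(loci)) {
    if (is.character(loci)) loci <- match(loci, gm$loci$id)
    calls <- calls[, loci, drop = FALSE]
  }
  .pair_counts(calls)$compared
}

#' @export
print.core_selection <- function(x, ...) {
  cat("core_selection:\n")
  print(x$summary)
  invisible(x)
}
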