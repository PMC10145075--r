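# End-to-end orchestration: statistics -> core-SNP selection -> genetic
# similarity -> threshold calibration -> EDV classification -> core
# collection -> identification panel -> fingerprints.  The run is a pure
# function of (inputs, config): identical inputs give identical outputs.

#' Pipeline configuration
#'
#' @param filter A [filter_config()] for core-SNP selection.
#' @param putative_gs Putative-derivation GS threshold, exclusive
#'   (default 0.9).
#' @param indisputable_gs Fixed indisputable threshold used when the
#'   metadata declares no positive-control pairs; when controls are
#'   present the threshold is calibrated from them instead.
#' @param core_fraction Fraction of each population kept as core varieties
#'   (default 0.20).
#' @param membership_min Admixture exclusion threshold for the core
#'   collection (default 0.8).
#' @param rounding Core-quota rounding rule (default `"half_up"`).
#' @param skip_core_snp If `TRUE`, similarity and the panel are computed on
#'   all loci instead of the core SNP set.
#' @param panel_target `"all_pairs"` (panel distinguishes every sample) or
#'   `"non_edv"` (panel restricted to samples never labelled EDV).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(), putative_gs = 0.9,
                            indisputable_gs = 0.97, core_fraction = 0.20,
                            membership_min = 0.8,
                            rounding = c("half_up", "floor", "ceil"),
                            skip_core_snp = FALSE,
                            panel_target = c("all_pairs", "non_edv")) {
  structure(list(filter = filter, putative_gs = putative_gs,
                 indisputable_gs = indisputable_gs,
                 core_fraction = core_fraction,
                 membership_min = membership_min,
                 rounding = match.arg(rounding),
                 skip_core_snp = isTRUE(skip_core_snp),
                 panel_target = match.arg(panel_target)),
            class = "pipeline_config")
}

#' Run the full EDV analysis pipeline
#'
#' @param gm A [geno_matrix()], e.g. from [read_vcf()] or
#'   [simulate_cohort()].
#' @param meta Validated sample metadata covering every sample in `gm`.
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory: when given, all stage tables are
#'   written there as TSV/CSV plus a JSON run report.
#' @return Object of class `edv_report`: list with `stats`, `candidates`,
#'   `core_snps`, `gs` (a `gs_result`), `threshold` (calibration record or
#'   the fixed fallback), `edv_calls`, `edv_summary`, `core_varieties`,
#'   `panel`, `fingerprints` and `counts` (per-stage cardinalities).
#' @export
run_pipeline <- function(gm, meta, config = pipeline_config(),
                         out_dir = NULL) {
  missing_ids <- setdiff(rownames(gm$calls), meta$sample_id)
  if (length(missing_ids)) {
    stop("samples absent from metadata: ", paste(missing_ids, collapse = ", "))
  }
  meta <- meta[match(rownames(gm$calls), meta$sample_id), , drop = FALSE]

  stats <- locus_stats(gm)
  if (config$skip_core_snp) {
    candidates <- seq_len(ncol(gm$calls))
    core <- candidates
  } else {
    candidates <- filter_candidates(gm, stats, config$filter)
    core <- select_core(gm, stats, config$filter, candidates)
    if (!length(core)) {
      stop("no core SNPs survive filtering; relax the thresholds or use skip_core_snp")
    }
  }

  gsr <- gs_matrix(gm, loci = core)
  pairs <- gs_pairs_table(gsr)

  ctrl <- control_pairs(meta)
  if (nrow(ctrl)) {
    ctrl_gs <- vapply(seq_len(nrow(ctrl)), function(i) {
      gsr$gs[ctrl$id_a[i], ctrl$id_b[i]]
    }, numeric(1))
    thr <- calibrate_threshold(ctrl_gs)
    thr$source <- "controls"
  } else {
    thr <- list(threshold = config$indisputable_gs, min_gs = NA_real_,
                n_controls = 0L, source = "fixed")
  }

  edv_calls <- classify_pairs(pairs, meta, putative = config$putative_gs,
                              indisputable = thr$threshold)
  esum <- edv_summary(edv_calls)

  core_vars <- select_core_varieties(
    gm, meta, fraction = config$core_fraction,
    membership_min = config$membership_min, edv_calls = edv_calls,
    rounding = config$rounding, loci = core)

  panel_samples <- NULL
  if (config$panel_target == "non_edv") {
    panel_samples <- setdiff(rownames(gm$calls), esum$edv_samples)
  }
  panel <- greedy_panel(gm, candidates = core, stats = stats,
                        samples = panel_samples)
  fp <- fingerprint_table(gm, panel)
  if (!is.null(panel_samples)) fp <- fp[fp$sample_id %in% panel_samples, ]

  counts <- list(n_samples = nrow(gm$calls), n_loci = ncol(gm$calls),
                 n_candidates = length(candidates),
                 n_core_snps = length(core),
                 n_pairs = gsr$n_pairs,
                 n_above_putative = esum$n_above_putative,
                 n_indisputable = esum$n_indisputable,
                 core_varieties_per_pop = stats::setNames(
                   core_vars$summary$core_count,
                   paste0("Pop", core_vars$summary$population)),
                 panel_size = length(panel$selected))
  report <- structure(
    list(stats = stats, candidates = candidates, core_snps = core,
         gs = gsr, threshold = thr, edv_calls = edv_calls,
         edv_summary = esum, core_varieties = core_vars, panel = panel,
         fingerprints = fp, counts = counts, config = config),
    class = "edv_report")
  if (!is.null(out_dir)) write_report(report, gm, out_dir)
  report
}

#' @export
print.edv_report <- function(x, ...) {
  c <- x$counts
  cat("EDV pipeline report\n")
  cat(sprintf("  samples: %d, loci: %d\n", c$n_samples, c$n_loci))
  cat(sprintf("  candidate SNPs: %d, core SNPs: %d\n",
              c$n_candidates, c$n_core_snps))
  cat(sprintf("  pairs: %d; GS > %.2f: %d (%.2f%%); indisputable (GS >= %.2f): %d\n",
              c$n_pairs, x$config$putative_gs, c$n_above_putative,
              x$edv_summary$pct_above_putative, x$threshold$threshold,
              c$n_indisputable))
  cat("  core varieties per population: ",
      paste(names(c$core_varieties_per_pop), c$core_varieties_per_pop,
            sep = "=", collapse = ", "), "\n", sep = "")
  cat(sprintf("  identification panel: %d SNPs (%d/%d pairs distinguished)\n",
              c$panel_size,
              if (length(x$panel$trace)) x$panel$trace[length(x$panel$trace)] else 0L,
              x$panel$n_pairs))
  invisible(x)
}

#' Write pipeline outputs to disk
#'
#' Emits per-stage TSVs (locus statistics, core SNP table, pair
#' classifications, core-variety ranking, panel and fingerprints), a
#' filtered core-SNP VCF and a machine-readable JSON report of the counts.
#'
#' @param report An `edv_report` from [run_pipeline()].
#' @param gm The genotype matrix the report was computed from.
#' @param out_dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_report <- function(report, gm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) {
    p <- file.path(out_dir, f)
    utils::write.table(d, p, sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
    p
  }
  paths <- c(
    locus_stats = tsv(report$stats, "locus_stats.tsv"),
    core_snps = tsv(core_snp_table(gm, report$core_snps, report$stats),
                    "core_snps.tsv"),
    edv_calls = tsv(report$edv_calls, "edv_calls.tsv"),
    core_ranking = tsv(report$core_varieties$ranking, "core_varieties.tsv"),
    panel = tsv(data.frame(rank = seq_along(report$panel$selected),
                           locus = report$panel$selected,
                           added = report$panel$added,
                           cumulative = report$panel$trace),
                "panel.tsv"),
    fingerprints = tsv(report$fingerprints, "fingerprints.tsv"))
  core_vcf <- file.path(out_dir, "core_snps.vcf")
  write_vcf(subset_geno(gm, loci = report$core_snps), core_vcf)
  paths <- c(paths, core_vcf = core_vcf)
  json <- file.path(out_dir, "report.json")
  jsonlite::write_json(
    list(counts = report$counts,
         threshold = report$threshold,
         pct_above_putative = report$edv_summary$pct_above_putative),
    json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, report = json)
  invisible(paths)
}
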