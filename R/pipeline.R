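# End-to-end orchestration: per-dataset filtration cascade, cross-dataset
# consensus with strand rescue and redundancy removal, positional stringent
# filters, genomic-context classification and the expression atlas, with a
# machine-readable run report whose counts always conserve.

#' Run the full lncRNA discovery pipeline
#'
#' Stages, in order: the filtration cascade on each dataset independently;
#' pooling with the cross-dataset match graph; consensus support filtering
#' (at least `min_support` datasets); strand rescue from the stranded
#' dataset; redundancy removal; in the stringent regime additionally the
#' sense-overlap and single-exon proximity filters; genomic-context
#' classification; and, when counts are supplied, the tissue expression
#' atlas.
#'
#' @param inputs List with elements `collection` (a [dataset_collection()]),
#'   `genes` (list of gene models), `nr_hits`, `ncrna_hits`, `scores`, and
#'   optionally `lncdb_hits` and `counts` (a [count_matrix()]).
#' @param mode `"traditional"` or `"stringent"`.
#' @param min_support Minimum number of supporting datasets.
#' @param dedup_overlap Redundancy threshold in nt (overlap strictly above
#'   it removes the shorter transcript).
#' @param strand_identity Percent identity (strict) for strand rescue.
#' @param window Intergenic classification window in nt.
#' @param fold,min_specific_rpkm,min_ubiquitous_rpkm Atlas thresholds.
#' @param min_corr,retain_fraction Co-expression clustering parameters.
#' @param cluster Whether to run correlation clustering (the slowest atlas
#'   step) when counts are present.
#' @param out_dir Optional directory; when given, merged GTF/BED, class and
#'   atlas TSVs and a JSON run report are written there.
#' @return List with `lncrnas` (final transcript models), `classes`
#'   (classification data frame), `class_summary`, `cascade_reports` (one
#'   stage report per dataset), `merge_report` (consensus-phase stage
#'   report), `support`, `conserved` (dataset-qualified ids flagged against
#'   known lncRNAs), `atlas` (or NULL) and `mode`.
#' @export
run_all <- function(inputs, mode = c("traditional", "stringent"),
                    min_support = 2L, dedup_overlap = 100L,
                    strand_identity = 95, window = 15000L,
                    fold = 8, min_specific_rpkm = 0.5,
                    min_ubiquitous_rpkm = 1.0,
                    min_corr = 0.97, retain_fraction = 0.20,
                    cluster = TRUE, out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(inputs$collection, "dataset_collection"))
  config <- filter_config(mode)
  collection <- inputs$collection

  # --- per-dataset cascade ---------------------------------------------
  cascade_reports <- list()
  survivors <- list()
  conserved <- character(0)
  for (d in names(collection$datasets)) {
    txs <- collection$datasets[[d]]
    ids <- vapply(txs, function(t) t$id, character(1))
    res <- run_cascade(
      txs,
      nr_hits = inputs$nr_hits[inputs$nr_hits$query_id %in% ids, , drop = FALSE],
      ncrna_hits = inputs$ncrna_hits[inputs$ncrna_hits$query_id %in% ids, ,
                                     drop = FALSE],
      score_table = inputs$scores,
      config = config,
      lncrna_hits = if (!is.null(inputs$lncdb_hits))
        inputs$lncdb_hits[inputs$lncdb_hits$query_id %in% ids, , drop = FALSE]
      else NULL)
    validate_stage_report(res$report)
    cascade_reports[[d]] <- res$report
    survivors[[d]] <- res$lncrnas
    conserved <- c(conserved, res$conserved)
  }

  # --- consensus phase --------------------------------------------------
  surv_coll <- structure(list(datasets = survivors,
                              stranded = collection$stranded),
                         class = "dataset_collection")
  pooled <- pool_transcripts(surv_coll)
  edges <- build_match_graph(surv_coll)
  cons <- consensus_filter(surv_coll, edges, min_support = min_support)
  merge_report <- list(.stage_report_row("consensus_support", length(pooled),
                                         length(pooled) - length(cons$kept)))
  stranded_set <- Filter(function(t) t$source %in% collection$stranded,
                         cons$kept)
  rescued <- assign_strand(cons$kept, stranded_set,
                           min_identity = strand_identity)
  dd <- deduplicate(rescued$transcripts, max_overlap_nt = dedup_overlap)
  merge_report[[2L]] <- .stage_report_row("deduplicate", length(cons$kept),
                                          length(dd$removed))
  final <- dd$kept

  gidx <- gene_index(inputs$genes)
  if (mode == "stringent") {
    so <- filter_sense_overlap(final, gidx)
    merge_report[[3L]] <- .stage_report_row("sense_overlap", length(final),
                                            length(so$removed))
    sx <- filter_single_exon_proximity(so$kept, gidx)
    merge_report[[4L]] <- .stage_report_row("single_exon_proximity",
                                            length(so$kept),
                                            length(sx$removed))
    final <- sx$kept
  }
  merge_report <- do.call(rbind, merge_report)
  validate_stage_report(merge_report)

  # --- classification ---------------------------------------------------
  classes <- classify_all(final, gidx, window = window)
  class_summary <- summarize_classes(classes)

  # --- expression atlas -------------------------------------------------
  atlas <- NULL
  if (!is.null(inputs$counts)) {
    expr <- rpkm(inputs$counts)
    atlas <- list(
      rpkm = expr,
      tissue_specific = call_tissue_specific(expr, fold = fold,
                                             min_rpkm = min_specific_rpkm),
      ubiquitous = call_ubiquitous(expr, min_rpkm = min_ubiquitous_rpkm),
      complexity = lapply(setNames(nm = colnames(expr)), function(t)
        complexity_curve(expr, t)))
    if (isTRUE(cluster)) {
      norm <- normalize_mean_scaling(expr)
      atlas$clusters <- cluster_correlated(norm, min_corr = min_corr,
                                           retain_fraction = retain_fraction)
    }
  }

  result <- list(lncrnas = final, classes = classes,
                 class_summary = class_summary,
                 cascade_reports = cascade_reports,
                 merge_report = merge_report,
                 support = cons$support,
                 conserved = sort(unique(conserved)),
                 atlas = atlas, mode = mode)
  if (!is.null(out_dir)) .write_run_outputs(result, out_dir)
  result
}

.write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(out_dir, ...)
  write_gtf(result$lncrnas, p("merged.gtf"))
  write_bed6(result$lncrnas, p("merged.bed"))
  write.table(result$classes, p("classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (d in names(result$cascade_reports))
    write_stage_report(result$cascade_reports[[d]],
                       p(paste0("cascade_", d, ".tsv")))
  write_stage_report(result$merge_report, p("merge_report.tsv"))
  if (!is.null(result$atlas)) {
    dir.create(p("atlas"), showWarnings = FALSE)
    write.table(data.frame(id = rownames(result$atlas$rpkm),
                           result$atlas$rpkm, check.names = FALSE),
                p("atlas", "rpkm.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    ts <- result$atlas$tissue_specific
    write.table(data.frame(id = names(ts)[!is.na(ts)],
                           tissue = ts[!is.na(ts)]),
                p("atlas", "tissue_specific.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ub <- result$atlas$ubiquitous
    write.table(data.frame(id = names(ub)[ub]),
                p("atlas", "ubiquitous.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  report <- list(
    mode = result$mode,
    n_lncrnas = length(result$lncrnas),
    cascade = lapply(result$cascade_reports, function(r)
      as.list(setNames(r$n_removed, r$stage))),
    merge = as.list(setNames(result$merge_report$n_removed,
                             result$merge_report$stage)),
    classes = as.list(setNames(result$class_summary$n,
                               result$class_summary$category)))
  jsonlite::write_json(report, p("report.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
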