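# The filtration cascade that reduces assembled transcripts to putative
# lncRNAs: minimum length, longest-ORF size, protein-database homology,
# coding-potential score, small non-coding RNA homology. Two shipped
# stringency regimes ("traditional" and "stringent"); the stringent regime
# never keeps a transcript the traditional one drops.

#' Filter configuration for the lncRNA cascade
#'
#' @param mode `"traditional"` or `"stringent"` preset, or `"custom"` to use
#'   the remaining arguments as given.
#' @param min_length_nt Transcripts strictly shorter than this are removed.
#' @param max_orf_aa Transcripts whose longest ORF exceeds this many amino
#'   acids (strictly) are removed. 100 in the traditional regime; 83 in the
#'   stringent regime (the mean ORF length of the shortest decile of
#'   protein-coding genes in the reference study).
#' @param max_orf_fraction Maximum tolerated ORF share of transcript length
#'   (strict); `NA` disables the check (traditional regime). 0.35 in the
#'   stringent regime.
#' @param homology_evalue Transcripts with any protein- or small-RNA-database
#'   hit at E-value `<=` this (inclusive) are removed.
#' @param coding_score_cutoff Transcripts are kept only when their
#'   coding-potential score is strictly below this cutoff (negative scores
#'   lean non-coding). -0.5 traditional, -1.0 stringent.
#' @param orf_frames Default number of frames for the ORF scan when the
#'   transcript strand is known; unknown-strand transcripts are always
#'   scanned in 6 frames.
#' @return A `filter_config` list.
#' @export
filter_config <- function(mode = c("traditional", "stringent", "custom"),
                          min_length_nt = 200L, max_orf_aa = 100L,
                          max_orf_fraction = NA_real_,
                          homology_evalue = 1e-4,
                          coding_score_cutoff = -0.5, orf_frames = 3L) {
  mode <- match.arg(mode)
  if (mode == "traditional") {
    max_orf_aa <- 100L; max_orf_fraction <- NA_real_
    coding_score_cutoff <- -0.5
  } else if (mode == "stringent") {
    max_orf_aa <- 83L; max_orf_fraction <- 0.35
    coding_score_cutoff <- -1.0
  }
  stopifnot(is.finite(min_length_nt), is.finite(max_orf_aa),
            is.finite(homology_evalue), is.finite(coding_score_cutoff),
            orf_frames %in% c(3L, 6L))
  structure(list(mode = mode, min_length_nt = as.integer(min_length_nt),
                 max_orf_aa = as.integer(max_orf_aa),
                 max_orf_fraction = max_orf_fraction,
                 homology_evalue = homology_evalue,
                 coding_score_cutoff = coding_score_cutoff,
                 orf_frames = as.integer(orf_frames)),
            class = "filter_config")
}

.tx_ids <- function(transcripts)
  vapply(transcripts, function(t) t$id, character(1))

.split_kept <- function(transcripts, keep) {
  list(kept = transcripts[keep], removed = transcripts[!keep])
}

#' Remove transcripts shorter than a minimum length
#'
#' Removal is strict: a transcript of exactly `min_length_nt` is kept.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param min_length_nt Minimum spliced length in nucleotides.
#' @return List with `kept` and `removed` transcript lists.
#' @export
filter_min_length <- function(transcripts, min_length_nt = 200L) {
  lens <- vapply(transcripts, tx_length, integer(1))
  .split_kept(transcripts, lens >= min_length_nt)
}

#' Remove transcripts with a long open reading frame
#'
#' A transcript is removed when its longest complete ORF exceeds
#' `max_orf_aa` amino acids, or (when `max_orf_fraction` is set) when the
#' ORF covers more than that fraction of the transcript length. Both
#' comparisons are strict. Strand-known transcripts are scanned in
#' `config$orf_frames` frames; unknown-strand transcripts in 6.
#'
#' @param transcripts List of `transcript_model` objects with sequences.
#' @param config A [filter_config()].
#' @return List with `kept`, `removed`, and `orf` (data frame of per-
#'   transcript ORF statistics).
#' @export
filter_orf <- function(transcripts, config = filter_config()) {
  orfs <- lapply(transcripts, function(t) {
    if (is.null(t$sequence))
      stop("transcript '", t$id, "': sequence required for ORF filtering")
    frames <- if (t$strand == "*") 6L else config$orf_frames
    find_longest_orf(t$sequence, frames)
  })
  aa <- vapply(orfs, function(o) o$aa_length, integer(1))
  frac <- vapply(orfs, function(o) o$fraction, numeric(1))
  drop <- aa > config$max_orf_aa
  if (!is.na(config$max_orf_fraction))
    drop <- drop | frac > config$max_orf_fraction
  out <- .split_kept(transcripts, !drop)
  out$orf <- data.frame(id = .tx_ids(transcripts), aa_length = aa,
                        fraction = frac)
  out
}

#' Remove transcripts with significant homology hits
#'
#' A transcript is removed when any hit naming it has an E-value at or below
#' the cutoff (inclusive, "E <= 0.0001"). Hits whose query id matches no
#' transcript are ignored with a warning.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param hits Hit table as returned by [read_hit_table()].
#' @param evalue_cutoff Inclusive E-value threshold.
#' @return List with `kept` and `removed`.
#' @export
filter_by_homology <- function(transcripts, hits, evalue_cutoff = 1e-4) {
  ids <- .tx_ids(transcripts)
  sig <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  unknown <- setdiff(unique(hits$query_id), ids)
  if (length(unknown) > 0L)
    warning(length(unknown), " hit query id(s) match no transcript; ignored")
  .split_kept(transcripts, !(ids %in% sig$query_id))
}

#' Remove transcripts that fail the coding-potential score test
#'
#' Retained transcripts must score strictly below the cutoff (more negative
#' means more confidently non-coding). Transcripts with no score entry are
#' kept and reported via a message.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param score_table Named numeric vector (id -> score).
#' @param cutoff Score cutoff (-0.5 traditional, -1.0 stringent).
#' @return List with `kept` and `removed`.
#' @export
filter_by_coding_score <- function(transcripts, score_table, cutoff = -0.5) {
  ids <- .tx_ids(transcripts)
  scores <- score_table[ids]
  missing <- is.na(scores)
  if (any(missing))
    message(sum(missing), " transcript(s) without a coding score; kept")
  .split_kept(transcripts, missing | scores < cutoff)
}

#' Flag transcripts conserved in known-lncRNA databases
#'
#' Unlike the homology filter this stage removes nothing: it annotates each
#' transcript with the known-lncRNA subjects it matches at or below the
#' E-value cutoff, to report evolutionary conservation.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param lncrna_hits Hit table against known-lncRNA databases.
#' @param evalue_cutoff Inclusive E-value threshold.
#' @return Named list mapping every transcript id to a (possibly empty)
#'   character vector of matched subject ids.
#' @export
annotate_known_lncrnas <- function(transcripts, lncrna_hits,
                                   evalue_cutoff = 1e-4) {
  ids <- .tx_ids(transcripts)
  sig <- lncrna_hits[lncrna_hits$evalue <= evalue_cutoff, , drop = FALSE]
  ann <- setNames(vector("list", length(ids)), ids)
  for (id in ids) ann[[id]] <- unique(sig$subject_id[sig$query_id == id])
  ann
}

.cascade_stages <- c("min_length", "orf", "nr_homology", "coding_score",
                     "small_ncrna_homology")

.stage_report_row <- function(stage, n_in, n_removed) {
  data.frame(stage = stage, n_in = n_in, n_removed = n_removed,
             n_out = n_in - n_removed)
}

#' Run the full lncRNA filtration cascade on one dataset
#'
#' Applies, in order: minimum length, longest-ORF, protein-database homology,
#' coding-potential score, and small non-coding RNA homology filters, and
#' reports per-stage counts. The output set is a pure function of the input
#' set (input order does not matter).
#'
#' @param transcripts List of `transcript_model` objects with sequences.
#' @param nr_hits Hit table against a protein database.
#' @param ncrna_hits Hit table against small non-coding RNA databases
#'   (tRNA/miRNA/LSU/SSU, merged; subjects may carry a database tag).
#' @param score_table Named numeric vector of coding-potential scores.
#' @param config A [filter_config()].
#' @param lncrna_hits Optional hit table against known-lncRNA databases,
#'   used only to annotate conservation (never to remove).
#' @return List with `lncrnas` (surviving transcripts), `report` (a stage
#'   report data frame with columns stage/n_in/n_removed/n_out), and
#'   `conserved` (ids flagged by [annotate_known_lncrnas()], or NULL).
#' @export
run_cascade <- function(transcripts, nr_hits, ncrna_hits, score_table,
                        config = filter_config(), lncrna_hits = NULL) {
  transcripts <- .sort_transcripts(transcripts)
  report <- list()
  s1 <- filter_min_length(transcripts, config$min_length_nt)
  report[[1L]] <- .stage_report_row("min_length", length(transcripts),
                                    length(s1$removed))
  s2 <- filter_orf(s1$kept, config)
  report[[2L]] <- .stage_report_row("orf", length(s1$kept), length(s2$removed))
  # hits naming transcripts already removed upstream are irrelevant here
  live_hits <- function(hits, txs)
    hits[hits$query_id %in% .tx_ids(txs), , drop = FALSE]
  s3 <- filter_by_homology(s2$kept, live_hits(nr_hits, s2$kept),
                           config$homology_evalue)
  report[[3L]] <- .stage_report_row("nr_homology", length(s2$kept),
                                    length(s3$removed))
  s4 <- filter_by_coding_score(s3$kept, score_table, config$coding_score_cutoff)
  report[[4L]] <- .stage_report_row("coding_score", length(s3$kept),
                                    length(s4$removed))
  s5 <- filter_by_homology(s4$kept, live_hits(ncrna_hits, s4$kept),
                           config$homology_evalue)
  report[[5L]] <- .stage_report_row("small_ncrna_homology", length(s4$kept),
                                    length(s5$removed))
  conserved <- NULL
  if (!is.null(lncrna_hits)) {
    ann <- annotate_known_lncrnas(s5$kept, lncrna_hits, config$homology_evalue)
    conserved <- names(ann)[lengths(ann) > 0L]
  }
  list(lncrnas = s5$kept, report = do.call(rbind, report),
       conserved = conserved)
}

#' Check a stage report for count conservation
#'
#' Every stage must satisfy `n_in = n_removed + n_out`, and consecutive
#' stages must chain (`n_out` of one equals `n_in` of the next).
#'
#' @param report Stage report data frame.
#' @return TRUE invisibly, or an error describing the violated row.
#' @export
validate_stage_report <- function(report) {
  bad <- which(report$n_in - report$n_removed != report$n_out)
  if (length(bad) > 0L)
    stop("stage report: n_in != n_removed + n_out at stage '",
         report$stage[bad[1L]], "'")
  if (nrow(report) > 1L) {
    chain <- report$n_out[-nrow(report)] != report$n_in[-1L]
    if (any(chain))
      stop("stage report: stages '", report$stage[which(chain)[1L]],
           "' and '", report$stage[which(chain)[1L] + 1L], "' do not chain")
  }
  invisible(TRUE)
}

#' Write a stage report as TSV
#' @param report Stage report data frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_stage_report <- function(report, path) {
  write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
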