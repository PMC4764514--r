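# Classification of lncRNAs by their position relative to protein-coding
# genes: genic (intronic, exonic sense/antisense/unknown, or containing a
# coding gene inside an intron) versus intergenic (convergent, divergent,
# unoriented within a distance window, or distal beyond it).

.lnc_categories <- c("intronic", "exonic_sense", "exonic_antisense",
                     "exonic_unknown", "containing",
                     "intergenic_convergent", "intergenic_divergent",
                     "intergenic_unoriented", "intergenic_distal")

#' Build an interval index over protein-coding genes
#'
#' @param genes List of `gene_model` objects (see [as_gene_models()]).
#' @return A `gene_index` with precomputed span and exon interval indexes.
#' @export
gene_index <- function(genes) {
  genes <- genes[order(vapply(genes, function(g) g$id, character(1)))]
  if (length(genes) > 0L) {
    span_gr <- GenomicRanges::GRanges(
      vapply(genes, function(g) g$chrom, character(1)),
      IRanges::IRanges(vapply(genes, function(g) g$span[["start"]], integer(1)) + 1L,
                       vapply(genes, function(g) g$span[["end"]], integer(1))))
    span_gr$gene <- seq_along(genes)
    n_ex <- vapply(genes, function(g) nrow(g$exons), integer(1))
    exon_gr <- GenomicRanges::GRanges(
      rep(vapply(genes, function(g) g$chrom, character(1)), n_ex),
      IRanges::IRanges(unlist(lapply(genes, function(g) g$exons$start)) + 1L,
                       unlist(lapply(genes, function(g) g$exons$end))))
    exon_gr$gene <- rep(seq_along(genes), n_ex)
  } else {
    span_gr <- GenomicRanges::GRanges(); exon_gr <- GenomicRanges::GRanges()
  }
  structure(list(genes = genes, span_gr = span_gr, exon_gr = exon_gr),
            class = "gene_index")
}

.lnc_gr1 <- function(lnc) {
  sp <- tx_span(lnc)
  GenomicRanges::GRanges(sp$chrom, IRanges::IRanges(sp$start + 1L, sp$end))
}

#' Distance from a transcript to its nearest protein-coding gene
#'
#' The gap between half-open intervals (`start2 - end1`); abutting
#' intervals have distance 0, overlapping genes distance 0. When the
#' chromosome carries no gene the distance is `Inf`.
#'
#' @param lnc A `transcript_model`.
#' @param index A [gene_index()].
#' @return List with `gene_id` (NA when none) and `distance_nt`.
#' @export
nearest_gene_distance <- function(lnc, index) {
  if (length(index$genes) == 0L)
    return(list(gene_id = NA_character_, distance_nt = Inf))
  sp <- tx_span(lnc)
  on_chrom <- which(vapply(index$genes, function(g) g$chrom, character(1)) ==
                      sp$chrom)
  if (length(on_chrom) == 0L)
    return(list(gene_id = NA_character_, distance_nt = Inf))
  d <- vapply(on_chrom, function(i) {
    g <- index$genes[[i]]
    gs <- g$span[["start"]]; ge <- g$span[["end"]]
    if (sp$start < ge && gs < sp$end) 0
    else if (sp$end <= gs) gs - sp$end
    else sp$start - ge
  }, numeric(1))
  best <- which.min(d)
  list(gene_id = index$genes[[on_chrom[best]]]$id, distance_nt = d[best])
}

.strand_relation <- function(a, b) {
  if (a == "*" || b == "*") "unknown" else if (a == b) "same" else "opposite"
}

#' Classify one lncRNA relative to protein-coding genes
#'
#' Decision order (first match wins):
#' 1. *containing* — a coding gene lies entirely within an intron of the
#'    lncRNA;
#' 2. *exonic* — any lncRNA exon intersects any coding exon; sense,
#'    antisense or unknown by strand comparison;
#' 3. *intronic* — the lncRNA overlaps a gene's span without touching its
#'    exons;
#' 4. *intergenic convergent/divergent/unoriented* — nearest gene within
#'    `window` nt (inclusive); convergent = same strand as the nearest gene,
#'    divergent = opposite strand, unoriented when either strand is unknown;
#' 5. *intergenic distal* — no gene within the window.
#'
#' @param lnc A `transcript_model`.
#' @param index A [gene_index()].
#' @param window Intergenic distance window in nt (inclusive).
#' @return List with `id`, `category`, `nearest_gene_id`, `distance_nt`
#'   (0 for genic categories) and `relative_orientation`.
#' @export
classify_lncrna <- function(lnc, index, window = 15000L) {
  sp <- tx_span(lnc)
  res <- function(category, gene_id, distance, orientation) {
    list(id = lnc$id, category = category, nearest_gene_id = gene_id,
         distance_nt = distance, relative_orientation = orientation)
  }
  # 1. containing: a gene entirely inside one of the lncRNA's introns
  introns <- tx_introns(lnc)
  if (nrow(introns) > 0L && length(index$genes) > 0L) {
    for (g in index$genes) {
      if (g$chrom != sp$chrom) next
      inside <- introns$start <= g$span[["start"]] &
        g$span[["end"]] <= introns$end
      if (any(inside))
        return(res("containing", g$id, 0,
                   .strand_relation(lnc$strand, g$strand)))
    }
  }
  # 2. exonic: exon-level intersection
  if (length(index$exon_gr) > 0L) {
    lgr <- exons_granges(list(lnc))
    GenomicRanges::strand(lgr) <- "*"
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(lgr, index$exon_gr, ignore.strand = TRUE))
    if (length(hit) > 0L) {
      gidx <- sort(unique(index$exon_gr$gene[S4Vectors::subjectHits(hit)]))[1L]
      g <- index$genes[[gidx]]
      rel <- .strand_relation(lnc$strand, g$strand)
      cat <- switch(rel, same = "exonic_sense", opposite = "exonic_antisense",
                    unknown = "exonic_unknown")
      return(res(cat, g$id, 0, rel))
    }
  }
  # 3. intronic: span overlap with a gene but no exon contact
  if (length(index$span_gr) > 0L) {
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(.lnc_gr1(lnc), index$span_gr,
                                  ignore.strand = TRUE))
    if (length(hit) > 0L) {
      gidx <- sort(unique(index$span_gr$gene[S4Vectors::subjectHits(hit)]))[1L]
      g <- index$genes[[gidx]]
      return(res("intronic", g$id, 0, .strand_relation(lnc$strand, g$strand)))
    }
  }
  # 4./5. intergenic
  nd <- nearest_gene_distance(lnc, index)
  if (is.finite(nd$distance_nt) && nd$distance_nt <= window) {
    gidx <- which(vapply(index$genes, function(g) g$id, character(1)) ==
                    nd$gene_id)[1L]
    rel <- .strand_relation(lnc$strand, index$genes[[gidx]]$strand)
    cat <- switch(rel, same = "intergenic_convergent",
                  opposite = "intergenic_divergent",
                  unknown = "intergenic_unoriented")
    return(res(cat, nd$gene_id, nd$distance_nt, rel))
  }
  res("intergenic_distal", nd$gene_id, nd$distance_nt, "unknown")
}

#' Classify a set of lncRNAs
#' @param lncrnas List of `transcript_model` objects.
#' @param index A [gene_index()].
#' @param window Intergenic distance window in nt (inclusive).
#' @return Data frame with one row per lncRNA: id, category, nearest_gene,
#'   distance, orientation.
#' @export
classify_all <- function(lncrnas, index, window = 15000L) {
  if (length(lncrnas) == 0L)
    return(data.frame(id = character(0), category = character(0),
                      nearest_gene = character(0), distance = numeric(0),
                      orientation = character(0)))
  rows <- lapply(lncrnas, function(l) {
    r <- classify_lncrna(l, index, window)
    data.frame(id = r$id, category = r$category,
               nearest_gene = r$nearest_gene_id %||% NA_character_,
               distance = r$distance_nt, orientation = r$relative_orientation)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Remove lncRNAs overlapping a coding gene in the sense orientation
#'
#' Removal requires exon-level overlap with a coding gene where both strands
#' are known and equal; unknown-strand overlaps are kept (sense cannot be
#' established) and counted in the returned `unresolved` ids.
#'
#' @param lncrnas List of `transcript_model` objects.
#' @param index A [gene_index()].
#' @return List with `kept`, `removed`, `unresolved`.
#' @export
filter_sense_overlap <- function(lncrnas, index) {
  unresolved <- character(0)
  drop <- vapply(lncrnas, function(l) {
    if (length(index$exon_gr) == 0L) return(FALSE)
    lgr <- exons_granges(list(l))
    GenomicRanges::strand(lgr) <- "*"
    hit <- suppressWarnings(
      GenomicRanges::findOverlaps(lgr, index$exon_gr, ignore.strand = TRUE))
    if (length(hit) == 0L) return(FALSE)
    gstr <- vapply(unique(index$exon_gr$gene[S4Vectors::subjectHits(hit)]),
                   function(i) index$genes[[i]]$strand, character(1))
    if (l$strand == "*" || all(gstr == "*")) {
      unresolved <<- c(unresolved, l$id)
      return(FALSE)
    }
    any(gstr == l$strand)
  }, logical(1))
  if (length(unresolved) > 0L)
    message(length(unresolved),
            " exonic overlap(s) with unknown strand; kept")
  c(.split_kept(lncrnas, !drop), list(unresolved = unresolved))
}

#' Remove single-exon lncRNAs close to a coding gene
#'
#' A single-exon lncRNA is removed when its distance to the nearest coding
#' gene is positive and at most `max_gap` nt (inclusive). Overlapping cases
#' (distance 0) are left to the sense-overlap and classification rules;
#' multi-exon lncRNAs are never touched.
#'
#' @param lncrnas List of `transcript_model` objects.
#' @param index A [gene_index()].
#' @param max_gap Maximum gap in nt (inclusive).
#' @return List with `kept` and `removed`.
#' @export
filter_single_exon_proximity <- function(lncrnas, index, max_gap = 500L) {
  drop <- vapply(lncrnas, function(l) {
    if (nrow(l$exons) != 1L) return(FALSE)
    d <- nearest_gene_distance(l, index)$distance_nt
    is.finite(d) && d > 0 && d <= max_gap
  }, logical(1))
  .split_kept(lncrnas, !drop)
}

#' Count lncRNAs per genomic-context category
#'
#' @param results Data frame from [classify_all()].
#' @return Data frame with one row per category (all categories listed, zero
#'   counts included) plus `genic` and `intergenic` totals as attributes.
#' @export
summarize_classes <- function(results) {
  counts <- table(factor(results$category, levels = .lnc_categories))
  out <- data.frame(category = names(counts), n = as.integer(counts))
  genic <- sum(out$n[out$category %in%
                       c("intronic", "exonic_sense", "exonic_antisense",
                         "exonic_unknown", "containing")])
  attr(out, "genic") <- genic
  attr(out, "intergenic") <- sum(out$n) - genic
  out
}
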