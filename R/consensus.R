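# Cross-dataset consensus: transcripts detected independently in several
# datasets support each other. Matching is anchored on genomic coordinates
# (all datasets are assembled against the same genome); sequence identity is
# a secondary confirmation when sequences are present.

#' Bundle per-dataset transcript sets into a collection
#'
#' @param datasets Named list; each element a list of `transcript_model`
#'   objects from one dataset. Names must be unique.
#' @param stranded Character vector naming the datasets whose transcripts
#'   carry reliable strand information (typically the Ribo-Zero library).
#' @return A `dataset_collection` object. Each transcript is tagged with its
#'   dataset via [tag_dataset()] so pooled ids stay unique.
#' @export
dataset_collection <- function(datasets, stranded = character(0)) {
  stopifnot(is.list(datasets), !is.null(names(datasets)),
            !anyDuplicated(names(datasets)),
            all(stranded %in% names(datasets)))
  datasets <- lapply(names(datasets), function(nm) {
    lapply(datasets[[nm]], tag_dataset, dataset = nm)
  })
  names(datasets) <- vapply(datasets, function(d) {
    if (length(d) > 0L) d[[1L]]$source else NA_character_
  }, character(1))
  # restore names for empty datasets
  structure(list(datasets = datasets, stranded = stranded),
            class = "dataset_collection")
}

#' Pool all transcripts of a collection into one list
#' @param collection A `dataset_collection`.
#' @return Flat list of `transcript_model` objects.
#' @export
pool_transcripts <- function(collection) {
  unname(do.call(c, unname(collection$datasets)))
}

# transcript sequence in plus-genomic orientation
.plus_oriented_seq <- function(tx) {
  if (is.null(tx$sequence)) return(NULL)
  if (tx$strand == "-") revcomp(tx$sequence) else tx$sequence
}

# shared exonic genomic nt between two transcripts on the same chrom
.tx_overlap_nt <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  tot <- 0L
  for (i in seq_len(nrow(a$exons))) {
    s <- pmax(a$exons$start[i], b$exons$start)
    e <- pmin(a$exons$end[i], b$exons$end)
    tot <- tot + sum(pmax(0L, e - s))
  }
  tot
}

# percent identity over the shared exonic genomic positions; NA when either
# transcript lacks a sequence or there is no overlap
.tx_identity_pct <- function(a, b) {
  sa <- .plus_oriented_seq(a); sb <- .plus_oriented_seq(b)
  if (is.null(sa) || is.null(sb)) return(NA_real_)
  if (a$chrom != b$chrom) return(NA_real_)
  offs_a <- c(0L, cumsum(a$exons$end - a$exons$start))
  offs_b <- c(0L, cumsum(b$exons$end - b$exons$start))
  matches <- 0L; total <- 0L
  for (i in seq_len(nrow(a$exons))) for (j in seq_len(nrow(b$exons))) {
    s <- max(a$exons$start[i], b$exons$start[j])
    e <- min(a$exons$end[i], b$exons$end[j])
    if (e <= s) next
    fa <- offs_a[i] + (s - a$exons$start[i]) + 1L
    fb <- offs_b[j] + (s - b$exons$start[j]) + 1L
    frag_a <- substring(sa, fa, fa + (e - s) - 1L)
    frag_b <- substring(sb, fb, fb + (e - s) - 1L)
    cmp <- strsplit(frag_a, "")[[1L]] == strsplit(frag_b, "")[[1L]]
    matches <- matches + sum(cmp)
    total <- total + (e - s)
  }
  if (total == 0L) return(NA_real_)
  100 * matches / total
}

#' Build the cross-dataset match graph
#'
#' Emits one edge for each pair of transcripts from different datasets that
#' overlap genomically on the same chromosome by at least `min_overlap_nt`
#' shared exonic nucleotides. Strand must agree when both are known and is
#' ignored when either is unknown. When both transcripts carry sequences the
#' identity over the shared region must also reach `min_identity`.
#'
#' @param collection A [dataset_collection()].
#' @param min_identity Minimum percent identity over the overlap (applied
#'   only when both sequences are present).
#' @param min_overlap_nt Minimum shared exonic nucleotides; 1 means any
#'   overlap counts as co-detection.
#' @return Data frame of edges: `a`, `b` (transcript ids), `dataset_a`,
#'   `dataset_b`, `overlap_nt`, `identity_pct`, `same_coordinates`.
#' @export
build_match_graph <- function(collection, min_identity = 0,
                              min_overlap_nt = 1L) {
  pool <- pool_transcripts(collection)
  if (length(pool) < 2L)
    return(data.frame(a = character(0), b = character(0),
                      dataset_a = character(0), dataset_b = character(0),
                      overlap_nt = integer(0), identity_pct = numeric(0),
                      same_coordinates = logical(0)))
  gr <- spans_granges(pool)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                drop.self = TRUE, drop.redundant = TRUE))
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  va <- character(0); vb <- character(0); da <- character(0)
  db <- character(0); ov_v <- integer(0); id_v <- numeric(0)
  for (k in seq_along(qh)) {
    a <- pool[[qh[k]]]; b <- pool[[sh[k]]]
    if (identical(a$source, b$source)) next
    if (a$strand != "*" && b$strand != "*" && a$strand != b$strand) next
    ov <- .tx_overlap_nt(a, b)
    if (ov < min_overlap_nt) next
    ident <- .tx_identity_pct(a, b)
    if (!is.na(ident) && ident < min_identity) next
    va <- c(va, a$id); vb <- c(vb, b$id)
    da <- c(da, a$source); db <- c(db, b$source)
    ov_v <- c(ov_v, ov); id_v <- c(id_v, ident)
  }
  df <- data.frame(a = va, b = vb, dataset_a = da, dataset_b = db,
                   overlap_nt = ov_v, identity_pct = id_v,
                   same_coordinates = rep(TRUE, length(va)))
  df[order(df$a, df$b), , drop = FALSE]
}

#' Keep transcripts supported by at least `min_support` datasets
#'
#' Transcripts are connected components of the match graph; a component that
#' spans fewer than `min_support` distinct datasets is dropped entirely.
#' With `min_support = 1` this is the identity on the pooled collection.
#'
#' @param collection A [dataset_collection()].
#' @param edges Match graph from [build_match_graph()].
#' @param min_support Minimum number of distinct supporting datasets.
#' @return List with `kept` (transcripts) and `support` (data frame mapping
#'   each kept transcript id to its component id and the datasets
#'   supporting it, comma-separated).
#' @export
consensus_filter <- function(collection, edges, min_support = 2L) {
  pool <- .sort_transcripts(pool_transcripts(collection))
  ids <- .tx_ids(pool)
  g <- igraph::make_empty_graph(n = length(ids), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = ids)
  if (nrow(edges) > 0L)
    g <- igraph::add_edges(g, t(as.matrix(edges[, c("a", "b")])))
  comp <- igraph::components(g)$membership[ids]
  src <- vapply(pool, function(t) t$source, character(1))
  support <- tapply(src, comp, function(s) sort(unique(s)))
  n_support <- lengths(support)[as.character(comp)]
  keep <- n_support >= min_support
  kept <- pool[keep]
  support_df <- data.frame(
    id = ids[keep], component = unname(comp[keep]),
    datasets = vapply(support[as.character(comp[keep])],
                      paste, character(1), collapse = ","),
    n_datasets = unname(n_support[keep]))
  list(kept = kept, support = support_df)
}

#' Remove redundant transcripts across datasets
#'
#' While any pair of transcripts from different datasets shares more than
#' `max_overlap_nt` genomic nucleotides (strictly), the shorter (spliced
#' length) member is removed; a length tie removes the lexicographically
#' later id. Repeats to a fixpoint, so the result contains no conflicting
#' pair.
#'
#' @param kept List of `transcript_model` objects (consensus-filtered).
#' @param max_overlap_nt Overlap tolerance in nucleotides (exceeding it
#'   strictly triggers removal).
#' @return List with `kept` and `removed`.
#' @export
deduplicate <- function(kept, max_overlap_nt = 100L) {
  txs <- .sort_transcripts(kept)
  if (length(txs) < 2L) return(list(kept = txs, removed = list()))
  # removing a transcript never creates a new overlap, so the conflict pair
  # list is computed once and consumed as members die
  gr <- spans_granges(txs)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, ignore.strand = TRUE,
                                drop.self = TRUE, drop.redundant = TRUE))
  qi <- S4Vectors::queryHits(hits); sj <- S4Vectors::subjectHits(hits)
  keep <- logical(length(qi))
  for (k in seq_along(qi)) {
    a <- txs[[qi[k]]]; b <- txs[[sj[k]]]
    keep[k] <- !identical(a$source, b$source) &&
      .tx_overlap_nt(a, b) > max_overlap_nt
  }
  qi <- qi[keep]; sj <- sj[keep]
  lens <- vapply(txs, tx_length, integer(1))
  ids <- .tx_ids(txs)
  alive <- rep(TRUE, length(txs))
  removed_idx <- integer(0)
  repeat {
    active <- alive[qi] & alive[sj]
    if (!any(active)) break
    # victim per conflicting pair: shorter, tie -> lexicographically later id
    victims <- mapply(function(i, j) {
      if (lens[i] < lens[j]) i
      else if (lens[j] < lens[i]) j
      else if (ids[i] > ids[j]) i else j
    }, qi[active], sj[active])
    victims <- unique(victims)
    # one removal per round, deterministically: shortest first, then id
    pick <- victims[order(lens[victims], ids[victims])][1L]
    alive[pick] <- FALSE
    removed_idx <- c(removed_idx, pick)
  }
  list(kept = txs[alive], removed = txs[removed_idx])
}

#' Assign strand to unknown-strand transcripts from a stranded dataset
#'
#' An unknown-strand transcript adopts the strand of a stranded counterpart
#' when their genomic spans overlap and their sequence identity over the
#' shared region exceeds `min_identity` percent (strictly). Counterparts
#' disagreeing on strand leave the transcript unknown, with a warning.
#'
#' @param unstranded List of `transcript_model` objects (strand may be `*`).
#' @param stranded_set List of `transcript_model` objects with known strand.
#' @param min_identity Percent identity threshold (strict `>`).
#' @return List with `transcripts` (the input list, strands updated),
#'   `n_assigned`, and `conflicts` (ids left unknown due to disagreement).
#' @export
assign_strand <- function(unstranded, stranded_set, min_identity = 95) {
  conflicts <- character(0)
  n_assigned <- 0L
  out <- lapply(unstranded, function(t) {
    if (t$strand != "*") return(t)
    cand_strands <- character(0)
    for (s in stranded_set) {
      if (s$strand == "*") next
      if (s$chrom != t$chrom) next
      sp_t <- tx_span(t); sp_s <- tx_span(s)
      if (sp_t$start >= sp_s$end || sp_s$start >= sp_t$end) next
      ident <- .tx_identity_pct(t, s)
      if (is.na(ident) || ident > min_identity)
        cand_strands <- c(cand_strands, s$strand)
    }
    cand_strands <- unique(cand_strands)
    if (length(cand_strands) == 1L) {
      t$strand <- cand_strands
      # unknown-strand sequences are stored plus-oriented; reorient to 5'->3'
      if (cand_strands == "-" && !is.null(t$sequence))
        t$sequence <- revcomp(t$sequence)
      n_assigned <<- n_assigned + 1L
    } else if (length(cand_strands) > 1L) {
      conflicts <<- c(conflicts, t$id)
    }
    t
  })
  if (length(conflicts) > 0L)
    warning("strand conflict for ", length(conflicts),
            " transcript(s); strand left unknown")
  list(transcripts = out, n_assigned = n_assigned, conflicts = conflicts)
}
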