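#' @importFrom stats rnbinom runif rnorm setNames cor hclust cutree as.dist sd
#' @importFrom utils read.table write.table head
NULL

# Internal coordinate convention: 0-based half-open [start, end).
# GTF files are 1-based inclusive; conversion happens only at I/O boundaries.
# Strand is "+", "-" or "*" (unknown), following the GRanges idiom.

.valid_strands <- c("+", "-", "*")

#' Construct a transcript model
#'
#' A transcript is an ordered set of non-overlapping exons on a single
#' chromosome and strand, with optional spliced sequence and a provenance
#' tag naming the dataset it was assembled from.
#'
#' @param id Unique transcript identifier.
#' @param chrom Chromosome (sequence) name; non-empty string.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @param exons Data frame with integer columns `start`, `end` in 0-based
#'   half-open coordinates. Exons are sorted and must be pairwise disjoint.
#' @param source Optional provenance tag (dataset name).
#' @param gene_id Optional gene identifier (GTF grouping).
#' @param sequence Optional spliced nucleotide sequence, 5'->3' when the
#'   strand is known; its length must equal the summed exon length.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(id, chrom, strand = "*", exons,
                             source = NA_character_, gene_id = NA_character_,
                             sequence = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.character(chrom) || length(chrom) != 1L || !nzchar(chrom))
    stop("transcript '", id, "': chrom must be a non-empty string")
  if (!strand %in% .valid_strands)
    stop("transcript '", id, "': strand must be one of +, -, *")
  exons <- as.data.frame(exons)[, c("start", "end")]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) < 1L) stop("transcript '", id, "': needs at least one exon")
  if (any(exons$start < 0L) || any(exons$end <= exons$start))
    stop("transcript '", id, "': invalid exon coordinates (need 0 <= start < end)")
  exons <- exons[order(exons$start, exons$end), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons) > 1L && any(exons$start[-1L] < exons$end[-nrow(exons)]))
    stop("transcript '", id, "': exons overlap")
  len <- sum(exons$end - exons$start)
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != len)
      stop("transcript '", id, "': sequence length ", nchar(sequence),
           " != exonic length ", len)
  }
  structure(
    list(id = id, chrom = chrom, strand = strand, exons = exons,
         source = source, gene_id = gene_id, sequence = sequence),
    class = "transcript_model"
  )
}

#' Spliced (exonic) length of a transcript in nucleotides
#' @param tx A `transcript_model`.
#' @return Integer length.
#' @export
tx_length <- function(tx) sum(tx$exons$end - tx$exons$start)

#' Genomic span of a transcript as a 0-based half-open interval
#' @param tx A `transcript_model`.
#' @return Named list with `chrom`, `start`, `end`, `strand`.
#' @export
tx_span <- function(tx) {
  list(chrom = tx$chrom, start = min(tx$exons$start),
       end = max(tx$exons$end), strand = tx$strand)
}

#' Introns of a transcript (gaps between consecutive exons)
#' @param tx A `transcript_model`.
#' @return Data frame with `start`, `end` columns (possibly zero rows).
#' @export
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(data.frame(start = integer(0), end = integer(0)))
  data.frame(start = tx$exons$end[-n], end = tx$exons$start[-1L])
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s  %s:%d-%d(%s)  %d exon(s), %d nt%s\n",
              x$id, x$chrom, min(x$exons$start), max(x$exons$end), x$strand,
              nrow(x$exons), tx_length(x),
              if (!is.null(x$sequence)) "  [seq]" else ""))
  invisible(x)
}

#' Group transcripts into gene models by their gene_id
#'
#' @param transcripts List of `transcript_model` objects carrying `gene_id`.
#' @return Named list of `gene_model` objects: each holds its transcripts,
#'   the union of exons, the covering span and the strand.
#' @export
as_gene_models <- function(transcripts) {
  gids <- vapply(transcripts, function(t) t$gene_id, character(1))
  gids[is.na(gids)] <- vapply(transcripts[is.na(gids)], function(t) t$id, character(1))
  out <- lapply(split(transcripts, gids), function(txs) {
    chrom <- unique(vapply(txs, function(t) t$chrom, character(1)))
    if (length(chrom) != 1L)
      stop("gene '", txs[[1L]]$gene_id, "': transcripts on multiple chromosomes")
    strands <- unique(vapply(txs, function(t) t$strand, character(1)))
    strand <- if (length(strands) == 1L) strands else "*"
    ex <- do.call(rbind, lapply(txs, function(t) t$exons))
    ex <- .merge_intervals(ex)
    structure(
      list(id = txs[[1L]]$gene_id %||% txs[[1L]]$id, chrom = chrom,
           strand = strand, transcripts = txs, exons = ex,
           span = c(start = min(ex$start), end = max(ex$end))),
      class = "gene_model")
  })
  out[order(names(out))]
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

# union of possibly overlapping half-open intervals
.merge_intervals <- function(df) {
  df <- df[order(df$start, df$end), , drop = FALSE]
  if (nrow(df) <= 1L) { rownames(df) <- NULL; return(df) }
  starts <- df$start; ends <- df$end
  keep_s <- starts[1L]; out_s <- integer(0); out_e <- integer(0)
  cur_e <- ends[1L]
  for (i in seq_len(nrow(df))[-1L]) {
    if (starts[i] <= cur_e) {
      cur_e <- max(cur_e, ends[i])
    } else {
      out_s <- c(out_s, keep_s); out_e <- c(out_e, cur_e)
      keep_s <- starts[i]; cur_e <- ends[i]
    }
  }
  data.frame(start = c(out_s, keep_s), end = c(out_e, cur_e))
}

# ---------------------------------------------------------------------------
# GTF

.parse_gtf_attributes <- function(attr, key) {
  m <- regmatches(attr, regexec(paste0(key, '[ =]+"?([^";]+)"?'), attr))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
}

#' Read transcript models from a GTF file
#'
#' Exon features are grouped by their `transcript_id` attribute; 1-based
#' inclusive file coordinates are converted to the internal 0-based
#' half-open convention. A strand of `"."` maps to unknown (`"*"`).
#'
#' @param path Path to a GTF file.
#' @param source Provenance tag stored on every returned transcript.
#' @return List of `transcript_model` objects, sorted by (chrom, start, id).
#' @export
read_gtf <- function(path, source = NA_character_) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  if (!any(keep)) return(list())
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield < 9L))
    stop("malformed GTF line ", lineno[which(nfield < 9L)[1L]],
         ": expected 9 tab-separated columns, got ", min(nfield))
  tab <- do.call(rbind, lapply(fields, `[`, 1:9))
  feature <- tab[, 3L]
  is_exon <- feature == "exon"
  if (!any(is_exon)) return(list())
  tab <- tab[is_exon, , drop = FALSE]
  lineno <- lineno[is_exon]
  start1 <- suppressWarnings(as.integer(tab[, 4L]))
  end1 <- suppressWarnings(as.integer(tab[, 5L]))
  bad <- is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1
  if (any(bad))
    stop("malformed GTF line ", lineno[which(bad)[1L]], ": bad coordinates")
  strand <- tab[, 7L]
  strand[strand == "."] <- "*"
  if (any(!strand %in% .valid_strands))
    stop("malformed GTF line ", lineno[which(!strand %in% .valid_strands)[1L]],
         ": bad strand")
  tx_id <- .parse_gtf_attributes(tab[, 9L], "transcript_id")
  gene_id <- .parse_gtf_attributes(tab[, 9L], "gene_id")
  if (anyNA(tx_id))
    stop("malformed GTF line ", lineno[which(is.na(tx_id))[1L]],
         ": missing transcript_id attribute")
  df <- data.frame(tx = tx_id, gene = gene_id, chrom = tab[, 1L],
                   start = start1 - 1L, end = end1, strand = strand)
  txs <- lapply(split(df, df$tx), function(d) {
    if (length(unique(d$chrom)) != 1L)
      stop("transcript '", d$tx[1L], "': exons on multiple chromosomes")
    if (length(unique(d$strand)) != 1L)
      stop("transcript '", d$tx[1L], "': exons on multiple strands")
    transcript_model(d$tx[1L], d$chrom[1L], d$strand[1L],
                     d[, c("start", "end")], source = source,
                     gene_id = d$gene[1L])
  })
  .sort_transcripts(unname(txs))
}

.sort_transcripts <- function(txs) {
  if (length(txs) == 0L) return(txs)
  key <- order(vapply(txs, function(t) t$chrom, character(1)),
               vapply(txs, function(t) min(t$exons$start), integer(1)),
               vapply(txs, function(t) t$id, character(1)))
  txs[key]
}

#' Write transcript models to a GTF file
#'
#' Emits one `exon` feature per exon with `gene_id`/`transcript_id`
#' attributes, in 1-based inclusive coordinates, deterministically ordered
#' by (chrom, start, transcript id). Unknown strand is written as `"."`.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output path.
#' @param feature_source Value for GTF column 2.
#' @return Invisibly, the path.
#' @export
write_gtf <- function(transcripts, path, feature_source = "lncsieve") {
  txs <- .sort_transcripts(transcripts)
  lines <- unlist(lapply(txs, function(t) {
    strand <- if (t$strand == "*") "." else t$strand
    gid <- t$gene_id %||% t$id
    sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
            t$chrom, feature_source, t$exons$start + 1L, t$exons$end,
            strand, gid, t$id)
  }))
  writeLines(lines, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# FASTA

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased on read. Duplicate record ids are an error.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence for FASTA record(s): ",
         paste(ids[!nzchar(seqs)], collapse = ", "))
  names(seqs) <- ids
  seqs
}

#' Write named sequences to a FASTA file
#'
#' @param records Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return Invisibly, the path.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (is.null(names(records)) || any(!nzchar(names(records))))
    stop("all records must be named")
  if (anyDuplicated(names(records)))
    stop("duplicate FASTA ids: ",
         paste(unique(names(records)[duplicated(names(records))]), collapse = ", "))
  set <- Biostrings::BStringSet(toupper(records))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Sequence extraction

#' Extract the spliced transcript sequence from a genome
#'
#' Exon sequences are concatenated in genomic order and reverse-complemented
#' when the transcript is on the minus strand. Unknown-strand transcripts are
#' returned in plus-strand orientation.
#'
#' @param tx A `transcript_model`.
#' @param genome Named character vector of chromosome sequences (as returned
#'   by [read_fasta()]).
#' @return Spliced nucleotide sequence (character scalar); its length equals
#'   `tx_length(tx)`.
#' @export
spliced_sequence <- function(tx, genome) {
  if (!tx$chrom %in% names(genome))
    stop("transcript '", tx$id, "': chromosome '", tx$chrom, "' not in genome")
  chrom_seq <- genome[[tx$chrom]]
  if (max(tx$exons$end) > nchar(chrom_seq))
    stop("transcript '", tx$id, "': exon beyond end of chromosome '",
         tx$chrom, "' (", nchar(chrom_seq), " nt)")
  parts <- substring(chrom_seq, tx$exons$start + 1L, tx$exons$end)
  seq <- paste(parts, collapse = "")
  if (tx$strand == "-") seq <- revcomp(seq)
  seq
}

#' Reverse-complement a nucleotide sequence
#' @param seq Character scalar over A/C/G/T/N (case-insensitive).
#' @return Reverse complement, uppercased.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(toupper(seq))))
}

# ---------------------------------------------------------------------------
# Tabular homology hits (12-column BLAST outfmt 6 dialect)

.hit_cols <- c("query_id", "subject_id", "percent_identity", "alignment_length",
               "mismatches", "gap_opens", "query_start", "query_end",
               "subject_start", "subject_end", "evalue", "bit_score")

#' Read a 12-column tabular homology hit file
#'
#' The standard tabular layout: query, subject, percent identity, alignment
#' length, mismatches, gap opens, query start/end (1-based inclusive),
#' subject start/end, E-value, bit score. Extra trailing columns are ignored
#' with a warning; fewer than 12 columns is a parse error.
#'
#' @param path Path to the hit table (may be empty).
#' @return Data frame with typed columns named as above.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^#", lines)]
  if (length(lines) == 0L) {
    df <- as.data.frame(setNames(rep(list(character(0)), 12L), .hit_cols))
    for (col in .hit_cols[c(3:10, 11, 12)]) df[[col]] <- numeric(0)
    return(df)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L))
    stop("hit table line ", which(nf < 12L)[1L], ": expected 12 columns, got ",
         min(nf))
  if (any(nf > 12L))
    warning("hit table has ", max(nf), " columns; columns beyond 12 ignored")
  tab <- do.call(rbind, lapply(fields, `[`, 1:12))
  df <- data.frame(
    query_id = tab[, 1L], subject_id = tab[, 2L],
    percent_identity = as.numeric(tab[, 3L]),
    alignment_length = as.integer(tab[, 4L]),
    mismatches = as.integer(tab[, 5L]), gap_opens = as.integer(tab[, 6L]),
    query_start = as.integer(tab[, 7L]), query_end = as.integer(tab[, 8L]),
    subject_start = as.integer(tab[, 9L]), subject_end = as.integer(tab[, 10L]),
    evalue = as.numeric(tab[, 11L]), bit_score = as.numeric(tab[, 12L])
  )
  if (anyNA(df$evalue) || any(df$evalue < 0))
    stop("hit table: invalid E-value")
  if (any(df$percent_identity < 0 | df$percent_identity > 100))
    stop("hit table: percent identity out of [0, 100]")
  df
}

#' Write a homology hit table in the 12-column tabular format
#' @param hits Data frame as returned by [read_hit_table()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_hit_table <- function(hits, path) {
  df <- hits[, .hit_cols]
  df$evalue <- formatC(df$evalue, format = "e", digits = 2)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a coding-potential score table
#'
#' Two-column tab-separated file: transcript id, score. Negative scores lean
#' non-coding (CPC-style index). Each id may appear only once.
#'
#' @param path Path to the score table.
#' @return Named numeric vector of scores.
#' @export
read_score_table <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("id", "score"),
                   colClasses = c("character", "numeric"))
  if (anyDuplicated(df$id))
    stop("score table: duplicate ids: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  setNames(df$score, df$id)
}

#' Write a coding-potential score table
#' @param scores Named numeric vector.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_score_table <- function(scores, path) {
  write.table(data.frame(names(scores), unname(scores)), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GRanges bridge and BED export

#' Convert transcript spans to a GRanges object
#' @param transcripts List of `transcript_model` objects.
#' @return A `GRanges` of transcript spans (1-based closed, as usual for
#'   GRanges) with `tx_id` and `source` metadata columns.
#' @export
spans_granges <- function(transcripts) {
  if (length(transcripts) == 0L)
    return(GenomicRanges::GRanges())
  chrom <- vapply(transcripts, function(t) t$chrom, character(1))
  start0 <- vapply(transcripts, function(t) min(t$exons$start), integer(1))
  end0 <- vapply(transcripts, function(t) max(t$exons$end), integer(1))
  strand <- vapply(transcripts, function(t) t$strand, character(1))
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  gr$tx_id <- vapply(transcripts, function(t) t$id, character(1))
  gr$source <- vapply(transcripts, function(t) t$source %||% NA_character_,
                      character(1))
  gr
}

#' Convert transcript exons to a GRanges object
#' @param transcripts List of `transcript_model` objects.
#' @return A `GRanges` with one range per exon and a `tx_id` metadata column.
#' @export
exons_granges <- function(transcripts) {
  if (length(transcripts) == 0L)
    return(GenomicRanges::GRanges())
  n_ex <- vapply(transcripts, function(t) nrow(t$exons), integer(1))
  chrom <- rep(vapply(transcripts, function(t) t$chrom, character(1)), n_ex)
  strand <- rep(vapply(transcripts, function(t) t$strand, character(1)), n_ex)
  start0 <- unlist(lapply(transcripts, function(t) t$exons$start))
  end0 <- unlist(lapply(transcripts, function(t) t$exons$end))
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start0 + 1L, end0),
                               strand = strand)
  gr$tx_id <- rep(vapply(transcripts, function(t) t$id, character(1)), n_ex)
  gr
}

#' Export transcript spans as BED6
#'
#' BED is 0-based half-open, matching the internal convention directly.
#' Name is the transcript id, score is 0, unknown strand becomes `"."`.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_bed6 <- function(transcripts, path) {
  txs <- .sort_transcripts(transcripts)
  lines <- vapply(txs, function(t) {
    sp <- tx_span(t)
    sprintf("%s\t%d\t%d\t%s\t0\t%s", sp$chrom, sp$start, sp$end, t$id,
            if (sp$strand == "*") "." else sp$strand)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Disambiguate transcript ids across datasets
#'
#' Transcripts assembled independently from several datasets may reuse ids;
#' ids are suffixed with `__<dataset>` so the pooled collection stays unique.
#' The original id is recoverable with [base_id()].
#'
#' @param tx A `transcript_model`.
#' @param dataset Dataset name.
#' @return The transcript with a dataset-qualified id and `source` set.
#' @export
tag_dataset <- function(tx, dataset) {
  tx$source <- dataset
  if (!grepl("__", tx$id, fixed = TRUE))
    tx$id <- paste0(tx$id, "__", dataset)
  tx
}

#' Strip the dataset qualifier from a transcript id
#' @param id Character vector of (possibly qualified) transcript ids.
#' @return The base ids.
#' @export
base_id <- function(id) sub("__.*$", "", id)
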