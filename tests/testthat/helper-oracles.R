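# Independent brute-force oracles. These deliberately share no code with the
# package internals: plain position-by-position scans and nested loops.

# every ATG, walk codon by codon to the first stop; best by (aa desc,
# nt start asc, forward before reverse)
oracle_longest_orf <- function(seq, frames = 3L) {
  seq <- toupper(seq)
  scan_one <- function(s) {
    n <- nchar(s)
    best <- NULL
    if (n >= 6L) {
      for (i in seq_len(n - 5L)) {
        if (substring(s, i, i + 2L) != "ATG") next
        j <- i + 3L
        while (j + 2L <= n) {
          codon <- substring(s, j, j + 2L)
          if (codon %in% c("TAA", "TAG", "TGA")) {
            aa <- (j - i) / 3L
            if (is.null(best) || aa > best$aa ||
                (aa == best$aa && (i - 1L) < best$start))
              best <- list(aa = aa, start = i - 1L)
            break
          }
          j <- j + 3L
        }
      }
    }
    best
  }
  fwd <- scan_one(seq)
  out <- list(aa = if (is.null(fwd)) 0L else fwd$aa,
              start = if (is.null(fwd)) NA_integer_ else fwd$start,
              reverse = FALSE)
  if (frames == 6L) {
    comp <- chartr("ACGTN", "TGCAN", seq)
    rc <- paste(rev(strsplit(comp, "")[[1L]]), collapse = "")
    rev_hit <- scan_one(rc)
    if (!is.null(rev_hit)) {
      if (rev_hit$aa > out$aa ||
          (rev_hit$aa == out$aa && (is.na(out$start) ||
                                    rev_hit$start < out$start)))
        out <- list(aa = rev_hit$aa, start = rev_hit$start, reverse = TRUE)
    }
  }
  out
}

# exhaustive classifier over plain interval arithmetic; same contract as
# classify_lncrna (precedence containing > exonic > intronic > intergenic)
oracle_classify <- function(lnc, genes, window = 15000L) {
  genes <- genes[order(vapply(genes, function(g) g$id, character(1)))]
  l_start <- min(lnc$exons$start); l_end <- max(lnc$exons$end)
  n <- nrow(lnc$exons)
  rel <- function(gs) {
    if (lnc$strand == "*" || gs == "*") "unknown"
    else if (lnc$strand == gs) "same" else "opposite"
  }
  # 1. containing
  if (n > 1L) {
    for (g in genes) {
      if (g$chrom != lnc$chrom) next
      for (k in seq_len(n - 1L)) {
        i_s <- lnc$exons$end[k]; i_e <- lnc$exons$start[k + 1L]
        if (i_s <= g$span[["start"]] && g$span[["end"]] <= i_e)
          return("containing")
      }
    }
  }
  # 2. exonic
  for (g in genes) {
    if (g$chrom != lnc$chrom) next
    for (i in seq_len(n)) for (j in seq_len(nrow(g$exons))) {
      if (lnc$exons$start[i] < g$exons$end[j] &&
          g$exons$start[j] < lnc$exons$end[i]) {
        return(switch(rel(g$strand), same = "exonic_sense",
                      opposite = "exonic_antisense",
                      unknown = "exonic_unknown"))
      }
    }
  }
  # 3. intronic (span overlap, no exon contact)
  for (g in genes) {
    if (g$chrom != lnc$chrom) next
    if (l_start < g$span[["end"]] && g$span[["start"]] < l_end)
      return("intronic")
  }
  # 4./5. intergenic by gap
  best <- Inf; best_g <- NULL
  for (g in genes) {
    if (g$chrom != lnc$chrom) next
    d <- if (l_end <= g$span[["start"]]) g$span[["start"]] - l_end
         else l_start - g$span[["end"]]
    if (d < best) { best <- d; best_g <- g }
  }
  if (is.finite(best) && best <= window)
    return(switch(rel(best_g$strand), same = "intergenic_convergent",
                  opposite = "intergenic_divergent",
                  unknown = "intergenic_unoriented"))
  "intergenic_distal"
}

# all-pairs cross-dataset overlap scan (consensus match-graph oracle)
oracle_match_edges <- function(transcripts, min_overlap_nt = 1L) {
  exon_overlap <- function(a, b) {
    if (a$chrom != b$chrom) return(0L)
    tot <- 0L
    for (i in seq_len(nrow(a$exons))) for (j in seq_len(nrow(b$exons))) {
      ov <- min(a$exons$end[i], b$exons$end[j]) -
        max(a$exons$start[i], b$exons$start[j])
      if (ov > 0L) tot <- tot + ov
    }
    tot
  }
  out <- character(0)
  n <- length(transcripts)
  if (n < 2L) return(out)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- transcripts[[i]]; b <- transcripts[[j]]
    if (identical(a$source, b$source)) next
    if (a$strand != "*" && b$strand != "*" && a$strand != b$strand) next
    if (exon_overlap(a, b) >= min_overlap_nt) {
      key <- paste(sort(c(a$id, b$id)), collapse = "|")
      out <- c(out, key)
    }
  }
  sort(out)
}

random_dna <- function(n, with_n = FALSE) {
  alphabet <- if (with_n) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
  prob <- if (with_n) c(0.24, 0.24, 0.24, 0.24, 0.04) else rep(0.25, 4)
  paste(sample(alphabet, n, replace = TRUE, prob = prob), collapse = "")
}

# random non-overlapping single/multi-exon transcripts on a small genome
random_transcripts <- function(n, chroms = c("c1", "c2"), max_pos = 100000L,
                              sources = NULL) {
  lapply(seq_len(n), function(i) {
    chrom <- sample(chroms, 1L)
    start <- sample.int(max_pos, 1L)
    n_ex <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
    lens <- sample(50:400, n_ex, replace = TRUE)
    gaps <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE) else integer(0)
    starts <- start + cumsum(c(0L, lens[-n_ex] + gaps))
    transcript_model(sprintf("rt%04d", i), chrom,
                     sample(c("+", "-", "*"), 1L),
                     data.frame(start = starts, end = starts + lens),
                     source = if (is.null(sources)) NA_character_
                              else sample(sources, 1L))
  })
}

# sequence whose longest ORF is exactly `aa` amino acids, padded to `len` nt
# with an A/C-only tail (no ATG, no stop possible)
orf_sequence <- function(aa, len = NULL) {
  body <- paste0("ATG", strrep("GAA", aa - 1L), "TAA")
  if (is.null(len)) return(body)
  stopifnot(len >= nchar(body))
  paste0(body, strrep("C", len - nchar(body)))
}
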