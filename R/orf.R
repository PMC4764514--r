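# Longest-ORF search used by the coding-potential filter. An ORF is a
# complete ATG..stop span; its amino-acid length counts the codons from the
# ATG up to (excluding) the stop. The ORF fraction charges the stop codon's
# 3 nt to the ORF: fraction = 3 * (aa_length + 1) / transcript length.

.stop_codons <- c("TAA", "TAG", "TGA")

# best complete ORF among the 3 forward frames of `seq`; NULL if none
.scan_forward_frames <- function(seq) {
  n <- nchar(seq)
  best <- NULL
  for (frame in 0:2) {
    n_codon <- (n - frame) %/% 3L
    if (n_codon < 2L) next
    pos <- frame + 3L * (seq_len(n_codon) - 1L) + 1L  # 1-based codon starts
    codons <- substring(seq, pos, pos + 2L)
    starts <- which(codons == "ATG")
    stops <- which(codons %in% .stop_codons)
    if (length(starts) == 0L || length(stops) == 0L) next
    # first in-frame stop strictly after each start
    idx <- findInterval(starts, stops) + 1L
    ok <- idx <= length(stops)
    if (!any(ok)) next
    starts <- starts[ok]
    aa <- stops[idx[ok]] - starts
    i <- which.max(aa)  # ties: which.max picks the first = smallest nt start
    cand <- list(aa_length = aa[i], frame = frame,
                 nt_start = pos[starts[i]] - 1L,            # 0-based
                 nt_end = pos[stops[idx[ok]][i]] + 2L)      # end of stop codon
    if (is.null(best) || cand$aa_length > best$aa_length ||
        (cand$aa_length == best$aa_length && cand$nt_start < best$nt_start))
      best <- cand
  }
  best
}

#' Find the longest complete open reading frame in a sequence
#'
#' Scans the three forward frames (and, when `frames = 6`, the three frames
#' of the reverse complement) for complete ATG-to-stop spans and returns the
#' one with the most amino acids. Ties are broken by the smaller nucleotide
#' start position, then by preferring the forward strand. Codons containing
#' `N` never match a start or stop.
#'
#' @param sequence Nucleotide sequence over A/C/G/T/N (case-insensitive).
#' @param frames Either 3 (forward only; strand known) or 6 (both strands;
#'   strand unknown).
#' @return List with `aa_length` (0 if no complete ORF), `frame` (0-2),
#'   `on_reverse`, `nt_start`/`nt_end` (0-based half-open span within the
#'   scanned orientation, including the stop codon) and `fraction`, the
#'   ORF's share of the transcript length, `3 * (aa_length + 1) / length`
#'   (0 when no ORF).
#' @examples
#' find_longest_orf("ATGAAATAA")  # 2 amino acids (Met-Lys), fraction 1
#' @export
find_longest_orf <- function(sequence, frames = 3L) {
  stopifnot(frames %in% c(3L, 6L))
  sequence <- toupper(as.character(sequence))
  none <- list(aa_length = 0L, frame = NA_integer_, on_reverse = FALSE,
               nt_start = NA_integer_, nt_end = NA_integer_, fraction = 0)
  n <- nchar(sequence)
  if (n == 0L) return(none)
  best <- .scan_forward_frames(sequence)
  if (!is.null(best)) best$on_reverse <- FALSE
  if (frames == 6L) {
    rev_best <- .scan_forward_frames(revcomp(sequence))
    if (!is.null(rev_best)) {
      rev_best$on_reverse <- TRUE
      # forward wins ties at equal aa_length and equal nt start
      if (is.null(best) || rev_best$aa_length > best$aa_length ||
          (rev_best$aa_length == best$aa_length &&
           rev_best$nt_start < best$nt_start))
        best <- rev_best
    }
  }
  if (is.null(best)) return(none)
  best$fraction <- 3 * (best$aa_length + 1) / n
  best[c("aa_length", "frame", "on_reverse", "nt_start", "nt_end", "fraction")]
}
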