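# Tissue expression atlas: RPKM quantification, mean-scaling normalization,
# tissue-specific and housekeeping (ubiquitous) calls, transcriptome
# complexity curves, expression entropy and correlation clustering.

#' Construct a count matrix with library-size and length provenance
#'
#' @param counts Integer matrix, transcripts x tissues, with dimnames.
#' @param lengths Named numeric vector of transcript lengths (nt), covering
#'   every row of `counts`.
#' @param totals Named numeric vector of total mapped reads per tissue,
#'   covering every column. Totals must be at least the column sums.
#' @return A `count_matrix` object.
#' @export
count_matrix <- function(counts, lengths, totals) {
  counts <- as.matrix(counts)
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)),
            all(counts >= 0), all(rownames(counts) %in% names(lengths)),
            all(colnames(counts) %in% names(totals)))
  lengths <- lengths[rownames(counts)]
  totals <- totals[colnames(counts)]
  if (any(lengths <= 0)) stop("transcript lengths must be positive")
  if (any(totals < colSums(counts)))
    stop("library totals smaller than column sums")
  structure(list(counts = counts, lengths = lengths, totals = totals,
                 tissues = colnames(counts)),
            class = "count_matrix")
}

#' Compute RPKM from a count matrix
#'
#' RPKM = count / ((length / 1e3) * (total mapped reads / 1e6)).
#'
#' @param cm A [count_matrix()].
#' @return Numeric matrix of RPKM values with the same dimnames.
#' @export
rpkm <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  if (any(cm$totals <= 0)) stop("zero library total")
  sweep(sweep(cm$counts, 1L, cm$lengths / 1e3, "/"),
        2L, cm$totals / 1e6, "/")
}

#' Mean-scaling normalization across tissues
#'
#' Each tissue column is scaled by (global mean of column means) / (its
#' column mean), so all column means become equal. All-zero columns are left
#' unscaled with a warning.
#'
#' @param mat RPKM matrix (transcripts x tissues).
#' @return Normalized matrix of the same shape.
#' @export
normalize_mean_scaling <- function(mat) {
  cm <- colMeans(mat)
  zero <- cm == 0
  if (any(zero))
    warning(sum(zero), " all-zero tissue column(s) left unscaled")
  target <- mean(cm[!zero])
  factors <- ifelse(zero, 1, target / cm)
  sweep(mat, 2L, factors, "*")
}

#' Call tissue-specific transcripts
#'
#' A transcript is specific to tissue t when its expression there is at
#' least `fold` times the maximum over all other tissues (inclusive ">=")
#' and at least `min_rpkm`. At most one tissue can qualify when `fold > 1`.
#'
#' @param mat RPKM matrix (transcripts x tissues, >= 2 tissues).
#' @param fold Fold-change threshold (inclusive).
#' @param min_rpkm Minimum expression in the candidate tissue.
#' @return Character vector (one per row): the specific tissue, or NA.
#' @export
call_tissue_specific <- function(mat, fold = 8, min_rpkm = 0.5) {
  stopifnot(ncol(mat) >= 2L)
  apply(mat, 1L, function(x) {
    t <- which.max(x)
    others <- max(x[-t])
    if (x[t] >= fold * others && x[t] >= min_rpkm) colnames(mat)[t]
    else NA_character_
  })
}

#' Call ubiquitously expressed (housekeeping) transcripts
#'
#' @param mat RPKM matrix.
#' @param min_rpkm Minimum expression required in every tissue (inclusive).
#' @return Logical vector, one per row.
#' @export
call_ubiquitous <- function(mat, min_rpkm = 1.0) {
  apply(mat, 1L, function(x) min(x) >= min_rpkm)
}

#' Transcriptome complexity curve for one tissue
#'
#' Ranks transcripts by descending expression and returns the cumulative
#' fraction of the tissue's total expression contributed by the top k
#' transcripts; monotone nondecreasing and ending at exactly 1.
#'
#' @param mat RPKM matrix.
#' @param tissue Column name.
#' @return Numeric vector of cumulative fractions, one per rank.
#' @export
complexity_curve <- function(mat, tissue) {
  x <- unname(mat[, tissue])
  if (sum(x) == 0) stop("tissue '", tissue, "' has no expression")
  x <- sort(x, decreasing = TRUE)
  cum <- cumsum(x) / sum(x)
  cum[length(cum)] <- 1
  cum
}

#' Shannon entropy of an expression profile across tissues
#'
#' H = -sum(p_i * log2(p_i)) with p_i = x_i / sum(x); 0 * log(0) is 0.
#' Ranges from 0 (expression confined to one tissue) to log2(n_tissues)
#' (perfectly uniform). Invariant under scaling of the profile.
#'
#' @param profile Non-negative numeric vector with positive sum.
#' @param base Logarithm base (2 for bits).
#' @return Entropy in `log(base)` units.
#' @export
expression_entropy <- function(profile, base = 2) {
  if (any(profile < 0)) stop("negative expression value")
  s <- sum(profile)
  if (s == 0) stop("entropy undefined for an all-zero profile")
  p <- profile / s
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Cluster transcripts by expression correlation and rank by entropy
#'
#' Average-linkage agglomerative clustering on Pearson correlation distance
#' (1 - r). The tree is cut, and clusters recursively split, until every
#' reported cluster's mean pairwise correlation is at least `min_corr`.
#' Within each cluster members are ranked by expression entropy (descending)
#' and the top `retain_fraction` (ceiling, so at least one member) is
#' retained. Zero-variance rows are excluded before correlation, with a
#' message.
#'
#' @param mat Normalized expression matrix (transcripts x tissues, >= 2
#'   tissues).
#' @param min_corr Minimum cluster-mean pairwise Pearson correlation.
#' @param retain_fraction Fraction of members kept after entropy ranking.
#' @param min_size Smallest cluster size reported (singletons excluded by
#'   default).
#' @return List with `clusters`: a list of data frames (`id`, `entropy`,
#'   `retained`), each satisfying the correlation contract; and
#'   `n_excluded`, the number of zero-variance rows dropped.
#' @export
cluster_correlated <- function(mat, min_corr = 0.97, retain_fraction = 0.20,
                               min_size = 2L) {
  stopifnot(ncol(mat) >= 2L)
  variances <- apply(mat, 1L, sd)
  usable <- variances > 0 & !is.na(variances)
  n_excluded <- sum(!usable)
  if (n_excluded > 0L)
    message(n_excluded, " zero-variance row(s) excluded from clustering")
  m <- mat[usable, , drop = FALSE]
  if (nrow(m) < 2L)
    return(list(clusters = list(), n_excluded = n_excluded))
  cmat <- cor(t(m))
  groups <- .split_by_correlation(rownames(m), cmat, min_corr)
  groups <- Filter(function(g) length(g) >= min_size, groups)
  clusters <- lapply(groups, function(ids) {
    ent <- vapply(ids, function(i) expression_entropy(mat[i, ]), numeric(1))
    ord <- order(-ent, ids)
    n_keep <- ceiling(retain_fraction * length(ids))
    data.frame(id = ids[ord], entropy = ent[ord],
               retained = seq_along(ids) <= n_keep)
  })
  # deterministic ordering: by size (desc) then first member id
  if (length(clusters) > 1L) {
    key <- order(-vapply(clusters, nrow, integer(1)),
                 vapply(clusters, function(cl) cl$id[1L], character(1)))
    clusters <- clusters[key]
  }
  list(clusters = clusters, n_excluded = n_excluded)
}

# recursively split ids until mean pairwise correlation >= min_corr
.split_by_correlation <- function(ids, cmat, min_corr) {
  if (length(ids) == 1L) return(list(ids))
  sub <- cmat[ids, ids]
  mean_r <- mean(sub[upper.tri(sub)])
  if (mean_r >= min_corr) return(list(sort(ids)))
  hc <- hclust(as.dist(1 - sub), method = "average")
  parts <- cutree(hc, k = 2L)
  c(.split_by_correlation(ids[parts == 1L], cmat, min_corr),
    .split_by_correlation(ids[parts == 2L], cmat, min_corr))
}
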