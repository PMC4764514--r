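# Deterministic synthetic-data generator. Builds a toy genome in which
# protein-coding genes, small RNAs and lncRNAs of every genomic-context
# class are planted with known truth labels, together with the homology hit
# tables, coding-potential scores, multi-dataset transcript views and
# per-tissue read counts the discovery pipeline consumes. Generation is a
# pure function of (config, seed).

.default_tissues <- c("brain", "white_muscle", "red_muscle", "fat", "gill",
                      "head_kidney", "kidney", "intestine", "skin", "spleen",
                      "stomach", "liver", "testis")

.default_class_counts <- c(
  intronic = 40L, exonic_sense = 20L, exonic_antisense = 20L,
  exonic_unknown = 25L, containing = 10L,
  intergenic_convergent = 45L, intergenic_divergent = 45L,
  intergenic_unoriented = 40L, intergenic_distal = 55L)

.genic_classes <- c("intronic", "exonic_sense", "exonic_antisense",
                    "exonic_unknown", "containing")
.stranded_required <- c("exonic_sense", "exonic_antisense",
                        "intergenic_convergent", "intergenic_divergent")
.unknown_classes <- c("exonic_unknown", "intergenic_unoriented")

# run expr with a private RNG state seeded from `seed`
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Configuration of the synthetic genome and datasets
#'
#' Defaults emulate the reference study's conditions: four transcriptome
#' datasets (one stranded Ribo-Zero-like), 13 tissues, lncRNAs averaging
#' ~0.82 kb and mostly single-exon versus protein-coding genes averaging
#' ~1.64 kb with ~4.8 exons, and negative-binomial read counts.
#'
#' @param seed Mandatory RNG seed; generation is a pure function of
#'   (config, seed).
#' @param n_coding Number of protein-coding genes (each also emitted as an
#'   assembled candidate transcript).
#' @param n_small_rna Number of planted small RNAs (< 200 nt).
#' @param class_counts Named integer vector of planted lncRNAs per
#'   genomic-context class.
#' @param tissues Tissue names (13 by default).
#' @param datasets Dataset names (4 by default).
#' @param stranded Name of the dataset carrying true strand information.
#' @param lnc_length_mean,lnc_length_sd,lnc_length_min,lnc_length_max
#'   Truncated-normal spliced-length model for lncRNAs (nt).
#' @param coding_length_mean,coding_length_sd mRNA length model (nt).
#' @param n_specific,n_ubiquitous Numbers of lncRNAs planted with a
#'   tissue-specific or ubiquitous expression pattern (rest are random).
#' @param n_coexpr_blocks Co-expression blocks (2 coding + 3 lncRNA members
#'   sharing a profile shape) planted among the random-pattern transcripts.
#' @param specific_rpkm Expression of a specific transcript in its target
#'   tissue (the study-wide mean lncRNA abundance is ~3.5 RPKM).
#' @param background_rpkm Leaky expression of specific transcripts in the
#'   other tissues.
#' @param ubiquitous_rpkm Expression of ubiquitous transcripts everywhere.
#' @param library_size Total mapped reads per tissue.
#' @param nb_size Negative-binomial size (dispersion) parameter; larger is
#'   closer to Poisson.
#' @param conserved_fraction Fraction of lncRNAs given known-lncRNA
#'   database hits (annotated, never filtered).
#' @param slot_width,slots_per_chrom Genome layout: each gene (with any
#'   companion lncRNAs) occupies one slot; slots are wide enough that
#'   features of different slots are always > 15 kb apart.
#' @return A `synth_config` list.
#' @export
synth_config <- function(seed,
                         n_coding = 200L, n_small_rna = 100L,
                         class_counts = .default_class_counts,
                         tissues = .default_tissues,
                         datasets = c("polyA_pe", "polyA_sr", "steelhead",
                                      "ribozero"),
                         stranded = "ribozero",
                         lnc_length_mean = 821, lnc_length_sd = 250,
                         lnc_length_min = 450, lnc_length_max = 2000,
                         coding_length_mean = 1636, coding_length_sd = 200,
                         n_specific = 60L, n_ubiquitous = 60L,
                         n_coexpr_blocks = 8L,
                         specific_rpkm = 4, background_rpkm = 0.05,
                         ubiquitous_rpkm = 4,
                         library_size = 1e7, nb_size = 50,
                         conserved_fraction = 0.1,
                         slot_width = 40000L, slots_per_chrom = 40L) {
  if (missing(seed)) stop("synth_config: a seed is mandatory")
  stopifnot(all(names(.default_class_counts) %in% names(class_counts)),
            stranded %in% datasets, length(datasets) >= 2L,
            length(tissues) >= 2L)
  class_counts <- class_counts[names(.default_class_counts)]
  n_lnc <- sum(class_counts)
  n_genic <- sum(class_counts[.genic_classes])
  n_near <- sum(class_counts[c("intergenic_convergent", "intergenic_divergent",
                               "intergenic_unoriented")])
  if (n_genic > n_coding)
    stop("infeasible layout: ", n_genic, " genic lncRNAs but only ",
         n_coding, " genes")
  if (n_genic + ceiling(n_near / 2) > n_coding)
    stop("infeasible layout: not enough genes to host the intergenic lncRNAs")
  if (n_specific + n_ubiquitous > n_lnc)
    stop("more planted expression patterns than lncRNAs")
  structure(
    list(seed = seed, n_coding = as.integer(n_coding),
         n_small_rna = as.integer(n_small_rna),
         class_counts = class_counts, tissues = tissues,
         datasets = datasets, stranded = stranded,
         lnc_length_mean = lnc_length_mean, lnc_length_sd = lnc_length_sd,
         lnc_length_min = lnc_length_min, lnc_length_max = lnc_length_max,
         coding_length_mean = coding_length_mean,
         coding_length_sd = coding_length_sd,
         n_specific = as.integer(n_specific),
         n_ubiquitous = as.integer(n_ubiquitous),
         n_coexpr_blocks = as.integer(n_coexpr_blocks),
         specific_rpkm = specific_rpkm, background_rpkm = background_rpkm,
         ubiquitous_rpkm = ubiquitous_rpkm,
         library_size = library_size, nb_size = nb_size,
         conserved_fraction = conserved_fraction,
         slot_width = as.integer(slot_width),
         slots_per_chrom = as.integer(slots_per_chrom)),
    class = "synth_config")
}

.bases <- c("A", "C", "G", "T")
.non_stop_codons <- {
  all_codons <- as.vector(outer(as.vector(outer(.bases, .bases, paste0)),
                                .bases, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
}

.random_bases <- function(n) sample(.bases, n, replace = TRUE)

# mRNA with a complete ORF of `aa` amino acids (ATG + aa-1 codons + stop)
.coding_mrna <- function(len, aa) {
  orf_nt <- 3L * (aa + 1L)
  stopifnot(orf_nt <= len)
  utr5 <- (len - orf_nt) %/% 2L
  utr3 <- len - orf_nt - utr5
  paste0(paste(.random_bases(utr5), collapse = ""),
         "ATG",
         paste(sample(.non_stop_codons, aa - 1L, replace = TRUE),
               collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L),
         paste(.random_bases(utr3), collapse = ""))
}

# split `total` nt over `k` exons, each at least `min_len`
.partition_length <- function(total, k, min_len = 120L) {
  if (k == 1L) return(total)
  w <- runif(k, 0.5, 1.5)
  lens <- pmax(min_len, floor(total * w / sum(w)))
  lens[k] <- total - sum(lens[-k])
  if (lens[k] < min_len) {  # rebalance from the largest exon
    i <- which.max(lens[-k])
    lens[i] <- lens[i] - (min_len - lens[k])
    lens[k] <- min_len
  }
  lens
}

# write a plus-strand base string into chrom base vector at exon coords
.write_exons <- function(chrom_bases, exons, plus_seq) {
  pos <- unlist(mapply(function(s, e) (s + 1L):e, exons$start, exons$end,
                       SIMPLIFY = FALSE))
  chrom_bases[pos] <- strsplit(plus_seq, "")[[1L]]
  chrom_bases
}

.read_exons <- function(chrom_bases, exons) {
  pos <- unlist(mapply(function(s, e) (s + 1L):e, exons$start, exons$end,
                       SIMPLIFY = FALSE))
  paste(chrom_bases[pos], collapse = "")
}

#' Expected RPKM profile for a planted expression pattern
#'
#' The pattern encodes what the tissue-expression caller should recover:
#' a `specific` transcript is expressed at `specific_rpkm` in its target
#' tissue and leakily (`background_rpkm`) elsewhere; a `ubiquitous` one at
#' `ubiquitous_rpkm` in every tissue; a `random` one draws an independent
#' log-normal level per tissue.
#'
#' @param pattern One of `"specific"`, `"ubiquitous"`, `"random"`.
#' @param tissue Target tissue (required for `"specific"`).
#' @param config A [synth_config()].
#' @return Named numeric vector of expected RPKM, one entry per tissue.
#' @export
plant_expression_pattern <- function(pattern, tissue = NA_character_,
                                     config) {
  tissues <- config$tissues
  out <- switch(pattern,
    specific = {
      stopifnot(tissue %in% tissues)
      x <- rep(config$background_rpkm, length(tissues))
      x[match(tissue, tissues)] <- config$specific_rpkm
      x
    },
    ubiquitous = rep(config$ubiquitous_rpkm, length(tissues)),
    random = stats::rlnorm(length(tissues), meanlog = log(2), sdlog = 1),
    stop("unknown expression pattern: ", pattern))
  setNames(out, tissues)
}

#' Draw negative-binomial read counts around an expected RPKM profile
#'
#' The expected count in tissue j is
#' `rpkm_j * (length / 1e3) * (total_j / 1e6)`; counts are drawn from a
#' negative binomial with that mean and size `nb_size` (size `Inf` gives
#' the noise-free expectation, rounded).
#'
#' @param expected_rpkm Named numeric vector (one entry per tissue).
#' @param len Transcript length in nt.
#' @param totals Named numeric vector of per-tissue library sizes.
#' @param nb_size Negative-binomial size parameter; `Inf` for noise-free.
#' @return Integer vector of counts, named by tissue.
#' @export
simulate_counts <- function(expected_rpkm, len, totals, nb_size = 50) {
  mu <- expected_rpkm * (len / 1e3) * (totals[names(expected_rpkm)] / 1e6)
  if (is.infinite(nb_size)) return(setNames(as.integer(round(mu)),
                                            names(expected_rpkm)))
  setNames(as.integer(rnbinom(length(mu), mu = mu, size = nb_size)),
           names(expected_rpkm))
}

# rewrite the freely-assignable bases of a planted lncRNA until its longest
# 6-frame ORF stays safely inside the keep conditions of both regimes
.plant_lnc_sequence <- function(chrom_bases, exons, fixed_mask,
                                max_aa = 80L, max_fraction = 0.33,
                                max_tries = 200L, label = "lncRNA") {
  pos <- unlist(mapply(function(s, e) (s + 1L):e, exons$start, exons$end,
                       SIMPLIFY = FALSE))
  free <- pos[!fixed_mask]
  for (i in seq_len(max_tries)) {
    chrom_bases[free] <- sample(.bases, length(free), replace = TRUE)
    seq <- paste(chrom_bases[pos], collapse = "")
    orf <- find_longest_orf(seq, frames = 6L)
    if (orf$aa_length <= max_aa && orf$fraction <= max_fraction)
      return(chrom_bases)
  }
  stop("could not plant an ORF-free sequence for ", label,
       " after ", max_tries, " attempts")
}

.hit_row <- function(query, subject, len, evalue) {
  data.frame(query_id = query, subject_id = subject,
             percent_identity = round(runif(1, 85, 100), 1),
             alignment_length = len,
             mismatches = sample(0:10, 1L), gap_opens = sample(0:2, 1L),
             query_start = 1L, query_end = len,
             subject_start = 1L, subject_end = len,
             evalue = evalue, bit_score = round(runif(1, 50, 500), 1))
}

.empty_hits <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   percent_identity = numeric(0),
                   alignment_length = integer(0), mismatches = integer(0),
                   gap_opens = integer(0), query_start = integer(0),
                   query_end = integer(0), subject_start = integer(0),
                   subject_end = integer(0), evalue = numeric(0),
                   bit_score = numeric(0))
  df
}

#' Generate a complete synthetic fixture with planted truth
#'
#' Builds the genome, the protein-coding annotation, per-dataset candidate
#' transcripts (coding, small-RNA and lncRNA roles), homology hit tables
#' (protein, small-RNA and known-lncRNA databases), a coding-potential
#' score table, per-tissue read counts and a truth table tracing every
#' record. Planted records are constructed to pass or fail each filter with
#' margin: coding transcripts carry ORFs well over 100 aa, protein hits at
#' E far below 1e-4 and positive coding scores; small RNAs are < 200 nt with
#' small-RNA database hits; lncRNAs are >= 450 nt, ORF-limited, hit-free
#' and score below -1.3, and are placed to realize their genomic-context
#' class exactly. Every lncRNA is emitted to at least two datasets.
#'
#' @param config A [synth_config()].
#' @return List with `genome` (named character vector), `coding_transcripts`
#'   (annotation transcripts), `genes` (gene models), `collection`
#'   (a [dataset_collection()] of candidate transcripts with sequences),
#'   `nr_hits`, `ncrna_hits`, `lncdb_hits`, `scores`, `counts`
#'   (a [count_matrix()]), `expected_rpkm` (noise-free RPKM matrix),
#'   `truth` (data frame) and `config`.
#' @export
synth_generate <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  .with_seed(config$seed, .synth_generate_impl(config))
}

.synth_generate_impl <- function(config) {
  cc <- config$class_counts
  n_lnc <- sum(cc)
  W <- config$slot_width
  spc <- config$slots_per_chrom
  n_gene_chroms <- ceiling(config$n_coding / spc)
  chrom_names <- paste0("chr", seq_len(n_gene_chroms))
  n_orphan <- cc[["intergenic_distal"]] + config$n_small_rna
  orphan_len <- (n_orphan + 1L) * 3000L + 2000L

  genome <- c(
    setNames(lapply(seq_len(n_gene_chroms),
                    function(i) .random_bases(spc * W)), chrom_names),
    list(chrU = .random_bases(orphan_len)))

  # ------- assign lncRNA classes to host genes -------------------------
  genic_lnc <- rep(.genic_classes, cc[.genic_classes])
  near_classes <- c("intergenic_convergent", "intergenic_divergent",
                    "intergenic_unoriented")
  near_lnc <- sample(rep(near_classes, cc[near_classes]))
  n_genic <- length(genic_lnc)
  # genes 1..n_genic host one genic lncRNA; subsequent genes host up to two
  # intergenic companions (one on each side)
  host_of <- integer(0); side_of <- integer(0)
  if (length(near_lnc) > 0L) {
    host_of <- n_genic + ceiling(seq_along(near_lnc) / 2)
    side_of <- rep_len(c(1L, -1L), length(near_lnc))
  }

  lnc_lengths <- pmin(config$lnc_length_max,
                      pmax(config$lnc_length_min,
                           round(rnorm(n_lnc, config$lnc_length_mean,
                                       config$lnc_length_sd))))

  # ------- build genes --------------------------------------------------
  genes <- vector("list", config$n_coding)
  coding_tx <- vector("list", config$n_coding)
  lnc_plan <- list()   # geometry requests, resolved after genes exist
  lnc_i <- 0L
  for (g in seq_len(config$n_coding)) {
    slot <- g - 1L
    chrom <- chrom_names[slot %/% spc + 1L]
    centre <- (slot %% spc) * W + W %/% 2L
    strand <- sample(c("+", "-"), 1L)
    hosts_genic <- if (g <= n_genic) genic_lnc[g] else NA_character_
    mrna_len <- max(900L, round(rnorm(1L, config$coding_length_mean,
                                      config$coding_length_sd)))
    if (identical(hosts_genic, "intronic")) {
      lnc_i <- lnc_i + 1L
      lnc_len <- lnc_lengths[lnc_i]
      exon_lens <- .partition_length(mrna_len, 2L)
      intron_lens <- lnc_len + 600L
    } else {
      if (!is.na(hosts_genic)) lnc_i <- lnc_i + 1L
      n_ex <- sample(3:7, 1L, prob = c(0.15, 0.3, 0.25, 0.2, 0.1))
      exon_lens <- .partition_length(mrna_len, n_ex)
      intron_lens <- round(runif(length(exon_lens) - 1L, 300, 1500))
    }
    span_len <- sum(exon_lens) + sum(intron_lens)
    gstart <- centre - span_len %/% 2L
    starts <- gstart + cumsum(c(0L, head(exon_lens, -1L) + intron_lens))
    exons <- data.frame(start = as.integer(starts),
                        end = as.integer(starts + exon_lens))
    aa <- max(110L, floor(0.8 * mrna_len / 3) - 1L)
    mrna <- .coding_mrna(mrna_len, aa)
    plus_seq <- if (strand == "+") mrna else revcomp(mrna)
    genome[[chrom]] <- .write_exons(genome[[chrom]], exons, plus_seq)
    gid <- sprintf("GENE%04d", g)
    coding_tx[[g]] <- transcript_model(sprintf("CODT%04d", g), chrom, strand,
                                       exons, gene_id = gid)
    genes[[g]] <- list(id = gid, chrom = chrom, strand = strand,
                       exons = exons, centre = centre, orf_aa = aa,
                       mrna_len = mrna_len)
    if (!is.na(hosts_genic))
      lnc_plan[[lnc_i]] <- list(class = hosts_genic, gene = g,
                                length = lnc_lengths[lnc_i], side = 1L)
  }
  for (k in seq_along(near_lnc)) {
    lnc_i <- lnc_i + 1L
    lnc_plan[[lnc_i]] <- list(class = near_lnc[k], gene = host_of[k],
                              length = lnc_lengths[lnc_i], side = side_of[k])
  }
  n_distal <- cc[["intergenic_distal"]]
  for (k in seq_len(n_distal)) {
    lnc_i <- lnc_i + 1L
    lnc_plan[[lnc_i]] <- list(class = "intergenic_distal", gene = NA_integer_,
                              length = lnc_lengths[lnc_i], side = k)
  }

  # ------- place lncRNAs and plant their sequences ----------------------
  lncs <- vector("list", n_lnc)
  for (i in seq_len(n_lnc)) {
    plan <- lnc_plan[[i]]
    L <- plan$length
    cls <- plan$class
    two_exon <- FALSE
    if (cls %in% c("intergenic_convergent", "intergenic_divergent",
                   "intergenic_unoriented", "intergenic_distal"))
      two_exon <- runif(1) < 0.12
    if (is.na(plan$gene)) {                        # distal, orphan chrom
      chrom <- "chrU"
      anchor <- plan$side * 3000L + 1500L
      exons <- if (two_exon) {
        l1 <- L %/% 2L; intr <- 400L
        data.frame(start = anchor, end = anchor + l1) |>
          rbind(data.frame(start = anchor + l1 + intr,
                           end = anchor + intr + L))
      } else data.frame(start = anchor, end = anchor + L)
      strand <- sample(c("+", "-"), 1L)
      fixed <- rep(FALSE, L)
    } else {
      g <- genes[[plan$gene]]
      chrom <- g$chrom
      gs <- min(g$exons$start); ge <- max(g$exons$end)
      if (cls == "intronic") {
        istart <- g$exons$end[1L]
        exons <- data.frame(start = istart + 300L, end = istart + 300L + L)
        strand <- sample(c("+", "-"), 1L)
        fixed <- rep(FALSE, L)
      } else if (cls %in% c("exonic_sense", "exonic_antisense",
                            "exonic_unknown")) {
        ov <- 80L
        exons <- data.frame(start = ge - ov, end = ge - ov + L)
        strand <- switch(cls, exonic_sense = g$strand,
                         exonic_antisense = setdiff(c("+", "-"), g$strand),
                         exonic_unknown = "*")
        fixed <- c(rep(TRUE, ov), rep(FALSE, L - ov))
      } else if (cls == "containing") {
        L <- 1600L
        exons <- data.frame(start = c(gs - 1200L, ge + 400L),
                            end = c(gs - 400L, ge + 1200L))
        strand <- sample(c("+", "-"), 1L)
        fixed <- rep(FALSE, L)
      } else {                                     # intergenic near classes
        d <- round(runif(1, 2000, 10000))
        span <- if (two_exon) L + 400L else L
        exons <- if (plan$side > 0L)
          data.frame(start = ge + d, end = ge + d + span)
        else data.frame(start = gs - d - span, end = gs - d)
        if (two_exon) {
          l1 <- L %/% 2L
          s0 <- exons$start[1L]
          exons <- data.frame(start = c(s0, s0 + l1 + 400L),
                              end = c(s0 + l1, s0 + 400L + L))
        }
        strand <- switch(cls,
                         intergenic_convergent = g$strand,
                         intergenic_divergent = setdiff(c("+", "-"), g$strand),
                         intergenic_unoriented = "*")
        fixed <- rep(FALSE, L)
      }
    }
    exons$start <- as.integer(exons$start); exons$end <- as.integer(exons$end)
    genome[[chrom]] <- .plant_lnc_sequence(
      genome[[chrom]], exons, fixed,
      label = sprintf("LNC%04d (%s)", i, cls))
    lncs[[i]] <- list(id = sprintf("LNC%04d", i), chrom = chrom,
                      strand = strand, exons = exons, class = cls, length = L)
  }

  # ------- small RNAs ---------------------------------------------------
  smalls <- lapply(seq_len(config$n_small_rna), function(k) {
    L <- round(runif(1, 70, 180))
    anchor <- (n_distal + k) * 3000L + 1500L
    list(id = sprintf("SML%04d", k), chrom = "chrU",
         strand = sample(c("+", "-"), 1L),
         exons = data.frame(start = anchor, end = as.integer(anchor + L)),
         length = L)
  })

  # ------- dataset emission --------------------------------------------
  ds <- config$datasets
  others <- setdiff(ds, config$stranded)
  emit_for <- function(role, cls = NA_character_) {
    if (role == "lncRNA") {
      if (cls %in% .unknown_classes) {
        k <- sample(2:min(3L, length(others)), 1L)
        sort(sample(others, k))
      } else if (cls %in% .stranded_required) {
        k <- sample(2:length(ds), 1L)
        sort(c(config$stranded, sample(others, k - 1L)))
      } else {
        k <- sample(2:length(ds), 1L)
        sort(sample(ds, k))
      }
    } else {
      k <- sample(seq_along(ds), 1L)
      sort(sample(ds, k))
    }
  }

  records <- c(
    lapply(seq_along(coding_tx), function(g)
      list(base = sprintf("COD%04d", g), role = "coding",
           chrom = coding_tx[[g]]$chrom, strand = coding_tx[[g]]$strand,
           exons = coding_tx[[g]]$exons, class = NA_character_,
           datasets = emit_for("coding"))),
    lapply(lncs, function(l)
      list(base = l$id, role = "lncRNA", chrom = l$chrom, strand = l$strand,
           exons = l$exons, class = l$class,
           datasets = emit_for("lncRNA", l$class))),
    lapply(smalls, function(s)
      list(base = s$id, role = "small_rna", chrom = s$chrom,
           strand = s$strand, exons = s$exons, class = NA_character_,
           datasets = emit_for("small_rna"))))

  genome_strings <- vapply(genome, paste, character(1), collapse = "")

  per_dataset <- setNames(lapply(ds, function(d) list()), ds)
  for (r in records) {
    for (d in r$datasets) {
      strand <- if (d == config$stranded) r$strand else "*"
      tx <- transcript_model(r$base, r$chrom, strand, r$exons)
      tx$sequence <- spliced_sequence(tx, genome_strings)
      per_dataset[[d]] <- c(per_dataset[[d]], list(tx))
    }
  }
  collection <- dataset_collection(per_dataset, stranded = config$stranded)

  # ------- hit tables and scores ---------------------------------------
  qid <- function(base, d) paste0(base, "__", d)
  nr_rows <- list(); nc_rows <- list(); db_rows <- list()
  scores <- numeric(0)
  lnc_ids <- vapply(lncs, function(l) l$id, character(1))
  conserved_ids <- sort(sample(lnc_ids,
                               round(config$conserved_fraction * n_lnc)))
  weak_hit_ids <- sort(sample(setdiff(lnc_ids, character(0)),
                              round(0.1 * n_lnc)))
  ncrna_dbs <- c("tRNA", "miRNA", "LSU", "SSU")
  for (r in records) {
    for (d in r$datasets) {
      q <- qid(r$base, d)
      len <- sum(r$exons$end - r$exons$start)
      if (r$role == "coding") {
        nr_rows[[length(nr_rows) + 1L]] <-
          .hit_row(q, sprintf("nr|prot%05d", sample.int(99999L, 1L)),
                   min(len, 500L), 10 ^ runif(1, -50, -10))
        scores[q] <- round(runif(1, 0.5, 3), 3)
      } else if (r$role == "small_rna") {
        nc_rows[[length(nc_rows) + 1L]] <-
          .hit_row(q, sprintf("%s|rna%05d", sample(ncrna_dbs, 1L),
                              sample.int(99999L, 1L)),
                   len, 10 ^ runif(1, -30, -8))
        if (runif(1) < 0.5) scores[q] <- round(runif(1, -2, -1.3), 3)
      } else {
        scores[q] <- round(runif(1, -2, -1.3), 3)
        if (r$base %in% conserved_ids)
          db_rows[[length(db_rows) + 1L]] <-
            .hit_row(q, sprintf("lncdb|known%05d", sample.int(99999L, 1L)),
                     min(len, 400L), 10 ^ runif(1, -20, -5))
        if (r$base %in% weak_hit_ids)
          nr_rows[[length(nr_rows) + 1L]] <-
            .hit_row(q, sprintf("nr|prot%05d", sample.int(99999L, 1L)),
                     min(len, 200L), 10 ^ runif(1, -3, -1))
      }
    }
  }
  bind_hits <- function(rows)
    if (length(rows) > 0L) do.call(rbind, rows) else .empty_hits()

  # ------- expression ---------------------------------------------------
  tissues <- config$tissues
  pattern <- rep("random", n_lnc)
  if (config$n_specific > 0L) pattern[seq_len(config$n_specific)] <- "specific"
  if (config$n_ubiquitous > 0L)
    pattern[config$n_specific + seq_len(config$n_ubiquitous)] <- "ubiquitous"
  specific_tissue <- rep(NA_character_, n_lnc)
  specific_tissue[pattern == "specific"] <-
    rep_len(tissues, config$n_specific)

  cod_ids <- vapply(coding_tx, function(t) sub("^CODT", "COD", t$id),
                    character(1))
  cod_lens <- vapply(coding_tx, tx_length, integer(1))
  all_ids <- c(lnc_ids, cod_ids)
  all_lens <- setNames(c(vapply(lncs, function(l)
    sum(l$exons$end - l$exons$start), integer(1)), cod_lens), all_ids)
  totals <- setNames(rep(config$library_size, length(tissues)), tissues)

  expected <- matrix(0, nrow = length(all_ids), ncol = length(tissues),
                     dimnames = list(all_ids, tissues))
  for (i in seq_len(n_lnc))
    expected[lnc_ids[i], ] <- plant_expression_pattern(
      pattern[i], specific_tissue[i], config)
  cod_pattern <- rep("random", length(cod_ids))
  for (j in seq_along(cod_ids))
    expected[cod_ids[j], ] <- plant_expression_pattern("random", config = config)
  # co-expression blocks: 2 coding + 3 random-pattern lncRNAs share a shape
  random_lnc <- lnc_ids[pattern == "random"]
  block_of <- setNames(rep(NA_integer_, length(all_ids)), all_ids)
  n_blocks <- config$n_coexpr_blocks
  if (n_blocks > 0L && length(random_lnc) >= 3L * n_blocks &&
      length(cod_ids) >= 2L * n_blocks) {
    lnc_pool <- sample(random_lnc, 3L * n_blocks)
    cod_pool <- sample(cod_ids, 2L * n_blocks)
    for (b in seq_len(n_blocks)) {
      shape <- stats::rlnorm(length(tissues), log(30), 0.8)
      members <- c(lnc_pool[(3L * b - 2L):(3L * b)],
                   cod_pool[(2L * b - 1L):(2L * b)])
      for (m in members) {
        expected[m, ] <- shape * runif(1, 0.5, 2)
        block_of[m] <- b
      }
    }
  }
  counts <- t(vapply(all_ids, function(id)
    simulate_counts(setNames(expected[id, ], tissues), len = all_lens[[id]],
                    totals = totals, nb_size = config$nb_size),
    integer(length(tissues))))
  colnames(counts) <- tissues
  cm <- count_matrix(counts, all_lens, totals)

  # ------- truth --------------------------------------------------------
  truth_of <- function(r) {
    len <- sum(r$exons$end - r$exons$start)
    data.frame(
      id = r$base, role = r$role, class = r$class,
      chrom = r$chrom, start = min(r$exons$start), end = max(r$exons$end),
      strand = r$strand, length = len, n_exons = nrow(r$exons),
      datasets = paste(r$datasets, collapse = ","),
      n_datasets = length(r$datasets),
      conserved = r$role == "lncRNA" && r$base %in% conserved_ids,
      pattern = if (r$role == "lncRNA") pattern[match(r$base, lnc_ids)]
                else if (r$role == "coding") "random" else NA_character_,
      specific_tissue = if (r$role == "lncRNA")
        specific_tissue[match(r$base, lnc_ids)] else NA_character_,
      coexpr_block = if (r$role %in% c("lncRNA", "coding"))
                       block_of[[r$base]] else NA_integer_)
  }
  truth <- do.call(rbind, c(lapply(records, truth_of),
                            list(make.row.names = FALSE)))

  list(genome = genome_strings,
       coding_transcripts = coding_tx,
       genes = as_gene_models(coding_tx),
       collection = collection,
       nr_hits = bind_hits(nr_rows),
       ncrna_hits = bind_hits(nc_rows),
       lncdb_hits = bind_hits(db_rows),
       scores = scores,
       counts = cm,
       expected_rpkm = expected,
       truth = truth,
       config = config)
}

#' Write a synthetic fixture to plain-text files
#'
#' Emits genome.fa, coding.gtf, one GTF and FASTA per dataset, the three
#' hit tables, the score table, counts/lengths/totals TSVs and truth.tsv.
#'
#' @param fixture Result of [synth_generate()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, `dir`.
#' @export
write_fixture <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_fasta(fixture$genome, p("genome.fa"))
  write_gtf(fixture$coding_transcripts, p("coding.gtf"))
  for (d in names(fixture$collection$datasets)) {
    txs <- fixture$collection$datasets[[d]]
    write_gtf(txs, p(paste0(d, ".gtf")))
    seqs <- setNames(vapply(txs, function(t) t$sequence, character(1)),
                     vapply(txs, function(t) t$id, character(1)))
    if (length(seqs) > 0L) write_fasta(seqs, p(paste0(d, ".fa")))
  }
  write_hit_table(fixture$nr_hits, p("nr_hits.tsv"))
  write_hit_table(fixture$ncrna_hits, p("ncrna_hits.tsv"))
  write_hit_table(fixture$lncdb_hits, p("lncdb_hits.tsv"))
  write_score_table(fixture$scores, p("scores.tsv"))
  write.table(data.frame(id = rownames(fixture$counts$counts),
                         fixture$counts$counts, check.names = FALSE),
              p("counts.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(id = names(fixture$counts$lengths),
                         length = unname(fixture$counts$lengths)),
              p("lengths.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(tissue = names(fixture$counts$totals),
                         total = unname(fixture$counts$totals)),
              p("totals.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(fixture$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(dir)
}
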