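# Shared synthetic fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

small_class_counts <- c(
  intronic = 4L, exonic_sense = 2L, exonic_antisense = 2L,
  exonic_unknown = 3L, containing = 2L,
  intergenic_convergent = 4L, intergenic_divergent = 4L,
  intergenic_unoriented = 4L, intergenic_distal = 5L)

small_config <- function(seed = 7L, ...) {
  synth_config(seed = seed, n_coding = 20L, n_small_rna = 10L,
               class_counts = small_class_counts,
               n_specific = 6L, n_ubiquitous = 6L, n_coexpr_blocks = 2L,
               slots_per_chrom = 10L, ...)
}

small_fixture <- function() {
  if (is.null(.fixture_cache$small))
    .fixture_cache$small <- synth_generate(small_config())
  .fixture_cache$small
}

# the reference study conditions: ~600 transcripts, seed 42
default_fixture <- function() {
  if (is.null(.fixture_cache$default))
    .fixture_cache$default <- synth_generate(synth_config(seed = 42L))
  .fixture_cache$default
}

pipeline_inputs <- function(fx)
  fx[c("collection", "genes", "nr_hits", "ncrna_hits", "lncdb_hits",
       "scores", "counts")]

result_base_ids <- function(res)
  sort(base_id(vapply(res$lncrnas, function(t) t$id, character(1))))

planted_lnc_ids <- function(fx) sort(fx$truth$id[fx$truth$role == "lncRNA"])

# one-exon transcript with an explicit sequence, for filter unit tests
seq_tx <- function(id, seq, strand = "+", chrom = "c1", start = 0L,
                   source = NA_character_) {
  transcript_model(id, chrom, strand,
                   data.frame(start = start, end = start + nchar(seq)),
                   source = source, sequence = seq)
}

# a two-exon plus-strand gene model: exons [1000,1200) and [1800,2000)
toy_gene <- function(id = "G1", chrom = "c1", strand = "+",
                     exons = data.frame(start = c(1000L, 1800L),
                                        end = c(1200L, 2000L))) {
  tx <- transcript_model(paste0(id, "_t"), chrom, strand, exons,
                         gene_id = id)
  as_gene_models(list(tx))[[1L]]
}
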