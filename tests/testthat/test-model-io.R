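test_that("transcript model validates and normalizes its exons", {
  tx <- transcript_model("t1", "c1", "+",
                         data.frame(start = c(300L, 99L),
                                    end = c(400L, 200L)))
  expect_equal(tx$exons$start, c(99L, 300L))
  expect_equal(tx_length(tx), 201L)
  # length is invariant under exon input order
  tx2 <- transcript_model("t1", "c1", "+",
                          data.frame(start = c(99L, 300L),
                                     end = c(200L, 400L)))
  expect_equal(tx_length(tx), tx_length(tx2))
  expect_error(transcript_model("t", "c1", "+",
                                data.frame(start = 10L, end = 10L)),
               "invalid exon")
  expect_error(transcript_model("t", "c1", "+",
                                data.frame(start = c(0L, 50L),
                                           end = c(100L, 150L))),
               "overlap")
  expect_error(transcript_model("t", "", "+",
                                data.frame(start = 0L, end = 10L)),
               "chrom")
  expect_error(transcript_model("t", "c1", "+",
                                data.frame(start = 0L, end = 10L),
                                sequence = "ACGT"),
               "sequence length")
})

test_that("GTF coordinates convert between 1-based file and 0-based model", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tx\texon\t100\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'c1\tx\texon\t301\t400\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'),
    path)
  txs <- read_gtf(path)
  expect_length(txs, 1L)
  expect_equal(txs[[1L]]$exons,
               data.frame(start = c(99L, 300L), end = c(200L, 400L)))
  expect_equal(tx_length(txs[[1L]]), 201L)  # 101 nt + 100 nt

  # single 1-exon transcript [0,200) writes as 1..200; unknown strand as "."
  out <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(list(transcript_model("t2", "c1", "*",
                                  data.frame(start = 0L, end = 200L))), out)
  line <- readLines(out)
  expect_length(line, 1L)
  fields <- strsplit(line, "\t")[[1L]]
  expect_equal(fields[4:5], c("1", "200"))
  expect_equal(fields[7], ".")
})

test_that("GTF read/write round-trips randomized transcripts", {
  withr::local_seed(11)
  txs <- random_transcripts(100)
  # unique ids required for grouping
  for (i in seq_along(txs)) txs[[i]]$id <- sprintf("tx%03d", i)
  path <- withr::local_tempfile(fileext = ".gtf")
  write_gtf(txs, path)
  back <- read_gtf(path)
  key <- function(ts) lapply(ts[order(vapply(ts, `[[`, "", "id"))],
                             function(t) t[c("id", "chrom", "strand", "exons")])
  expect_equal(key(back), key(txs))
})

test_that("GTF errors name the offending line and reject mixed chromosomes", {
  path <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c('c1\tx\texon\t1\t100\t.\t+\t.\ttranscript_id "t1";',
               'c1\tx\texon\tbad'), path)
  expect_error(read_gtf(path), "line 2")
  writeLines(c('c1\tx\texon\t1\t100\t.\t+\t.\ttranscript_id "t1";',
               'c2\tx\texon\t1\t100\t.\t+\t.\ttranscript_id "t1";'), path)
  expect_error(read_gtf(path), "multiple chromosomes")
  writeLines(character(0), path)
  expect_equal(read_gtf(path), list())
})

test_that("FASTA round-trips, uppercases and rejects duplicates", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(s1 = "acgt"), path)
  expect_equal(read_fasta(path), c(s1 = "ACGT"))

  withr::local_seed(5)
  recs <- setNames(vapply(1:50, function(i) random_dna(sample(10:300, 1L)),
                          character(1)),
                   sprintf("rec%02d", 1:50))
  write_fasta(recs, path)
  expect_equal(read_fasta(path), recs)

  writeLines(c(">a", "ACGT", ">a", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate")
  writeLines(c(">a", "ACGT", ">b", ""), path)
  expect_error(read_fasta(path), "empty sequence")
})

test_that("spliced_sequence concatenates exons and honors strand", {
  genome <- c(c1 = "ACGTAA", c2 = "AACGGTTT")
  plus <- transcript_model("p", "c1", "+", data.frame(start = 0L, end = 4L))
  expect_equal(spliced_sequence(plus, genome), "ACGT")
  # palindromic case: revcomp("ACGT") == "ACGT"
  minus <- transcript_model("m", "c1", "-", data.frame(start = 0L, end = 4L))
  expect_equal(spliced_sequence(minus, genome), "ACGT")
  # hand-computed: revcomp("AAC") = "GTT"
  minus2 <- transcript_model("m2", "c2", "-", data.frame(start = 0L, end = 3L))
  expect_equal(spliced_sequence(minus2, genome), "GTT")
  # multi-exon: exons concatenated in genomic order before reverse-complement
  multi <- transcript_model("mm", "c2", "-",
                            data.frame(start = c(0L, 5L), end = c(3L, 8L)))
  expect_equal(spliced_sequence(multi, genome), revcomp("AACTTT"))
  expect_equal(nchar(spliced_sequence(multi, genome)), tx_length(multi))
  out_of_bounds <- transcript_model("ob", "c1",
                                    "+", data.frame(start = 2L, end = 10L))
  expect_error(spliced_sequence(out_of_bounds, genome), "beyond end")
  wrong_chrom <- transcript_model("wc", "c9", "+",
                                  data.frame(start = 0L, end = 2L))
  expect_error(spliced_sequence(wrong_chrom, genome), "not in genome")
})

test_that("hit tables parse scientific E-values and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-05\t180.3", path)
  hits <- read_hit_table(path)
  expect_equal(hits$evalue, 1e-5)
  expect_equal(hits$percent_identity, 98.5)

  writeLines(character(0), path)
  expect_equal(nrow(read_hit_table(path)), 0L)

  withr::local_seed(13)
  big <- do.call(rbind, lapply(1:1000, function(i) data.frame(
    query_id = sprintf("q%04d", i), subject_id = sprintf("s%04d", i),
    percent_identity = round(runif(1, 0, 100), 1),
    alignment_length = sample(20:500, 1L), mismatches = sample(0:20, 1L),
    gap_opens = sample(0:3, 1L), query_start = 1L,
    query_end = sample(20:500, 1L), subject_start = 1L,
    subject_end = sample(20:500, 1L),
    evalue = 10 ^ runif(1, -50, 0), bit_score = round(runif(1, 30, 900), 1))))
  write_hit_table(big, path)
  back <- read_hit_table(path)
  expect_equal(back$query_id, big$query_id)
  expect_equal(back$evalue / big$evalue, rep(1, 1000), tolerance = 0.01)

  writeLines("q1\ts1\t98.5\t100", path)
  expect_error(read_hit_table(path), "12 columns")
  writeLines("q1\ts1\t98.5\t100\t1\t0\t1\t100\t1\t100\t1e-05\t180.3\textra",
             path)
  expect_warning(read_hit_table(path), "ignored")
})

test_that("BED6 export uses 0-based half-open coordinates", {
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed6(list(transcript_model("t1", "c1", "*",
                                   data.frame(start = 10L, end = 50L))), path)
  expect_equal(readLines(path), "c1\t10\t50\tt1\t0\t.")
})

test_that("dataset tagging qualifies ids reversibly", {
  tx <- transcript_model("t1", "c1", "+", data.frame(start = 0L, end = 10L))
  tagged <- tag_dataset(tx, "ds1")
  expect_equal(tagged$id, "t1__ds1")
  expect_equal(tagged$source, "ds1")
  expect_equal(base_id(tagged$id), "t1")
  # idempotent: a tagged id is not tagged twice
  expect_equal(tag_dataset(tagged, "ds2")$id, "t1__ds1")
})
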