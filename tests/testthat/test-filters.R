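make_len_tx <- function(len, id = paste0("t", len)) {
  transcript_model(id, "c1", "+", data.frame(start = 0L, end = len))
}

test_that("minimum-length removal is strictly below the cutoff", {
  res <- filter_min_length(list(make_len_tx(199L), make_len_tx(200L),
                                make_len_tx(201L)), 200L)
  expect_equal(vapply(res$removed, tx_length, integer(1)), 199L)
  expect_setequal(vapply(res$kept, tx_length, integer(1)), c(200L, 201L))
  empty <- filter_min_length(list(), 200L)
  expect_length(empty$kept, 0L)
  expect_length(empty$removed, 0L)
})

test_that("ORF filter applies strict aa and fraction thresholds per regime", {
  # aa 84, fraction 255/900 = 0.283: traditional keeps, stringent removes
  t84 <- seq_tx("t84", orf_sequence(84L, 900L))
  # aa 50, fraction 153/380 = 0.403 > 0.35: stringent removes on fraction
  t50 <- seq_tx("t50", orf_sequence(50L, 380L))
  # aa 100 is kept by traditional (strict >); aa 101 removed
  t100 <- seq_tx("t100", orf_sequence(100L, 1200L))
  t101 <- seq_tx("t101", orf_sequence(101L, 1200L))
  # aa 83, fraction 252/900 = 0.28: boundary kept by stringent
  t83 <- seq_tx("t83", orf_sequence(83L, 900L))

  trad <- filter_orf(list(t84, t50, t100, t101, t83),
                     filter_config("traditional"))
  expect_setequal(vapply(trad$kept, `[[`, "", "id"),
                  c("t84", "t50", "t100", "t83"))
  expect_equal(vapply(trad$removed, `[[`, "", "id"), "t101")

  strict <- filter_orf(list(t84, t50, t100, t101, t83),
                       filter_config("stringent"))
  expect_setequal(vapply(strict$removed, `[[`, "", "id"),
                  c("t84", "t50", "t100", "t101"))
  expect_equal(vapply(strict$kept, `[[`, "", "id"), "t83")
  expect_error(filter_orf(list(make_len_tx(300L))), "sequence required")
})

test_that("homology removal is inclusive at the E-value cutoff", {
  txs <- lapply(c("a", "b", "c", "d"), function(id) make_len_tx(300L, id))
  hits <- data.frame(query_id = c("a", "b", "c"),
                     subject_id = "s", percent_identity = 90,
                     alignment_length = 100L, mismatches = 0L, gap_opens = 0L,
                     query_start = 1L, query_end = 100L, subject_start = 1L,
                     subject_end = 100L, evalue = c(1e-5, 1e-3, 1e-4),
                     bit_score = 100)
  res <- filter_by_homology(txs, hits, 1e-4)
  expect_setequal(vapply(res$removed, `[[`, "", "id"), c("a", "c"))
  expect_setequal(vapply(res$kept, `[[`, "", "id"), c("b", "d"))
  expect_warning(
    filter_by_homology(txs[1:2], hits, 1e-4),
    "match no transcript")
})

test_that("coding-score filter keeps strictly-below-cutoff and missing ids", {
  txs <- lapply(c("a", "b", "c", "d"), function(id) make_len_tx(300L, id))
  scores <- c(a = -0.3, b = -0.7, c = -1.2)
  at05 <- filter_by_coding_score(txs, scores, -0.5)
  expect_setequal(vapply(at05$removed, `[[`, "", "id"), "a")
  expect_message(filter_by_coding_score(txs, scores, -0.5), "without a coding score")
  at10 <- suppressMessages(filter_by_coding_score(txs, scores, -1.0))
  expect_setequal(vapply(at10$removed, `[[`, "", "id"), c("a", "b"))
  expect_setequal(vapply(at10$kept, `[[`, "", "id"), c("c", "d"))
  # exact-cutoff score is removed ("strictly below" keeps)
  at_eq <- filter_by_coding_score(txs[1:3], c(a = -0.5, b = -0.6, c = -2),
                                  -0.5)
  expect_true("a" %in% vapply(at_eq$removed, `[[`, "", "id"))
})

test_that("known-lncRNA annotation flags without removing", {
  txs <- lapply(c("a", "b"), function(id) make_len_tx(300L, id))
  hits <- data.frame(query_id = c("a", "a", "b"), subject_id = c("k1", "k2", "k3"),
                     percent_identity = 90, alignment_length = 100L,
                     mismatches = 0L, gap_opens = 0L, query_start = 1L,
                     query_end = 100L, subject_start = 1L, subject_end = 100L,
                     evalue = c(1e-6, 1e-8, 1e-2), bit_score = 100)
  ann <- annotate_known_lncrnas(txs, hits, 1e-4)
  expect_setequal(ann$a, c("k1", "k2"))
  expect_length(ann$b, 0L)
  expect_equal(sum(lengths(ann) > 0L), 1L)
})

test_that("cascade conserves counts, ignores input order, nests regimes", {
  fx <- small_fixture()
  d1 <- fx$collection$datasets[[1L]]
  ids <- vapply(d1, `[[`, "", "id")
  nr <- fx$nr_hits[fx$nr_hits$query_id %in% ids, ]
  nc <- fx$ncrna_hits[fx$ncrna_hits$query_id %in% ids, ]

  res <- suppressMessages(run_cascade(d1, nr, nc, fx$scores,
                                      filter_config("traditional")))
  expect_silent(validate_stage_report(res$report))
  expect_equal(res$report$n_in[1L], length(d1))
  expect_equal(res$report$n_out[nrow(res$report)], length(res$lncrnas))
  expect_equal(res$report$n_in[1L] - sum(res$report$n_removed),
               length(res$lncrnas))

  # order invariance: the output is a pure function of the input set
  withr::local_seed(3)
  shuffled <- suppressMessages(run_cascade(sample(d1), nr, nc, fx$scores,
                                           filter_config("traditional")))
  expect_equal(vapply(shuffled$lncrnas, `[[`, "", "id"),
               vapply(res$lncrnas, `[[`, "", "id"))

  # stringent output is a subset of traditional output
  strict <- suppressMessages(run_cascade(d1, nr, nc, fx$scores,
                                         filter_config("stringent")))
  expect_true(all(vapply(strict$lncrnas, `[[`, "", "id") %in%
                    vapply(res$lncrnas, `[[`, "", "id")))

  # all-pass input reports zero removals everywhere
  clean <- lapply(1:5, function(i)
    seq_tx(sprintf("ok%d", i), orf_sequence(20L, 500L)))
  empty_hits <- fx$nr_hits[0L, ]
  allpass <- run_cascade(clean, empty_hits, empty_hits,
                         setNames(rep(-2, 5), sprintf("ok%d", 1:5)))
  expect_true(all(allpass$report$n_removed == 0L))
  expect_length(allpass$lncrnas, 5L)
})

test_that("stage report validation catches broken arithmetic", {
  bad <- data.frame(stage = c("a", "b"), n_in = c(10L, 8L),
                    n_removed = c(2L, 1L), n_out = c(8L, 6L))
  expect_error(validate_stage_report(bad), "n_removed")
  unchained <- data.frame(stage = c("a", "b"), n_in = c(10L, 7L),
                          n_removed = c(2L, 1L), n_out = c(8L, 6L))
  expect_error(validate_stage_report(unchained), "chain")
})

test_that("the stringent preset dominates the traditional preset", {
  trad <- filter_config("traditional")
  strict <- filter_config("stringent")
  expect_lt(strict$max_orf_aa, trad$max_orf_aa)
  expect_lt(strict$coding_score_cutoff, trad$coding_score_cutoff)
  expect_false(is.na(strict$max_orf_fraction))
  expect_true(is.na(trad$max_orf_fraction))
})
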