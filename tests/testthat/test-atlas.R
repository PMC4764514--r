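mat_of <- function(values, ids = NULL) {
  m <- if (is.matrix(values)) values else matrix(values, nrow = 1L)
  rownames(m) <- if (!is.null(ids)) ids
                 else rownames(m) %||% sprintf("t%d", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- sprintf("tis%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("RPKM follows the unit formula and its invariances", {
  cm <- count_matrix(
    matrix(c(1000L, 0L, 250L, 0L), nrow = 2L, byrow = TRUE,
           dimnames = list(c("a", "b"), c("t1", "t2"))),
    lengths = c(a = 1000, b = 500),
    totals = c(t1 = 1e6, t2 = 5e7))
  r <- rpkm(cm)
  expect_equal(r["a", "t1"], 1000)       # unit case
  expect_equal(r["a", "t2"], 0)          # zero count
  expect_equal(r["b", "t1"], 500)
  # count 250, length 500, total 5e7 -> 250 / (0.5 * 50) = 10
  cm2 <- count_matrix(matrix(250L, dimnames = list("b", "t2")),
                      c(b = 500), c(t2 = 5e7))
  expect_equal(rpkm(cm2)["b", "t2"], 10)

  # doubling the count doubles RPKM; scaling count and total together
  # leaves it unchanged
  cm3 <- count_matrix(matrix(2000L, dimnames = list("a", "t1")),
                      c(a = 1000), c(t1 = 1e6))
  expect_equal(rpkm(cm3)["a", "t1"], 2 * r["a", "t1"])
  cm4 <- count_matrix(matrix(3000L, dimnames = list("a", "t1")),
                      c(a = 1000), c(t1 = 3e6))
  expect_equal(rpkm(cm4)["a", "t1"], r["a", "t1"])

  expect_error(count_matrix(matrix(10L, dimnames = list("a", "t1")),
                            c(a = 0), c(t1 = 1e6)), "positive")
  bad <- count_matrix(matrix(0L, dimnames = list("a", "t1")),
                      c(a = 100), c(t1 = 1e6))
  bad$totals["t1"] <- 0
  expect_error(rpkm(bad), "zero library total")
})

test_that("mean scaling equalizes column means", {
  m <- mat_of(matrix(c(1, 3, 2, 6), nrow = 2L))  # column means 2 and 4
  norm <- normalize_mean_scaling(m)
  expect_equal(unname(colMeans(norm)), c(3, 3))

  eq <- mat_of(matrix(c(1, 3, 3, 1), nrow = 2L))  # equal means: identity
  expect_equal(normalize_mean_scaling(eq), eq)

  withr::local_seed(61)
  for (i in 1:20) {
    r <- mat_of(matrix(runif(60, 0.1, 50), nrow = 6L))
    cms <- colMeans(normalize_mean_scaling(r))
    expect_equal(max(cms) - min(cms), 0, tolerance = 1e-12)
  }
  withzero <- mat_of(matrix(c(1, 3, 0, 0), nrow = 2L))
  expect_warning(norm0 <- normalize_mean_scaling(withzero), "all-zero")
  expect_equal(norm0[, 2L], withzero[, 2L])
})

test_that("tissue-specific calls apply inclusive fold and minimum RPKM", {
  # 4.0 = 8 x 0.5: "8-fold or higher" is inclusive
  m <- mat_of(c(4.0, 0.5, 0.4))
  expect_equal(unname(call_tissue_specific(m)), "tis1")
  # 4.0 < 8 x 0.6: not specific
  expect_true(is.na(call_tissue_specific(mat_of(c(4.0, 0.6, 0.1)))))
  # below the 0.5 RPKM floor despite a large fold
  expect_true(is.na(call_tissue_specific(mat_of(c(0.4, 0.04, 0.01)))))
  # a flat profile is never specific
  expect_true(is.na(call_tissue_specific(mat_of(rep(2, 13)))))
})

test_that("ubiquitous calls use an inclusive per-tissue floor", {
  expect_true(call_ubiquitous(mat_of(rep(1.0, 13))))
  expect_false(call_ubiquitous(mat_of(c(rep(1.0, 12), 0.99))))
})

test_that("specific and ubiquitous calls are mutually exclusive", {
  withr::local_seed(67)
  m <- mat_of(matrix(rexp(13 * 300, rate = 0.5), ncol = 13L))
  spec <- call_tissue_specific(m)
  ubiq <- call_ubiquitous(m)
  expect_false(any(!is.na(spec) & ubiq))
})

test_that("complexity curves are monotone, exact and end at 1", {
  one <- mat_of(c(5, 0, 0), ids = "a")
  m <- rbind(one, mat_of(c(0, 0, 0), ids = "b"))
  expect_equal(complexity_curve(m, "tis1"), c(1, 1))

  unif <- mat_of(matrix(rep(2, 10), ncol = 1L))
  colnames(unif) <- "t"
  expect_equal(complexity_curve(unif, "t"), (1:10) / 10)

  withr::local_seed(71)
  r <- mat_of(matrix(rexp(40), ncol = 1L)); colnames(r) <- "t"
  curve <- complexity_curve(r, "t")
  x <- sort(unname(r[, "t"]), decreasing = TRUE)
  expect_equal(curve, cumsum(x) / sum(x))
  expect_true(all(diff(curve) >= 0))
  expect_equal(curve[length(curve)], 1)

  zero <- mat_of(matrix(0, nrow = 2L, ncol = 1L)); colnames(zero) <- "t"
  expect_error(complexity_curve(zero, "t"), "no expression")
})

test_that("expression entropy has its closed forms and scale invariance", {
  expect_equal(expression_entropy(rep(1, 13)), log2(13))
  expect_equal(expression_entropy(c(5, 0, 0, 0)), 0)
  withr::local_seed(73)
  for (i in 1:20) {
    p <- rexp(13)
    expect_equal(expression_entropy(p * runif(1, 0.01, 100)),
                 expression_entropy(p))
  }
  expect_error(expression_entropy(rep(0, 13)), "all-zero")
  expect_error(expression_entropy(c(-1, 2)), "negative")
})

test_that("correlation clustering honors the threshold and retention rule", {
  withr::local_seed(79)
  base <- runif(13, 1, 50)
  # two identical profiles always co-cluster
  m <- mat_of(rbind(base, base * 2), ids = c("a", "b"))
  colnames(m) <- sprintf("tis%d", 1:13)
  cl <- cluster_correlated(m)
  expect_length(cl$clusters, 1L)
  expect_setequal(cl$clusters[[1L]]$id, c("a", "b"))

  # weakly correlated profiles stay apart
  x <- runif(13); y <- 0.5 * x + sqrt(1 - 0.25) * runif(13)
  m2 <- mat_of(rbind(x, y), ids = c("a", "b"))
  expect_length(cluster_correlated(m2)$clusters, 0L)

  # a 10-member cluster retains ceiling(0.2 * 10) = 2 members
  mm <- mat_of(do.call(rbind, lapply(1:10, function(i) base * i)),
               ids = sprintf("m%02d", 1:10))
  cl10 <- cluster_correlated(mm)
  expect_length(cl10$clusters, 1L)
  expect_equal(sum(cl10$clusters[[1L]]$retained), 2L)
  # retained members have the highest entropies
  df <- cl10$clusters[[1L]]
  expect_true(min(df$entropy[df$retained]) >= max(df$entropy[!df$retained]))

  # zero-variance rows are excluded with a message
  flat <- mat_of(rbind(base, rep(3, 13)), ids = c("a", "flat"))
  expect_message(clf <- cluster_correlated(flat), "zero-variance")
  expect_equal(clf$n_excluded, 1L)
})

test_that("every reported cluster satisfies the correlation contract", {
  withr::local_seed(83)
  m <- matrix(rlnorm(13 * 80, log(5), 1), ncol = 13L,
              dimnames = list(sprintf("g%02d", 1:80), sprintf("t%d", 1:13)))
  # add a few strongly correlated blocks
  for (b in 0:3) {
    shape <- rlnorm(13, log(20), 0.5)
    for (k in 1:4) m[b * 4 + k, ] <- shape * runif(1, 0.5, 2)
  }
  cl <- cluster_correlated(m, min_corr = 0.97)
  expect_gt(length(cl$clusters), 0L)
  for (cluster in cl$clusters) {
    sub <- cor(t(m[cluster$id, ]))
    expect_gte(mean(sub[upper.tri(sub)]), 0.97)
  }
})

test_that("planted co-expression blocks are recovered from expected RPKM", {
  fx <- small_fixture()
  truth <- fx$truth
  blocks <- split(truth$id[!is.na(truth$coexpr_block)],
                  truth$coexpr_block[!is.na(truth$coexpr_block)])
  expect_gt(length(blocks), 0L)
  cl <- suppressMessages(
    cluster_correlated(fx$expected_rpkm, min_corr = 0.97))
  assignment <- setNames(
    rep(seq_along(cl$clusters), vapply(cl$clusters, nrow, integer(1))),
    unlist(lapply(cl$clusters, `[[`, "id")))
  for (b in names(blocks)) {
    members <- blocks[[b]]
    expect_length(unique(assignment[members]), 1L)
    # blocks mix coding and lncRNA ids: a co-expression cluster
    roles <- truth$role[match(members, truth$id)]
    expect_setequal(unique(roles), c("coding", "lncRNA"))
  }
})
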