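test_that("cosine similarity evaluates the standard formula", {
  expect_equal(cosine_similarity(c(3, 1, 2), c(3, 1, 2)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 2)), 0)
  expect_equal(cosine_similarity(c(1, 2, 2), c(2, 1, 2)), 8 / 9)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("stage relevance compares count and document-length vectors", {
  v <- stage_vocabulary(c("alpha beta beta gamma delta",
                          "beta gamma gamma epsilon delta"), stage_id = 1)
  # single-document stage: any present stem has relevance 1
  v1 <- stage_vocabulary("alpha beta beta", stage_id = 1)
  expect_equal(stage_relevance("alpha", v1), 1)
  # counts proportional to document totals -> collinear -> 1
  expect_equal(stage_relevance("delta", v), 1)    # counts (1,1), totals (5,5)
  # counts (1,0) against totals (5,5) -> 1/sqrt(2)
  expect_equal(stage_relevance("alpha", v), 1 / sqrt(2))
  # absent stem -> 0 by convention
  expect_equal(stage_relevance("zeta", v), 0)
})

test_that("n_keywords = 1 returns the single most relevant stem", {
  v <- stage_vocabulary(c("alpha alpha beta", "alpha gamma gamma"),
                        stage_id = 1)
  rels <- vapply(v$stems, stage_relevance, numeric(1), vocab = v)
  expect_identical(mrmr_select(v, 1), names(which.max(rels)))
  expect_error(mrmr_select(v, 0), ">= 1")
})

test_that("greedy selection equals the brute-force oracle on many random vocabularies", {
  for (seed in 1:100) {
    set.seed(seed)
    n_stems <- sample(4:15, 1)
    m <- sample(2:6, 1)
    stems <- sort(sapply(seq_len(n_stems), function(i)
      paste(sample(letters, 6, replace = TRUE), collapse = "")))
    counts <- matrix(rpois(n_stems * m, 1.2), n_stems, m,
                     dimnames = list(stems, NULL))
    counts[cbind(seq_len(n_stems), sample(m, n_stems, replace = TRUE))] <-
      counts[cbind(seq_len(n_stems), sample(m, n_stems, replace = TRUE))] + 1L
    keep <- rowSums(counts) > 0
    counts <- counts[keep, , drop = FALSE]
    if (nrow(counts) < 2) next
    doc_totals <- colSums(counts) + rpois(m, 2)
    vocab <- structure(list(stage_id = 1L, stems = rownames(counts),
                            counts = counts, doc_totals = doc_totals),
                       class = "stage_vocabulary")
    k <- sample(seq_len(nrow(counts)), 1)
    sel <- mrmr_select(vocab, k)
    expect_length(sel, min(k, nrow(counts)))
    expect_greedy_optimal(sel, counts, doc_totals)
  }
})

test_that("a duplicated count vector is penalized by redundancy 1", {
  counts <- rbind(aa = c(3L, 0L), bb = c(3L, 0L), cc = c(1L, 1L))
  vocab <- structure(list(stage_id = 1L, stems = rownames(counts),
                          counts = counts, doc_totals = c(5L, 1L)),
                     class = "stage_vocabulary")
  sel <- mrmr_select(vocab, 2)
  # aa wins step 1 (lexicographic over identical bb); bb then scores
  # rel - 1 < rel(cc) - cos(cc, aa), so cc is picked despite lower relevance
  expect_identical(sel, c("aa", "cc"))
})

test_that("keyword labels mark exactly the uniquely selected stems", {
  kw <- build_keyword_labels(list(c("alpha", "shared"), c("beta", "shared"),
                                  c("gamma")))
  expect_identical(kw$keywords, c("alpha", "shared", "beta", "gamma"))
  expect_identical(unname(kw$unique_stage["shared"]), NA_integer_)
  expect_identical(unname(kw$unique_stage[c("alpha", "beta", "gamma")]),
                   c(1L, 2L, 3L))
  expect_identical(kw$provenance$shared, c(1L, 2L))

  disjoint <- build_keyword_labels(list("alpha", "beta", "gamma"))
  expect_true(all(!is.na(disjoint$unique_stage)))
})

test_that("selection respects budget and the Eq-objective bounds", {
  d <- tiny_descriptions()
  kw <- select_keywords(d, n_keywords = 8)
  expect_lte(length(kw$keywords), 8L)
  expect_true(all(lengths(kw$selections) == 2L))
  # per-stage selections never exceed the stage vocabulary
  for (s in 1:4) {
    v <- stage_vocabulary(d$sentences[[s]], s)
    expect_lte(length(kw$selections[[s]]), length(v$stems))
    rels <- vapply(v$stems, stage_relevance, numeric(1), vocab = v)
    expect_true(all(rels >= 0 & rels <= 1))
  }
})

test_that("keyword sets round trip through disk", {
  kw <- build_keyword_labels(list(c("alpha", "shared"), c("beta", "shared")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_keyword_set(kw, path)
  back <- read_keyword_set(path)
  expect_identical(back$keywords, kw$keywords)
  expect_identical(back$unique_stage, kw$unique_stage)
  expect_identical(back$provenance, kw$provenance)
})
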