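test_that("positional encoding assigns L - i + 1 and accumulates repeats", {
  expect_equal(positional_encoding(c("adenine", "aminase")),
               c(adenine = 2, aminase = 1))
  expect_equal(positional_encoding("solo"), c(solo = 1))
  enc <- positional_encoding(c("a", "b", "a"))
  expect_equal(enc[["a"]], 4)  # 3 + 1
  expect_equal(enc[["b"]], 2)
  expect_equal(sum(enc), 6)    # L(L+1)/2
})

test_that("index rows hold permutation values and complete inverted lists", {
  bp <- mk_profiles(list("X:1" = "adenine aminase activity",
                         "X:2" = c("cella", "photoreceptor cella")))
  idx <- build_index(bp$profiles)
  expect_length(idx$rows, 3L)
  r1 <- idx$rows[[1L]]
  expect_setequal(unname(r1$enc), 1:3)
  expect_equal(r1$value_sum, 6)
  # every row reachable from each of its tokens
  for (i in seq_along(idx$rows)) {
    for (t in idx$rows[[i]]$tokens) {
      expect_true(i %in% get(t, envir = idx$inverted))
    }
  }
  # two concepts sharing a token sequence both keep their rows
  bp2 <- mk_profiles(list("Y:1" = "cella", "Y:2" = "cella"))
  idx2 <- build_index(bp2$profiles)
  expect_length(idx2$rows, 2L)
  expect_length(get("cella", envir = idx2$inverted), 2L)
})

test_that("variants add rows for their concepts", {
  bp <- mk_profiles(list("X:1" = "adenine aminase activity"))
  vs <- data.table::data.table(concept_id = "X:1",
                               source = "adenine aminase activity",
                               variant = "adenine aminase",
                               rule = "MULTI_TOKEN_DROP")
  idx <- build_index(bp$profiles, variants = vs)
  expect_length(idx$rows, 2L)
  expect_equal(idx$rows[[2L]]$c_n, 2L)
  expect_equal(idx$rows[[2L]]$concept_id, "X:1")
})

test_that("score_query evaluates the ranking function", {
  bp <- mk_profiles(list("X:1" = "alpha beta"))
  row <- build_index(bp$profiles)$rows[[1L]]
  # self query scores exactly 1
  expect_identical(score_query(c("alpha", "beta"), row), 1)
  # out-of-vocabulary query scores 0
  expect_equal(score_query(c("zzz", "qqq"), row), 0)
  # row [alpha(2), beta(1)], query [alpha]: (1/1) * (2/3)
  expect_equal(score_query("alpha", row), 2 / 3)
  # one known + one unknown token: (1/2) * (2/3)
  expect_equal(score_query(c("alpha", "qqq"), row), 1 / 3)
})

test_that("self-retrieval holds for every indexed representation", {
  onto <- make_ontology(fixture_spec(seed = 11, n_concepts = 100))
  bp <- build_profiles(onto$concepts)
  idx <- build_index(bp$profiles)
  for (r in idx$rows) expect_identical(score_query(r$tokens, r), 1)
})

test_that("score-1 agrees with a multiset-equality oracle under fuzzing", {
  set.seed(4242)
  vocab <- sprintf("tok%02d", 1:12)
  trials <- 2000L
  hits <- 0L
  for (i in seq_len(trials)) {
    row_toks <- sample(vocab, sample(1:5, 1L))  # distinct row tokens
    enc <- positional_encoding(row_toks)
    row <- list(concept_id = "F:1", tokens = row_toks, enc = enc,
                c_n = length(row_toks), value_sum = sum(enc))
    # queries biased towards near-misses: permutations, subsets, repeats
    q <- switch(sample(4L, 1L),
                sample(row_toks),
                sample(vocab, sample(1:5, 1L), replace = TRUE),
                c(row_toks, sample(vocab, 1L)),
                if (length(row_toks) > 1L) row_toks[-1L] else row_toks)
    got <- score_query(q, row) == 1 && length(q) == row$c_n
    want <- identical(sort(q), sort(row_toks))   # multiset equality
    expect_identical(got, want)
    if (want) hits <- hits + 1L
  }
  expect_gt(hits, 100L)  # the fuzz actually exercises the positive branch
})

test_that("sentence splitting respects abbreviations and offsets", {
  s <- split_sentences("First one. Second, e.g. still second. Third!")
  expect_equal(nrow(s), 3L)
  txt <- "Alpha beta. Gamma?"
  s2 <- split_sentences(txt)
  # the boundary consumes the separating whitespace
  expect_equal(substring(txt, s2$start[2L] + 1L, s2$end[2L]), "Gamma?")
})

test_that("candidate generation windows and spans behave", {
  # 3-token sentence, max_len 2 -> 3 unigrams + 2 bigrams
  cands <- generate_candidates("alpha beta gamma", 2L)
  expect_length(cands, 5L)
  # spans cover only surviving tokens: "the cella" -> span of "cella"
  cands2 <- generate_candidates("see the cella here", 1L)
  txts <- vapply(cands2, function(cd)
    substring("see the cella here", cd$start + 1L, cd$end), "")
  expect_true("cella" %in% txts)
  expect_false(any(grepl("^the", txts)))
  # candidates never cross sentence boundaries
  cands3 <- generate_candidates("alpha beta. gamma delta", 4L)
  for (cd in cands3) {
    expect_false(grepl("\\.", substring("alpha beta. gamma delta",
                                        cd$start + 1L, cd$end)))
  }
})

test_that("annotate finds exact, nested and overlapping matches", {
  bp <- mk_profiles(list("C:0" = "cella", "C:1" = "epithelial cella"))
  idx <- build_index(bp$profiles)
  doc <- c(d1 = "We observed epithelial cellas in the sample.")
  ann <- annotate(doc, idx)
  # find-all behaviour: both the nested and the enclosing concept
  expect_setequal(ann$concept_id, c("C:0", "C:1"))
  long <- ann[ann$concept_id == "C:1", ]
  expect_equal(long$text, "epithelial cellas")
  short <- ann[ann$concept_id == "C:0", ]
  expect_equal(short$text, "cellas")
  # spans nest
  expect_gte(short$start, long$start)
  expect_lte(short$end, long$end)
})

test_that("case-sensitive index separates acronym homographs", {
  bp_cs <- mk_profiles(list("PR:000013884" = c("advanced glycation product",
                                               "AGE")),
                       case_sensitive = TRUE)
  idx_cs <- build_index(bp_cs$profiles, case_sensitive = TRUE)
  expect_equal(nrow(annotate(c(d = "their age increased"), idx_cs)), 0L)
  ann <- annotate(c(d = "the AGE level rose"), idx_cs)
  expect_equal(ann$concept_id, "PR:000013884")
  expect_equal(ann$text, "AGE")
  # the same lexicon indexed case-insensitively annotates the homograph
  bp_ci <- mk_profiles(list("PR:000013884" = c("advanced glycation product",
                                               "AGE")))
  idx_ci <- build_index(bp_ci$profiles, case_sensitive = FALSE)
  expect_equal(nrow(annotate(c(d = "their age increased"), idx_ci)), 1L)
})

test_that("duplicate (span, concept) annotations collapse", {
  bp <- mk_profiles(list("C:1" = c("alpha beta", "alpha beta")))
  idx <- build_index(bp$profiles)
  ann <- annotate(c(d = "alpha beta here"), idx)
  expect_equal(nrow(ann), 1L)
})
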