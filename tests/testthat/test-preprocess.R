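test_that("tokenize lowercases, strips punctuation and removes stopwords", {
  expect_identical(tokenize("The doctor said: TRUST!",
                            stopwords = c("the", "said")),
                   c("doctor", "trust"))
  expect_identical(tokenize(""), character(0))
  expect_identical(tokenize(NA_character_), character(0))
  expect_identical(tokenize("risk, risk; RISK", stopwords = character(0)),
                   c("risk", "risk", "risk"))
  # apostrophes are stripped, not split on
  expect_identical(tokenize("don't worry", stopwords = character(0)),
                   c("dont", "worry"))
})

test_that("tokenization is idempotent on its own output", {
  set.seed(31)
  vocab <- c(random_word_vocab(30), "risk", "family", "doctor")
  for (k in 1:50) {
    toks <- random_tokens(sample(0:25, 1), vocab)
    expect_identical(tokenize(paste(toks, collapse = " "),
                              stopwords = character(0)), toks)
  }
})

test_that("extract_ngrams enumerates sliding windows with counts", {
  p <- extract_ngrams(c("open", "family", "talk"), max_n = 2)
  expect_identical(p[order(names(p))],
                   c("family" = 1L, "family talk" = 1L, "open" = 1L,
                     "open family" = 1L, "talk" = 1L))
  expect_identical(extract_ngrams(character(0), max_n = 3),
                   structure(integer(0), names = character(0)))
  p2 <- extract_ngrams(c("a", "b", "a", "b"), max_n = 2)
  expect_identical(p2[order(names(p2))],
                   c("a" = 2L, "a b" = 2L, "b" = 2L, "b a" = 1L))
  expect_error(extract_ngrams("a", max_n = 4), "max_n")
  expect_error(extract_ngrams("a", max_n = 0), "max_n")
})

test_that("extract_ngrams agrees with brute-force enumeration and conserves counts", {
  set.seed(99)
  vocab <- random_word_vocab(12)
  for (k in 1:500) {
    L <- sample(0:30, 1)
    toks <- random_tokens(L, vocab)
    max_n <- sample(1:3, 1)
    got <- extract_ngrams(toks, max_n)
    expect_identical(got[order(names(got))], oracle_ngram_counts(toks, max_n))
    # count conservation per order
    for (n in seq_len(max_n)) {
      ord <- lengths(strsplit(names(got), " ", fixed = TRUE))
      expect_identical(sum(got[ord == n]), as.integer(max(L - n + 1, 0)))
    }
  }
})

test_that("corpus_statistics implements tf * ln(N/df) with the stated conventions", {
  one <- corpus_statistics(list(d1 = c(a = 2L, b = 1L)))
  expect_true(all(one$stats$tf_idf == 0))  # ln(1/1) = 0
  two <- corpus_statistics(list(d1 = c(a = 3L, b = 1L), d2 = c(b = 2L)))
  a_row <- two$stats[two$stats$term == "a", ]
  expect_equal(a_row$tf_idf, 3 * log(2))
  # term absent from a document has no (doc, term) row at all
  expect_identical(nrow(two$stats[two$stats$doc == "d2" &
                                    two$stats$term == "a", ]), 0L)
  # sign invariant: >= 0, zero exactly when df = N
  expect_true(all(two$stats$tf_idf >= 0))
  expect_true(all((two$stats$tf_idf == 0) == (two$stats$df == 2)))
  expect_error(corpus_statistics(list()), "empty corpus")
  smooth <- corpus_statistics(list(d1 = c(a = 2L), d2 = c(a = 1L)),
                              smooth = TRUE)
  expect_true(all(smooth$stats$tf_idf > 0))
})

test_that("vocabulary_summary counts distinct orders and ranks terms", {
  profs <- list(d1 = c(a = 2L, "a b" = 1L, b = 1L),
                d2 = c(a = 1L, b = 3L, "b c d" = 1L, c = 1L, d = 1L))
  vs <- vocabulary_summary(profs, top_k = 3)
  expect_identical(vs$n_unigrams, 4L)
  expect_identical(vs$n_bigrams, 1L)
  expect_identical(vs$n_trigrams, 1L)
  # b and a tie-break: counts b=4 > a=3
  expect_identical(vs$top_terms$term[1:2], c("b", "a"))
  # ties broken lexicographically
  profs2 <- list(d = c(zz = 2L, aa = 2L, mm = 2L))
  expect_identical(vocabulary_summary(profs2, top_k = 3)$top_terms$term,
                   c("aa", "mm", "zz"))
  # k beyond vocabulary returns everything
  expect_identical(nrow(vocabulary_summary(profs2, top_k = 99)$top_terms), 3L)
  # two documents sharing all terms count once
  shared <- list(d1 = c(x = 1L, y = 2L), d2 = c(x = 4L, y = 1L))
  expect_identical(vocabulary_summary(shared)$n_unigrams, 2L)
})

test_that("narratives JSONL round-trips and rejects malformed input", {
  df <- data.frame(id = c("n1", "n2"), subject_id = c("s1", "s2"),
                   language = c("de", "ko"),
                   text = c("we spoke openly, and often!", ""),
                   stringsAsFactors = FALSE)
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_narratives(df, f)
  expect_identical(read_narratives(f), df)
  writeLines(c('{"id":"a","subject_id":"s","language":"en","text":"x"}',
               '{"id":"a","subject_id":"s2","language":"en","text":"y"}'), f)
  expect_error(read_narratives(f), "duplicate")
  writeLines('{"id":"a","subject_id":"s"}', f)
  expect_error(read_narratives(f), "missing field")
})
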