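test_that("emotion counting matches the defining example", {
  lex <- list(fear = c("fear", "negative"), trust = c("trust", "positive"))
  f <- emotion_features(c("fear", "fear", "trust"), lex)
  expect_equal(f[["fear"]], 2)
  expect_equal(f[["trust"]], 1)
  expect_equal(f[["nrc_pos"]], 1)
  expect_equal(f[["nrc_neg"]], 2)
  expect_equal(f[["net_sentiment"]], -1)
  z <- emotion_features(character(0), lex)
  expect_true(all(z == 0))
})

test_that("net sentiment is exactly positive minus negative", {
  expect_equal(net_sentiment(c(nrc_pos = 7, nrc_neg = 4)), 3)
  expect_equal(net_sentiment(c(nrc_pos = 5, nrc_neg = 5)), 0)
  expect_equal(net_sentiment(c(nrc_pos = 0, nrc_neg = 5)), -5)
})

test_that("emotion features equal an independent recount and are order-invariant", {
  set.seed(55)
  emo <- demo_emotion_lexicon()
  vocab <- c(names(emo), random_word_vocab(20))
  for (k in 1:60) {
    toks <- random_tokens(sample(0:60, 1), vocab)
    got <- emotion_features(toks, emo)
    want <- oracle_emotion_counts(toks, emo)
    cats <- c("anger", "anticipation", "disgust", "fear", "joy",
              "sadness", "surprise", "trust")
    expect_equal(got[cats], want[cats])
    expect_equal(got[["nrc_pos"]], want[["positive"]])
    expect_equal(got[["nrc_neg"]], want[["negative"]])
    expect_equal(got[["net_sentiment"]],
                 want[["positive"]] - want[["negative"]])
    # bag-of-words: shuffling tokens changes nothing
    expect_equal(emotion_features(sample(toks), emo), got)
  }
})

test_that("net sentiment is antisymmetric under swapping positive/negative flags", {
  set.seed(56)
  emo <- demo_emotion_lexicon()
  swapped <- lapply(emo, function(cc) {
    cc[cc == "positive"] <- "POS"; cc[cc == "negative"] <- "positive"
    cc[cc == "POS"] <- "negative"; cc
  })
  vocab <- c(names(emo), random_word_vocab(10))
  for (k in 1:20) {
    toks <- random_tokens(40, vocab)
    expect_equal(emotion_features(toks, emo)[["net_sentiment"]],
                 -emotion_features(toks, swapped)[["net_sentiment"]])
  }
})

test_that("emotion counts are additive over document concatenation", {
  set.seed(57)
  emo <- demo_emotion_lexicon()
  vocab <- c(names(emo), random_word_vocab(10))
  for (k in 1:20) {
    a <- random_tokens(30, vocab); b <- random_tokens(30, vocab)
    expect_equal(emotion_features(c(a, b), emo),
                 emotion_features(a, emo) + emotion_features(b, emo))
  }
})

test_that("valence sums and polarity counts follow their lexicons", {
  val <- c(good = 3L, bad = -2L)
  expect_equal(valence_features(c("good", "good", "bad", "zz"), val),
               c(valence_sum = 4))
  expect_equal(valence_features(character(0), val), c(valence_sum = 0))
  pol <- c(good = "positive", bad = "negative")
  expect_equal(polarity_features(c("good", "bad", "bad"), pol),
               c(polarity_pos = 1, polarity_neg = 2))
})

test_that("sentiment lexicon TSV loaders reproduce the bundled demo lexicons", {
  emo_path <- system.file("extdata", "demo_emotion_lexicon.tsv",
                          package = "famcomm")
  emo <- load_emotion_lexicon(emo_path)
  demo <- demo_emotion_lexicon()
  expect_identical(emo[order(names(emo))], demo[order(names(demo))])
  val <- load_valence_lexicon(system.file("extdata",
                                          "demo_valence_lexicon.tsv",
                                          package = "famcomm"))
  expect_identical(val, demo_valence_lexicon())
  pol <- load_polarity_lexicon(system.file("extdata",
                                           "demo_polarity_lexicon.tsv",
                                           package = "famcomm"))
  expect_identical(pol, demo_polarity_lexicon())
})

test_that("sentiment lexicon loaders validate their ranges", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("word\tscore", "good\t6"), f)
  expect_error(load_valence_lexicon(f), "\\[-5, 5\\]")
  writeLines(c("word\tcategory\tflag", "good\tserenity\t1"), f)
  expect_error(load_emotion_lexicon(f), "unknown emotion")
  writeLines(c("word\tpolarity", "good\tmeh"), f)
  expect_error(load_polarity_lexicon(f), "polarity")
})

test_that("sentiment_features covers a corpus with optional extra lexicons", {
  narr <- data.frame(id = c("n1", "n2"), subject_id = c("s1", "s2"),
                     language = "en",
                     text = c("wonderful reliable visit", "awful scared"),
                     stringsAsFactors = FALSE)
  out <- sentiment_features(narr, demo_emotion_lexicon(),
                            valence_lexicon = demo_valence_lexicon(),
                            polarity_lexicon = demo_polarity_lexicon())
  expect_identical(out$narrative_id, c("n1", "n2"))
  expect_equal(out$trust, c(1, 0))
  expect_equal(out$net_sentiment, c(1, -1))
  expect_equal(out$valence_sum, c(4, -5))
  expect_equal(out$polarity_pos, c(1, 0))
  expect_equal(out$polarity_neg, c(0, 2))
})
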