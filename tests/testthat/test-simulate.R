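test_that("planted lexical signal is recovered exactly by the extractors", {
  co <- simulate_cohort(sim_config(n_subjects = 25, seed = 301))
  sent <- sentiment_features(co$narratives, demo_emotion_lexicon())
  expect_equal(sent$fear, co$truth$fear)
  expect_equal(sent$net_sentiment, co$truth$net_sentiment)
  for (cc in c("anger", "anticipation", "disgust", "joy", "sadness",
               "surprise", "trust")) {
    expect_equal(sent[[cc]], co$truth[[cc]])
  }
  sc <- score_corpus(co$narratives, demo_openness_lexicon())
  expect_identical(sc$scores$openness_score, co$truth$planted_score)
  # phrase quantization keeps the text score within 1.5 of the latent
  expect_lte(max(abs(co$truth$planted_score - co$truth$latent_openness)),
             1.5 + 1e-9)
})

test_that("zero noise and zero slopes give a constant latent openness", {
  cfg <- sim_config(n_subjects = 12, seed = 302, noise_sd = 0,
                    beta = c(single = 0, academic = 0, fear = 0,
                             informational_support = 0,
                             net_sentiment = 0),
                    intercept = 30)
  co <- simulate_cohort(cfg)
  expect_true(all(co$truth$latent_openness == 30))
  expect_true(all(co$truth$pos_units == co$truth$pos_units[1]))
  expect_true(all(co$truth$neg_units == 0L))
})

test_that("with zero noise OLS on extracted features reproduces the truth", {
  cfg <- sim_config(n_subjects = 60, seed = 303, noise_sd = 0)
  co <- simulate_cohort(cfg)
  sent <- sentiment_features(co$narratives, demo_emotion_lexicon())
  sc <- score_corpus(co$narratives, demo_openness_lexicon())
  tab <- assemble_features(co$subjects, sent, sc$scores)
  tab$latent <- co$truth$latent_openness
  m <- lm(latent ~ single + academic + fear + informational_support +
            net_sentiment, data = tab)
  b <- attr(co$truth, "beta")
  est <- coef(m)
  expect_lt(abs(est[["(Intercept)"]] - attr(co$truth, "intercept")) /
              abs(attr(co$truth, "intercept")), 1e-8)
  for (v in names(b)) {
    expect_lt(abs(est[[v]] - b[[v]]) / abs(b[[v]]), 1e-8)
  }
})

test_that("cohort summary statistics converge to the configured targets", {
  co <- simulate_cohort(sim_config(n_subjects = 2000, seed = 304))
  s <- co$subjects; tr <- co$truth
  n <- nrow(s)
  within3se <- function(est, p_or_mean, se) {
    abs(est - p_or_mean) <= 3 * se
  }
  prop_se <- function(p) sqrt(p * (1 - p) / n)
  expect_true(within3se(mean(s$marital_status == "single"), 0.08,
                        prop_se(0.08)))
  expect_true(within3se(mean(s$education == "university_postgraduate"),
                        0.40, prop_se(0.40)))
  expect_true(within3se(mean(s$sex == "female"), 0.89, prop_se(0.89)))
  expect_true(within3se(mean(s$cancer_status == "affected"), 0.60,
                        prop_se(0.60)))
  # age is a clipped Normal(53, 12): clipping barely moves the mean
  expect_lt(abs(mean(s$age) - 53), 1.5)
  # latent openness targets the configured mean, SD near 20
  expect_true(within3se(mean(tr$latent_openness), 29.8,
                        sd(tr$latent_openness) / sqrt(n)))
  expect_lt(abs(sd(tr$latent_openness) - 20), 3)
  # simulated external inventory correlates as configured
  r <- external_correlation(tr$latent_openness, s$iri_total)$r
  expect_lt(abs(r - 0.46), 3 / sqrt(n - 3) / (1 - 0.46^2))
})

test_that("identical seeds reproduce the cohort and infeasible configs fail", {
  a <- simulate_cohort(sim_config(n_subjects = 12, seed = 305))
  b <- simulate_cohort(sim_config(n_subjects = 12, seed = 305))
  expect_identical(a$narratives$text, b$narratives$text)
  expect_identical(a$subjects, b$subjects)
  expect_error(simulate_cohort(sim_config(n_subjects = 12, seed = 306,
                                          mean_tokens = 60L)),
               "infeasible")
  expect_error(sim_config(n_subjects = 5), "n_subjects")
})

test_that("planting vocabularies are disjoint from stopwords and each other", {
  stop <- default_stopwords()
  lex_tokens <- unique(unlist(strsplit(demo_openness_lexicon()$ngram, " ",
                                       fixed = TRUE)))
  emo_words <- names(demo_emotion_lexicon())
  filler <- famcomm:::filler_vocabulary(5700L)
  expect_length(intersect(lex_tokens, stop), 0L)
  expect_length(intersect(emo_words, stop), 0L)
  expect_length(intersect(lex_tokens, emo_words), 0L)
  expect_length(intersect(filler, c(stop, lex_tokens, emo_words)), 0L)
  # planting phrases are entries of the demo lexicon at full strength
  pl <- famcomm:::openness_planting_phrases()
  lex <- demo_openness_lexicon()
  expect_true(all(lex$score[match(pl$positive, lex$ngram)] == 3L))
  expect_true(all(lex$score[match(pl$negative, lex$ngram)] == -3L))
})

test_that("a 53-narrative corpus carries a realistic unigram vocabulary", {
  co <- simulate_cohort(sim_config(seed = 307))
  vs <- vocabulary_summary(corpus_profiles(co$narratives))
  expect_gt(vs$n_unigrams, 5000)
  expect_lt(vs$n_unigrams, 6000)
})
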