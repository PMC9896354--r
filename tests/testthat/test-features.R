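make_subjects <- function(ids) {
  n <- length(ids)
  data.frame(subject_id = ids, age = seq(40, 40 + n - 1),
             sex = rep("female", n),
             education = rep(c("university_postgraduate",
                               "high_school_graduate"), length.out = n),
             marital_status = rep(c("single", "married"), length.out = n),
             employed = rep(1L, n), cancer_status = rep("affected", n),
             test_result = rep("positive", n),
             informational_support = rep(5L, n),
             communication_preference = rep(3L, n),
             perceived_utility = rep(6L, n), stringsAsFactors = FALSE)
}

make_sentiment <- function(ids) {
  n <- length(ids)
  data.frame(narrative_id = paste0("n", ids), subject_id = ids,
             anger = 0, anticipation = 0, disgust = 0, fear = seq_len(n),
             joy = 0, sadness = 0, surprise = 0, trust = 0,
             nrc_pos = seq_len(n) + 1, nrc_neg = 1,
             net_sentiment = seq_len(n), stringsAsFactors = FALSE)
}

make_scores <- function(ids) {
  data.frame(narrative_id = paste0("n", ids), subject_id = ids,
             openness_score = 10L * seq_along(ids), n_matches = 2L,
             stringsAsFactors = FALSE)
}

test_that("assemble_features builds the documented schema", {
  ids <- c("s1", "s2", "s3")
  tab <- assemble_features(make_subjects(ids), make_sentiment(ids),
                           make_scores(ids))
  expect_identical(tab$subject_id, ids)
  expect_identical(names(tab)[1:3], c("subject_id", "single", "academic"))
  expect_identical(tail(names(tab), 1), "openness")
  expect_identical(tab$single, c(1L, 0L, 1L))
  expect_identical(tab$academic, c(1L, 0L, 1L))
  expect_equal(tab$fear, 1:3)
  expect_equal(tab$openness, c(10L, 20L, 30L))
  # indicator columns are strictly 0/1
  for (cc in c("single", "academic", "sex_female", "employed", "cancer",
               "test_positive")) {
    expect_true(all(tab[[cc]] %in% c(0L, 1L)))
  }
})

test_that("assemble_features reports id mismatches explicitly", {
  ids <- c("s1", "s2", "s3")
  expect_error(assemble_features(make_subjects(ids),
                                 make_sentiment(ids),
                                 make_scores(c("s1", "s2"))),
               "without narrative scores.*s3")
  expect_error(assemble_features(make_subjects(c("s1", "s2")),
                                 make_sentiment(ids), make_scores(ids)),
               "without subject record.*s3")
  dup <- make_scores(c("s1", "s2", "s2"))
  expect_error(assemble_features(make_subjects(c("s1", "s2")),
                                 make_sentiment(c("s1", "s2")), dup),
               "multiple narratives.*s2")
})

test_that("complete-case filtering drops rows with missing covariates", {
  ids <- c("s1", "s2", "s3")
  subj <- make_subjects(ids)
  subj$age[2] <- NA
  expect_message(
    tab <- assemble_features(subj, make_sentiment(ids), make_scores(ids)),
    "complete-case")
  expect_identical(tab$subject_id, c("s1", "s3"))
})

test_that("collinearity filter drops one member of a near-duplicate pair", {
  set.seed(8)
  n <- 80
  x1 <- rnorm(n)
  d <- data.frame(x1 = x1, x2 = x1 + rnorm(n, sd = 0.05),
                  x3 = rnorm(n), x4 = rnorm(n))
  flt <- collinearity_filter(d, predictors = names(d))
  expect_identical(nrow(flt$dropped), 1L)
  expect_true(flt$dropped$dropped %in% c("x1", "x2"))
  expect_identical(sort(c(flt$kept, flt$dropped$dropped)),
                   c("x1", "x2", "x3", "x4"))
  # independent columns: nothing dropped
  d2 <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  expect_identical(collinearity_filter(d2, predictors = names(d2))$kept,
                   c("a", "b", "c"))
})

test_that("collinearity threshold is strict: |r| = 0.60 kept, above dropped", {
  # construct exact correlations by Gram-Schmidt
  set.seed(9)
  n <- 50
  u <- scale(rnorm(n))[, 1]
  z <- rnorm(n)
  z <- scale(z - u * sum(u * z) / sum(u * u))[, 1]  # orthogonal to u
  make_r <- function(r) r * u + sqrt(1 - r^2) * z
  d_keep <- data.frame(x = u, y = make_r(0.60))
  expect_equal(cor(d_keep$x, d_keep$y), 0.60, tolerance = 1e-12)
  flt <- collinearity_filter(d_keep, predictors = c("x", "y"),
                             threshold = 0.60)
  expect_identical(nrow(flt$dropped), 0L)
  d_drop <- data.frame(x = u, y = make_r(0.601))
  flt2 <- collinearity_filter(d_drop, predictors = c("x", "y"),
                              threshold = 0.60)
  expect_identical(nrow(flt2$dropped), 1L)
})

test_that("victim selection follows mean absolute correlation with schema-order ties", {
  set.seed(10)
  n <- 200
  u <- scale(rnorm(n))[, 1]
  z1 <- rnorm(n); z1 <- scale(z1 - u * sum(u * z1) / n)[, 1]
  # a and b are highly correlated; b also correlates with c, so b has
  # the larger mean absolute correlation and must be the victim
  a <- u
  b <- 0.9 * u + sqrt(1 - 0.81) * z1
  c_ <- 0.5 * z1 + sqrt(0.75) * scale(rnorm(n))[, 1]
  d <- data.frame(a = a, b = b, c = c_, e = rnorm(n))
  flt <- collinearity_filter(d, predictors = names(d), threshold = 0.6)
  expect_identical(flt$dropped$dropped[1], "b")
  expect_true(all(c("a", "c", "e") %in% flt$kept))
  # exact tie (duplicated column): later schema column dropped
  d2 <- data.frame(p = u, q = u)
  flt2 <- suppressWarnings(collinearity_filter(d2, predictors = c("p", "q"),
                                               threshold = 0.6))
  expect_identical(flt2$dropped$dropped, "q")
})

test_that("collinearity filter warns on constant columns and ignores row order", {
  set.seed(11)
  d <- data.frame(k = rep(2, 40), x = rnorm(40), y = rnorm(40))
  expect_warning(flt <- collinearity_filter(d, predictors = names(d)),
                 "zero-variance")
  expect_identical(flt$constant, "k")
  x1 <- rnorm(60)
  d2 <- data.frame(a = x1, b = x1 + rnorm(60, sd = 0.01), c = rnorm(60))
  perm <- sample(nrow(d2))
  f1 <- collinearity_filter(d2, predictors = names(d2))
  f2 <- collinearity_filter(d2[perm, ], predictors = names(d2))
  expect_identical(f1$kept, f2$kept)
  expect_identical(f1$dropped$dropped, f2$dropped$dropped)
})
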