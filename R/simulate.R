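#' Configuration for the synthetic-cohort generator
#'
#' The defaults reproduce the study conditions the pipeline was designed
#' around: 53 subjects; age about Normal(53, 12) years; 89% female; 8%
#' single; 40% academic education; 60% with a prior cancer diagnosis;
#' 96% carriers; Likert covariates on 1..7; an openness outcome that is
#' linear in being single, academic education, the narrative fear count,
#' informational support and net sentiment with additive Gaussian noise,
#' with coefficients matching the fitted regression signs and magnitudes
#' (single +19.782, academic -10.387, fear +0.204, support +11.392,
#' net sentiment +0.260) and a mean openness score of about 29.8.  The
#' intercept, when not given, is solved from the covariate means so the
#' expected openness hits `target_mean`.
#'
#' @param n_subjects Cohort size (>= 10).
#' @param seed Integer seed governing all randomness.
#' @param beta Named numeric vector of true coefficients for `single`,
#'   `academic`, `fear`, `informational_support`, `net_sentiment`.
#' @param intercept Intercept; `NULL` solves it from `target_mean`.
#' @param target_mean Target expected openness score (default 29.8).
#' @param noise_sd SD of the additive noise on the latent openness
#'   (default 8, on the scale of the openness score; the default
#'   variance budget puts the openness SD near 20 with most variance
#'   explained by the five true predictors).
#' @param mean_tokens Mean narrative length in tokens (default 800).
#' @param filler_vocab_size Distinct filler pseudo-words available
#'   (default 5700, sized so a 53-narrative corpus carries roughly 5800
#'   unique unigrams).
#' @param emotion_lambda Named means for the planted per-narrative
#'   emotion counts (fear is Normal(60, 20) truncated at 0; the other
#'   seven are Poisson with these means, ordered so trust dominates the
#'   positive emotions and surprise/anger are rare).
#' @param net_mean,net_sd Mean/SD of the planted net sentiment.
#' @param polarity_base Baseline positive and negative word insertions
#'   present in every narrative (net sentiment rides on top).
#' @param iri_r Target correlation of the simulated external inventory
#'   total with the latent openness (default 0.46); `NA` omits the
#'   column.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 53L, seed = 1L,
                       beta = c(single = 19.782, academic = -10.387,
                                fear = 0.204,
                                informational_support = 11.392,
                                net_sentiment = 0.260),
                       intercept = NULL, target_mean = 29.8,
                       noise_sd = 8, mean_tokens = 800L,
                       filler_vocab_size = 5700L,
                       emotion_lambda = c(anger = 10, anticipation = 40,
                                          disgust = 15, joy = 35,
                                          sadness = 45, surprise = 8,
                                          trust = 70),
                       fear_mean = 60, fear_sd = 20,
                       net_mean = 25, net_sd = 20,
                       polarity_base = 15L, iri_r = 0.46) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 10L) stop("n_subjects must be >= 10")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  need <- c("single", "academic", "fear", "informational_support",
            "net_sentiment")
  if (!all(need %in% names(beta))) {
    stop("beta must name: ", paste(need, collapse = ", "))
  }
  # covariate means used both for the intercept solve and for planting
  means <- c(single = 0.08, academic = 0.40, fear = fear_mean,
             informational_support = 5.0, net_sentiment = net_mean)
  if (is.null(intercept)) {
    intercept <- target_mean - sum(beta[need] * means[need])
  }
  structure(list(n_subjects = n_subjects, seed = as.integer(seed),
                 beta = beta[need], intercept = intercept,
                 noise_sd = noise_sd, mean_tokens = as.integer(mean_tokens),
                 filler_vocab_size = as.integer(filler_vocab_size),
                 emotion_lambda = emotion_lambda, fear_mean = fear_mean,
                 fear_sd = fear_sd, net_mean = net_mean, net_sd = net_sd,
                 polarity_base = as.integer(polarity_base), iri_r = iri_r),
            class = "sim_config")
}

#' @param fear_mean,fear_sd Mean/SD of the planted fear count.
#' @rdname sim_config
#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat("  n_subjects:", x$n_subjects, " seed:", x$seed, "\n")
  cat("  intercept:", format(x$intercept, digits = 6),
      " noise_sd:", x$noise_sd, "\n")
  cat("  beta:", paste(names(x$beta), format(x$beta), sep = "=",
                       collapse = ", "), "\n")
  cat("  mean narrative length:", x$mean_tokens, "tokens\n")
  invisible(x)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Simulate a synthetic cohort with planted lexical signal
#'
#' Generates subject records, narrative texts and the ground truth under
#' a known linear model of openness.  Planting is exact by construction:
#' the narrative contains `round(max(Y*, 0) / 3)` insertions of +3
#' openness phrases (or the mirror-image -3 phrases for negative latent
#' scores), exactly the planted number of fear-category words, Poisson
#' counts of the other emotion words, and positive/negative polarity
#' words whose difference equals the planted net sentiment.  Remaining
#' length is filled with pseudo-word filler and the token order is
#' shuffled, keeping multi-word phrases intact.  Running the pipeline on
#' the narratives therefore recovers the planted fear count and net
#' sentiment exactly, and the openness score up to phrase-quantization
#' (at most 1.5 points).
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `subjects` (data.frame in the
#'   [read_subjects()] layout incl. `iri_total`), `narratives`
#'   (data.frame in the [read_narratives()] layout), `truth` (data.frame
#'   with per-subject latent openness and planted counts, plus
#'   attributes `beta`, `intercept`, `noise_sd`), and `config`.
#' @export
#' @examples
#' cohort <- simulate_cohort(sim_config(n_subjects = 12, seed = 42))
#' head(cohort$truth)
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_subjects
  # covariates (Table-1-like cohort structure)
  age <- clip(round(stats::rnorm(n, 53, 12)), 30, 80)
  sex_female <- stats::rbinom(n, 1, 0.89)
  single <- stats::rbinom(n, 1, 0.08)
  marital <- ifelse(single == 1, "single",
                    ifelse(stats::runif(n) < 0.77 / 0.92, "married",
                           "divorced_separated_widowed"))
  academic <- stats::rbinom(n, 1, 0.40)
  edu_other <- sample(c("elementary_high_school", "high_school_graduate",
                        "technical_school_graduate"), n, replace = TRUE,
                      prob = c(5, 14, 13))
  education <- ifelse(academic == 1, "university_postgraduate", edu_other)
  employed <- stats::rbinom(n, 1, 0.64)
  cancer <- stats::rbinom(n, 1, 0.60)
  test_positive <- stats::rbinom(n, 1, 0.96)
  lik <- function(mu, sd) as.integer(clip(round(stats::rnorm(n, mu, sd)),
                                          1, 7))
  informational_support <- lik(5.0, 1.25)
  communication_preference <- lik(2.5, 1.4)
  perceived_utility <- lik(6.0, 1.0)
  # planted narrative features
  fear <- as.integer(pmax(0, round(stats::rnorm(n, config$fear_mean,
                                                config$fear_sd))))
  net <- as.integer(round(stats::rnorm(n, config$net_mean, config$net_sd)))
  other <- vapply(names(config$emotion_lambda), function(cc) {
    stats::rpois(n, config$emotion_lambda[[cc]])
  }, integer(n))
  if (n == 1L) other <- matrix(other, nrow = 1,
                               dimnames = list(NULL,
                                               names(config$emotion_lambda)))
  # latent openness
  b <- config$beta
  latent <- config$intercept + b[["single"]] * single +
    b[["academic"]] * academic + b[["fear"]] * fear +
    b[["informational_support"]] * informational_support +
    b[["net_sentiment"]] * net +
    stats::rnorm(n, 0, config$noise_sd)
  # narratives
  pl <- openness_planting_phrases()
  ws <- emotion_word_sets()
  filler <- filler_vocabulary(config$filler_vocab_size)
  pos_units <- as.integer(round(pmax(latent, 0) / 3))
  neg_units <- as.integer(round(pmax(-latent, 0) / 3))
  pos_words_n <- config$polarity_base + pmax(net, 0L)
  neg_words_n <- config$polarity_base + pmax(-net, 0L)
  texts <- character(n)
  for (i in seq_len(n)) {
    units <- c(
      sample(pl$positive, pos_units[i], replace = TRUE),
      sample(pl$negative, neg_units[i], replace = TRUE),
      sample(ws$fear, fear[i], replace = TRUE),
      unlist(lapply(names(config$emotion_lambda), function(cc) {
        sample(ws[[cc]], other[i, cc], replace = TRUE)
      })),
      sample(ws$positive, pos_words_n[i], replace = TRUE),
      sample(ws$negative, neg_words_n[i], replace = TRUE)
    )
    used <- sum(lengths(strsplit(units, " ", fixed = TRUE)))
    target_len <- round(stats::rnorm(1, config$mean_tokens,
                                     0.1 * config$mean_tokens))
    n_filler <- target_len - used
    if (n_filler < 0L) {
      stop("infeasible config: planted counts (", used,
           " tokens) exceed narrative length (", target_len,
           ") for subject ", i)
    }
    units <- c(units, sample(filler, n_filler, replace = TRUE))
    texts[i] <- paste(sample(units), collapse = " ")
  }
  sid <- sprintf("S%03d", seq_len(n))
  subjects <- data.frame(
    subject_id = sid, age = age,
    sex = ifelse(sex_female == 1, "female", "male"),
    education = education, marital_status = marital, employed = employed,
    cancer_status = ifelse(cancer == 1, "affected", "unaffected"),
    test_result = ifelse(test_positive == 1, "positive", "negative"),
    informational_support = informational_support,
    communication_preference = communication_preference,
    perceived_utility = perceived_utility, stringsAsFactors = FALSE)
  if (!is.na(config$iri_r)) {
    r <- config$iri_r
    z <- if (stats::sd(latent) > 0) as.numeric(scale(latent)) else
      rep(0, n)
    iri_z <- r * z + sqrt(1 - r^2) * stats::rnorm(n)
    subjects$iri_total <- as.integer(clip(round(160 + 25 * iri_z), 37, 259))
  }
  narratives <- data.frame(id = paste0("N", sid), subject_id = sid,
                           language = sample(c("de", "fr", "it", "en",
                                               "ko"), n, replace = TRUE,
                                             prob = c(.45, .20, .10, .08,
                                                      .17)),
                           text = texts, stringsAsFactors = FALSE)
  truth <- data.frame(subject_id = sid, latent_openness = latent,
                      planted_score = 3L * pos_units - 3L * neg_units,
                      fear = fear, net_sentiment = net,
                      pos_units = pos_units, neg_units = neg_units,
                      stringsAsFactors = FALSE)
  truth <- cbind(truth, as.data.frame(other))
  attr(truth, "beta") <- b
  attr(truth, "intercept") <- config$intercept
  attr(truth, "noise_sd") <- config$noise_sd
  structure(list(subjects = subjects, narratives = narratives,
                 truth = truth, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$subjects), "subjects (seed",
      x$config$seed, ")\n")
  cat("  latent openness: mean",
      format(mean(x$truth$latent_openness), digits = 4), "sd",
      format(stats::sd(x$truth$latent_openness), digits = 4), "\n")
  invisible(x)
}

#' Run the full pipeline on a cohort
#'
#' Convenience driver: tokenizes and scores the narratives with a given
#' openness lexicon, extracts sentiment features, assembles the feature
#' table, and (optionally) runs the split-sample evaluation.
#'
#' @param narratives,subjects Data in the [read_narratives()] /
#'   [read_subjects()] layouts.
#' @param lexicon An [openness_lexicon()]; default
#'   [demo_openness_lexicon()].
#' @param emotion_lexicon Word -> categories list; default
#'   [demo_emotion_lexicon()].
#' @param stopwords Stopword list.
#' @param policy Overlap policy for [score_narrative()].
#' @param evaluate Run [evaluate_openness()] as well.
#' @param split_seed,train_fraction Passed to [evaluate_openness()].
#' @param ... Passed to [openness_fit()] / [evaluate_openness()]
#'   (e.g. `predictors`, `criterion`).
#' @return List: `scores` ([score_corpus()] result), `sentiment`,
#'   `features` (the assembled table), and when `evaluate = TRUE`
#'   `evaluation` (an `openness_eval`), otherwise `fit` (an
#'   [openness_fit()] on the full table).
#' @export
run_pipeline <- function(narratives, subjects,
                         lexicon = demo_openness_lexicon(),
                         emotion_lexicon = demo_emotion_lexicon(),
                         stopwords = default_stopwords(),
                         policy = "greedy", evaluate = TRUE,
                         split_seed = 1L, train_fraction = 0.70, ...) {
  sc <- score_corpus(narratives, lexicon, stopwords = stopwords,
                     policy = policy)
  sent <- sentiment_features(narratives, emotion_lexicon,
                             stopwords = stopwords)
  tab <- assemble_features(subjects, sent, sc$scores)
  out <- list(scores = sc, sentiment = sent, features = tab)
  if (evaluate) {
    out$evaluation <- evaluate_openness(tab, split_seed = split_seed,
                                        train_fraction = train_fraction,
                                        ...)
  } else {
    out$fit <- openness_fit(tab, ...)
  }
  out
}
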