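# Built-in demonstration vocabularies for the synthetic-cohort generator
# and the test fixtures.  These are synthetic stand-ins, hand-authored to
# be plainly communication- or emotion-themed; they are NOT the study
# lexicons (the real openness lexicon is unpublished and the three
# sentiment resources are third-party).  Planting in simulate_cohort()
# is exact-by-construction, which requires the word sets below to be
# mutually disjoint, disjoint from the default stopword list, and (for
# the emotion sets) single-category.

openness_planting_phrases <- function() {
  list(
    positive = c("spoke openly", "shared everything immediately",
                 "told relatives directly", "discussed risks honestly"),
    negative = c("kept secret", "avoided telling anyone",
                 "refused discussing results", "hid diagnosis")
  )
}

#' Demonstration openness lexicon
#'
#' A 40-entry hand-authored synthetic lexicon of communication-themed
#' N-grams scored on the -3..+3 openness scale, shipped for examples,
#' tests and the synthetic-data generator.  It is a small demonstration
#' resource, not the unpublished 532-item study lexicon.
#'
#' @return An [openness_lexicon()] with 40 entries (12 unigrams,
#'   15 bigrams, 13 trigrams).
#' @export
#' @examples
#' demo_openness_lexicon()
demo_openness_lexicon <- function() {
  pl <- openness_planting_phrases()
  ngram <- c(
    pl$positive, pl$negative,
    # unigrams
    "talk", "conversation", "communicate", "informed", "disclosure",
    "dialogue", "openness", "silence", "secrecy", "concealment",
    "unspoken", "avoidance",
    # bigrams
    "open conversation", "good communication", "honest exchange",
    "family meeting", "regular contact", "close contact",
    "communication barrier", "broken contact", "strained relationship",
    "awkward silence", "poor communication", "difficult topic",
    # trigrams
    "whole family knows", "everybody felt informed",
    "freely exchanged news", "always felt heard",
    "nobody ever mentioned", "never talked anymore",
    "completely stopped talking", "rarely mentioned anything"
  )
  score <- c(
    3L, 3L, 3L, 3L, -3L, -3L, -3L, -3L,
    1L, 1L, 2L, 2L, 2L, 2L, 3L, -2L, -3L, -3L, -2L, -2L,
    3L, 2L, 3L, 1L, 2L, 2L, -2L, -3L, -2L, -2L, -2L, -1L,
    3L, 2L, 3L, 2L, -3L, -3L, -3L, -2L
  )
  openness_lexicon(ngram, score,
                   source = rep(c("corpus", "thesaurus"),
                                c(8L, length(ngram) - 8L)))
}

emotion_word_sets <- function() {
  list(
    anger = c("furious", "outraged", "irritated", "resentful", "angered"),
    anticipation = c("expectation", "awaiting", "eagerness", "foresee",
                     "anticipate"),
    disgust = c("revulsion", "repulsed", "nauseating", "loathing",
                "disgusted"),
    fear = c("afraid", "scared", "terrified", "dread", "panic",
             "worried", "frightened", "anxious"),
    joy = c("delighted", "cheerful", "joyful", "elated", "gladness"),
    sadness = c("sorrow", "grieving", "mournful", "tearful",
                "heartbroken"),
    surprise = c("astonished", "startled", "amazed", "stunned",
                 "unexpected"),
    trust = c("reliable", "faithful", "trustworthy", "dependable",
              "reassured"),
    positive = c("wonderful", "excellent", "marvelous", "superb",
                 "pleasant", "admirable"),
    negative = c("awful", "horrible", "nasty", "unpleasant",
                 "miserable", "painful")
  )
}

#' Demonstration sentiment lexicons
#'
#' Tiny hand-authored synthetic stand-ins for the three third-party
#' sentiment lexicon families, shipped for examples, tests and the
#' synthetic generator.  In `demo_emotion_lexicon()` every word carries
#' exactly one category, which is what makes feature planting in
#' [simulate_cohort()] exact; real emotion lexicons attach several
#' categories to many words.
#'
#' @return `demo_emotion_lexicon()`: named list word -> categories;
#'   `demo_valence_lexicon()`: named integer vector word -> score in
#'   `[-5, 5]`; `demo_polarity_lexicon()`: named character vector
#'   word -> `"positive"`/`"negative"`.
#' @export
demo_emotion_lexicon <- function() {
  ws <- emotion_word_sets()
  words <- unlist(ws, use.names = FALSE)
  cats <- rep(names(ws), lengths(ws))
  split(cats, words)[words]
}

#' @rdname demo_emotion_lexicon
#' @export
demo_valence_lexicon <- function() {
  c(wonderful = 4L, excellent = 3L, marvelous = 4L, superb = 3L,
    pleasant = 2L, admirable = 2L, delighted = 3L, cheerful = 2L,
    reassured = 2L, awful = -3L, horrible = -3L, nasty = -3L,
    unpleasant = -2L, miserable = -2L, painful = -2L, scared = -2L,
    terrified = -4L, sorrow = -2L, worried = -2L)
}

#' @rdname demo_emotion_lexicon
#' @export
demo_polarity_lexicon <- function() {
  pos <- c("wonderful", "excellent", "marvelous", "superb", "pleasant",
           "admirable", "delighted", "cheerful", "reassured")
  neg <- c("awful", "horrible", "nasty", "unpleasant", "miserable",
           "painful", "scared", "terrified", "sorrow", "worried")
  structure(rep(c("positive", "negative"), c(length(pos), length(neg))),
            names = c(pos, neg))
}

# Deterministic pseudo-word filler vocabulary (consonant-vowel syllable
# pairs), guaranteed disjoint from the real-word vocabularies above.
filler_vocabulary <- function(size = 5700L) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))          # 70 syllables
  words <- as.vector(outer(syl, syl, paste0))         # 4900 two-syllable
  if (size > length(words)) {
    three <- as.vector(outer(words, syl, paste0))     # extend as needed
    words <- c(words, three)
  }
  reserved <- c(default_stopwords(),
                unlist(strsplit(demo_openness_lexicon()$ngram, " ",
                                fixed = TRUE)),
                unlist(emotion_word_sets(), use.names = FALSE))
  words <- setdiff(words, reserved)
  if (size > length(words)) stop("filler vocabulary size too large")
  words[seq_len(size)]
}
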