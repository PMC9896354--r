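#' Load sentiment lexicons
#'
#' Three third-party lexicon families drive the sentiment features; the
#' package ships only tiny synthetic stand-ins for tests, real resources
#' are user-supplied.
#'
#' * Emotion lexicon (`load_emotion_lexicon`): TSV
#'   `word<TAB>category<TAB>flag` (the standard word-association triple
#'   layout); rows with flag 1 assign the word to the category.  Valid
#'   categories are the eight emotions (anger, anticipation, disgust,
#'   fear, joy, sadness, surprise, trust) plus positive and negative.
#' * Valence lexicon (`load_valence_lexicon`): TSV `word<TAB>score` with
#'   integer scores in `[-5, 5]`.
#' * Polarity lexicon (`load_polarity_lexicon`): TSV
#'   `word<TAB>polarity` with polarity `positive` or `negative`.
#'
#' @param path TSV file path.
#' @return `load_emotion_lexicon`: named list mapping each word to its
#'   character vector of categories.  `load_valence_lexicon`: named
#'   integer vector.  `load_polarity_lexicon`: named character vector of
#'   polarities.
#' @name sentiment_lexicons
NULL

emotion_categories <- function() {
  c("anger", "anticipation", "disgust", "fear", "joy", "sadness",
    "surprise", "trust", "positive", "negative")
}

#' @rdname sentiment_lexicons
#' @export
load_emotion_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  if (!all(c("word", "category", "flag") %in% names(raw))) {
    stop("emotion lexicon TSV must have columns word, category, flag")
  }
  bad <- setdiff(unique(raw$category), emotion_categories())
  if (length(bad) > 0L) {
    stop("unknown emotion categories: ", paste(bad, collapse = ", "))
  }
  raw <- raw[raw$flag == 1L, , drop = FALSE]
  split(raw$category, raw$word)
}

#' @rdname sentiment_lexicons
#' @export
load_valence_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  if (!all(c("word", "score") %in% names(raw))) {
    stop("valence lexicon TSV must have columns word, score")
  }
  sc <- as.integer(raw$score)
  if (any(is.na(sc) | sc < -5L | sc > 5L)) {
    stop("valence scores must be integers in [-5, 5]")
  }
  structure(sc, names = raw$word)
}

#' @rdname sentiment_lexicons
#' @export
load_polarity_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  if (!all(c("word", "polarity") %in% names(raw))) {
    stop("polarity lexicon TSV must have columns word, polarity")
  }
  if (!all(raw$polarity %in% c("positive", "negative"))) {
    stop("polarity must be 'positive' or 'negative'")
  }
  if (anyDuplicated(raw$word)) stop("duplicate words in polarity lexicon")
  structure(raw$polarity, names = raw$word)
}

#' Emotion-category features for one token sequence
#'
#' Counts, per category, the token *occurrences* whose word carries that
#' category (a word flagged for several categories increments each).
#' Counts are raw, not normalized by document length.  The net sentiment
#' is the positive total minus the negative total.
#'
#' @param tokens Character vector of tokens.
#' @param emotion_lexicon Named list word -> categories (see
#'   [load_emotion_lexicon()]).
#' @return Named numeric vector: the eight emotion counts, `nrc_pos`,
#'   `nrc_neg`, and `net_sentiment = nrc_pos - nrc_neg`.
#' @export
#' @examples
#' lex <- list(fear = c("fear", "negative"), trust = c("trust", "positive"))
#' emotion_features(c("fear", "fear", "trust"), lex)
emotion_features <- function(tokens, emotion_lexicon) {
  cats <- emotion_categories()
  counts <- stats::setNames(integer(length(cats)), cats)
  hit <- tokens[tokens %in% names(emotion_lexicon)]
  if (length(hit) > 0L) {
    flags <- unlist(emotion_lexicon[hit], use.names = FALSE)
    tab <- table(factor(flags, levels = cats))
    counts <- counts + as.integer(tab)
    names(counts) <- cats
  }
  out <- as.numeric(counts[c("anger", "anticipation", "disgust", "fear",
                             "joy", "sadness", "surprise", "trust")])
  names(out) <- c("anger", "anticipation", "disgust", "fear", "joy",
                  "sadness", "surprise", "trust")
  pos <- as.numeric(counts[["positive"]])
  neg <- as.numeric(counts[["negative"]])
  c(out, nrc_pos = pos, nrc_neg = neg, net_sentiment = pos - neg)
}

#' Valence and polarity features for one token sequence
#'
#' `valence_features` sums the valence score of every matched token
#' occurrence; `polarity_features` counts positive and negative token
#' occurrences.
#'
#' @param tokens Character vector of tokens.
#' @param valence_lexicon Named integer vector word -> score in `[-5, 5]`.
#' @return `valence_features`: named vector with `valence_sum`.
#' @export
valence_features <- function(tokens, valence_lexicon) {
  s <- valence_lexicon[tokens]
  c(valence_sum = sum(s, na.rm = TRUE))
}

#' @param polarity_lexicon Named character vector word -> polarity.
#' @rdname valence_features
#' @export
polarity_features <- function(tokens, polarity_lexicon) {
  p <- polarity_lexicon[tokens]
  c(polarity_pos = sum(p == "positive", na.rm = TRUE),
    polarity_neg = sum(p == "negative", na.rm = TRUE))
}

#' Net sentiment of a feature vector
#'
#' The overall net sentiment of a narrative: emotion-lexicon positive
#' total minus negative total.  Positive values mean the narrative
#' expressed more positive than negative sentiment.
#'
#' @param features Named vector containing `nrc_pos` and `nrc_neg` (as
#'   from [emotion_features()]).
#' @return Numeric scalar `nrc_pos - nrc_neg`.
#' @export
net_sentiment <- function(features) {
  unname(features[["nrc_pos"]] - features[["nrc_neg"]])
}

#' Sentiment features for a corpus
#'
#' Runs [emotion_features()] (and optionally the valence and polarity
#' counters) over every narrative.
#'
#' @param narratives Data.frame as from [read_narratives()].
#' @param emotion_lexicon Named list word -> categories.
#' @param valence_lexicon,polarity_lexicon Optional extra lexicons.
#' @param stopwords Stopword list for [tokenize()].
#' @param per_tokens If non-`NULL`, rescale every count (and the net
#'   sentiment) to occurrences per `per_tokens` tokens of the
#'   narrative, e.g. `per_tokens = 1000`.  Default `NULL`: raw counts,
#'   which keeps coefficient units in score points per word occurrence.
#' @return Data.frame with `narrative_id`, `subject_id`, the eight
#'   emotion counts, `nrc_pos`, `nrc_neg`, `net_sentiment`, and (when the
#'   extra lexicons are given) `valence_sum`, `polarity_pos`,
#'   `polarity_neg`.
#' @export
sentiment_features <- function(narratives, emotion_lexicon,
                               valence_lexicon = NULL,
                               polarity_lexicon = NULL,
                               stopwords = default_stopwords(),
                               per_tokens = NULL) {
  toks <- lapply(narratives$text, tokenize, stopwords = stopwords)
  emo <- t(vapply(toks, emotion_features,
                  numeric(11), emotion_lexicon = emotion_lexicon))
  if (!is.null(per_tokens)) {
    len <- vapply(toks, length, integer(1))
    scale_by <- ifelse(len > 0, per_tokens / len, 0)
    emo <- emo * scale_by
  }
  out <- data.frame(narrative_id = narratives$id,
                    subject_id = narratives$subject_id,
                    emo, stringsAsFactors = FALSE)
  if (!is.null(valence_lexicon)) {
    out$valence_sum <- vapply(toks, function(tk)
      valence_features(tk, valence_lexicon)[["valence_sum"]], numeric(1))
  }
  if (!is.null(polarity_lexicon)) {
    pp <- t(vapply(toks, polarity_features, numeric(2),
                   polarity_lexicon = polarity_lexicon))
    out$polarity_pos <- pp[, "polarity_pos"]
    out$polarity_neg <- pp[, "polarity_neg"]
  }
  rownames(out) <- NULL
  out
}
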