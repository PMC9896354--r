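#' Tokenize a narrative text
#'
#' Lowercases, strips apostrophes, splits on any run of non-alphanumeric
#' characters, drops empty fragments, and removes stopwords.  This is the
#' single normalization convention for the whole pipeline: openness and
#' sentiment lexicons are matched against tokens produced by this rule, so
#' lexicon entries must be normalized the same way (see
#' [normalize_ngram()]).  Stopword removal happens *before* N-gram
#' extraction, so higher-order N-grams span removed stopwords.
#'
#' @param text A character scalar (free-form text; may be empty or `NA`,
#'   both yield an empty token vector).
#' @param stopwords Character vector of lowercase stopwords to drop.
#'   Defaults to [default_stopwords()]; use `character(0)` to keep
#'   everything.
#' @return Character vector of tokens in source order.
#' @export
#' @examples
#' tokenize("The doctor said: TRUST!", stopwords = c("the", "said"))
tokenize <- function(text, stopwords = default_stopwords()) {
  if (length(text) != 1L) stop("text must be a single string")
  if (is.na(text) || !nzchar(text)) return(character(0))
  x <- tolower(enc2utf8(text))
  x <- gsub("['’‘]", "", x, perl = TRUE)
  toks <- strsplit(x, "[^\\p{L}\\p{N}]+", perl = TRUE)[[1]]
  toks <- toks[nzchar(toks)]
  toks[!toks %in% stopwords]
}

#' Normalize a lexicon N-gram key
#'
#' Applies the tokenizer convention ([tokenize()] with an empty stopword
#' list) to an N-gram string and re-joins with single spaces, so lexicon
#' keys match pipeline tokens exactly.
#'
#' @param ngram Character vector of N-gram strings.
#' @return Character vector of normalized keys.
#' @export
normalize_ngram <- function(ngram) {
  vapply(ngram, function(g) {
    paste(tokenize(g, stopwords = character(0)), collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract N-gram occurrence counts from a token sequence
#'
#' Counts all contiguous N-grams of orders 1..`max_n` (keys are tokens
#' joined by a single space).  A sequence of length L yields L - n + 1
#' N-grams of order n (none if L < n).
#'
#' @param tokens Character vector of tokens (from [tokenize()]).
#' @param max_n Maximum N-gram order, between 1 and 3.
#' @return Named integer vector of occurrence counts; empty for an empty
#'   sequence.
#' @export
#' @examples
#' extract_ngrams(c("open", "family", "talk"), max_n = 2)
extract_ngrams <- function(tokens, max_n = 3L) {
  max_n <- as.integer(max_n)
  if (is.na(max_n) || max_n < 1L || max_n > 3L) {
    stop("max_n must be 1, 2, or 3")
  }
  L <- length(tokens)
  keys <- character(0)
  for (n in seq_len(max_n)) {
    if (L < n) next
    if (n == 1L) {
      w <- tokens
    } else {
      idx <- seq_len(L - n + 1L)
      parts <- lapply(seq_len(n) - 1L, function(k) tokens[idx + k])
      w <- do.call(paste, parts)
    }
    keys <- c(keys, w)
  }
  if (length(keys) == 0L) {
    return(structure(integer(0), names = character(0)))
  }
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}

#' N-gram profiles for a corpus of narratives
#'
#' @param narratives Data.frame as returned by [read_narratives()].
#' @param stopwords Stopword list passed to [tokenize()].
#' @param max_n Maximum N-gram order (1..3).
#' @return Named list of N-gram count vectors, one per narrative, named by
#'   narrative id.
#' @export
corpus_profiles <- function(narratives, stopwords = default_stopwords(),
                            max_n = 3L) {
  profs <- lapply(narratives$text, function(tx) {
    extract_ngrams(tokenize(tx, stopwords), max_n = max_n)
  })
  names(profs) <- narratives$id
  profs
}

#' Corpus term statistics (TF, DF, TF-IDF)
#'
#' Computes, for every (document, term) pair present in the profiles, the
#' raw term frequency, the document frequency and the TF-IDF weight
#' `tf * ln(N / df)` (unsmoothed, natural log; a term present in every
#' document gets weight 0).  With `smooth = TRUE` the idf becomes
#' `ln((1 + N) / (1 + df)) + 1`, which never vanishes.
#'
#' @param profiles Named list of N-gram count vectors
#'   (see [corpus_profiles()]).
#' @param smooth Use the smoothed idf variant.  Default `FALSE`.
#' @return A list with `stats` (data.frame: `doc`, `term`, `tf`, `df`,
#'   `tf_idf`), `n_docs`, and `convention` (a string recording the formula
#'   used).
#' @export
corpus_statistics <- function(profiles, smooth = FALSE) {
  if (length(profiles) == 0L) stop("empty corpus: at least one profile required")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles)))) {
    stop("profiles must be named by document id")
  }
  N <- length(profiles)
  docs <- rep(names(profiles), vapply(profiles, length, integer(1)))
  terms <- unlist(lapply(profiles, names), use.names = FALSE)
  tf <- unlist(profiles, use.names = FALSE)
  if (length(terms) == 0L) {
    stats <- data.frame(doc = character(), term = character(),
                        tf = integer(), df = integer(), tf_idf = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    df_tab <- table(unlist(lapply(profiles, names), use.names = FALSE))
    df <- as.integer(df_tab[terms])
    idf <- if (smooth) log((1 + N) / (1 + df)) + 1 else log(N / df)
    stats <- data.frame(doc = docs, term = terms, tf = as.integer(tf),
                        df = df, tf_idf = tf * idf,
                        stringsAsFactors = FALSE)
    rownames(stats) <- NULL
  }
  list(stats = stats, n_docs = N,
       convention = if (smooth) "tf * (ln((1+N)/(1+df)) + 1)"
       else "tf * ln(N/df), raw counts, unsmoothed")
}

#' Vocabulary summary for a corpus
#'
#' Counts the distinct unigrams, bigrams and trigrams over a list of
#' N-gram profiles and lists the `top_k` most frequent terms (total count
#' descending, ties broken lexicographically).
#'
#' @param profiles Named list of N-gram count vectors.
#' @param top_k Number of top terms to report (truncated to the vocabulary
#'   size).
#' @return List with `n_unigrams`, `n_bigrams`, `n_trigrams`, and
#'   `top_terms` (data.frame: `term`, `order`, `count`).
#' @export
vocabulary_summary <- function(profiles, top_k = 20L) {
  all_terms <- unlist(lapply(profiles, names), use.names = FALSE)
  all_counts <- unlist(profiles, use.names = FALSE)
  if (length(all_terms) == 0L) {
    return(list(n_unigrams = 0L, n_bigrams = 0L, n_trigrams = 0L,
                top_terms = data.frame(term = character(),
                                       order = integer(),
                                       count = integer(),
                                       stringsAsFactors = FALSE)))
  }
  totals <- tapply(all_counts, all_terms, sum)
  terms <- names(totals)
  ord <- lengths(strsplit(terms, " ", fixed = TRUE))
  o <- order(-as.integer(totals), terms)
  k <- min(as.integer(top_k), length(terms))
  top <- data.frame(term = terms[o][seq_len(k)],
                    order = as.integer(ord[o][seq_len(k)]),
                    count = as.integer(totals[o][seq_len(k)]),
                    stringsAsFactors = FALSE)
  list(n_unigrams = sum(ord == 1L), n_bigrams = sum(ord == 2L),
       n_trigrams = sum(ord == 3L), top_terms = top)
}
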