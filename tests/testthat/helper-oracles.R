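# Independent oracles and random-instance generators used across the
# suite.  Each oracle is deliberately implemented with a different
# strategy from the package function it checks.

# Greedy longest-match scoring, re-implemented as an explicit
# consume-and-restart scan over a score lookup table (no precomputed
# window vectors, no match()).
oracle_greedy_score <- function(tokens, lexicon) {
  keys <- lexicon$ngram
  vals <- lexicon$score
  total <- 0L
  n_matches <- 0L
  i <- 1
  while (i <= length(tokens)) {
    matched_len <- 0
    for (len in c(3, 2, 1)) {
      if (i + len - 1 > length(tokens)) next
      cand <- paste(tokens[seq(i, i + len - 1)], collapse = " ")
      k <- which(keys == cand)
      if (length(k) == 1) {
        total <- total + vals[k]
        n_matches <- n_matches + 1L
        matched_len <- len
        break
      }
    }
    i <- i + if (matched_len > 0) matched_len else 1
  }
  list(score = total, n_matches = n_matches)
}

# All-matches scoring by exhaustive window enumeration.
oracle_all_score <- function(tokens, lexicon) {
  total <- 0L
  for (len in 1:3) {
    if (length(tokens) < len) next
    for (i in seq_len(length(tokens) - len + 1)) {
      cand <- paste(tokens[seq(i, i + len - 1)], collapse = " ")
      k <- which(lexicon$ngram == cand)
      if (length(k) == 1) total <- total + lexicon$score[k]
    }
  }
  total
}

# N-gram counting by substring enumeration into an environment.
oracle_ngram_counts <- function(tokens, max_n) {
  env <- new.env(parent = emptyenv())
  for (n in seq_len(max_n)) {
    if (length(tokens) < n) next
    for (i in seq_len(length(tokens) - n + 1)) {
      key <- paste(tokens[seq(i, i + n - 1)], collapse = " ")
      env[[key]] <- (if (is.null(env[[key]])) 0L else env[[key]]) + 1L
    }
  }
  out <- vapply(ls(env), function(k) env[[k]], integer(1))
  out[order(names(out))]
}

# AUC by exhaustive concordance counting over all (positive, negative)
# pairs, ties half credit.
oracle_auc <- function(predicted, labels) {
  pos <- predicted[as.logical(labels)]
  neg <- predicted[!as.logical(labels)]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  conc <- 0
  for (p in pos) for (q in neg) {
    conc <- conc + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  conc / (length(pos) * length(neg))
}

# Per-category emotion recount: loop over lexicon words, sum exact
# token equality.
oracle_emotion_counts <- function(tokens, emotion_lexicon) {
  cats <- c("anger", "anticipation", "disgust", "fear", "joy", "sadness",
            "surprise", "trust", "positive", "negative")
  out <- stats::setNames(numeric(length(cats)), cats)
  for (w in names(emotion_lexicon)) {
    hits <- sum(tokens == w)
    if (hits > 0) {
      for (cc in emotion_lexicon[[w]]) out[cc] <- out[cc] + hits
    }
  }
  out
}

# Confusion-matrix recount at a given prediction cut.
oracle_confusion <- function(predicted, labels, cut) {
  labels <- as.logical(labels)
  tp <- sum(predicted > cut & labels)
  fn <- sum(predicted <= cut & labels)
  tn <- sum(predicted <= cut & !labels)
  fp <- sum(predicted > cut & !labels)
  list(sens = tp / (tp + fn), spec = tn / (tn + fp),
       acc = (tp + tn) / length(labels))
}

random_word_vocab <- function(n) {
  sprintf("w%02d", seq_len(n))
}

random_tokens <- function(len, vocab) {
  if (len == 0) return(character(0))
  sample(vocab, len, replace = TRUE)
}

# Random valid openness lexicon over a vocabulary: unique 1-3-gram keys,
# integer scores in [-3, 3].
random_openness_lexicon <- function(n_entries, vocab) {
  keys <- character(0)
  guard <- 0
  while (length(keys) < n_entries && guard < 50 * n_entries) {
    guard <- guard + 1
    ord <- sample(1:3, 1)
    keys <- unique(c(keys, paste(sample(vocab, ord, replace = FALSE),
                                 collapse = " ")))
  }
  openness_lexicon(keys, sample(-3:3, length(keys), replace = TRUE))
}
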