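#' Score a narrative against the openness lexicon
#'
#' Matches N-grams in a token sequence against the lexicon and sums the
#' scores of the matches.  Two overlap policies are available:
#'
#' * `"greedy"` (default): longest-match-first, left-to-right,
#'   non-overlapping.  At each position the longest lexicon entry
#'   (trigram before bigram before unigram) starting there is taken and
#'   its tokens are consumed, so each token participates in at most one
#'   match and sub-N-grams of a match never score.
#' * `"all"`: every N-gram window occurrence that is a lexicon key scores
#'   independently (overlaps and nestings all count).
#'
#' Every *occurrence* of a matched N-gram contributes its score once per
#' occurrence.  An empty sequence scores 0.
#'
#' @param tokens Character vector of tokens normalized by the same
#'   convention as the lexicon (see [tokenize()]).
#' @param lexicon An [openness_lexicon()].
#' @param policy `"greedy"` or `"all"`.
#' @return List with `score` (integer), `matches` (data.frame: `ngram`,
#'   `position`, `score`), and `policy`.
#' @export
#' @examples
#' lex <- openness_lexicon(c("open conversation", "not talk", "talk"),
#'                         c(3L, -2L, 1L))
#' score_narrative(c("we", "had", "open", "conversation", "but", "he",
#'                   "would", "not", "talk"), lex)
score_narrative <- function(tokens, lexicon, policy = c("greedy", "all")) {
  policy <- match.arg(policy)
  stopifnot(inherits(lexicon, "openness_lexicon"))
  L <- length(tokens)
  m_ngram <- character(0); m_pos <- integer(0); m_score <- integer(0)
  if (L > 0L) {
    # vectorized window keys per order, matched against lexicon keys once
    win <- vector("list", 3L)
    hit <- vector("list", 3L)  # hit[[n]][i]: lexicon row of the order-n
    for (n in 1:3) {           # window starting at i, NA if no entry
      if (L < n) { hit[[n]] <- integer(0); next }
      idx <- seq_len(L - n + 1L)
      keys <- if (n == 1L) tokens else
        do.call(paste, lapply(seq_len(n) - 1L, function(k) tokens[idx + k]))
      win[[n]] <- keys
      hit[[n]] <- match(keys, lexicon$ngram)
    }
    if (policy == "greedy") {
      i <- 1L
      res_row <- integer(0)
      while (i <= L) {
        adv <- 1L
        for (n in 3:1) {
          if (i + n - 1L > L) next
          r <- hit[[n]][i]
          if (!is.na(r)) {
            res_row <- c(res_row, r)
            m_pos <- c(m_pos, i)
            adv <- n
            break
          }
        }
        i <- i + adv
      }
      m_ngram <- lexicon$ngram[res_row]
      m_score <- lexicon$score[res_row]
    } else {
      for (n in 1:3) {
        found <- which(!is.na(hit[[n]]))
        rows <- hit[[n]][found]
        m_ngram <- c(m_ngram, win[[n]][found])
        m_pos <- c(m_pos, found)
        m_score <- c(m_score, lexicon$score[rows])
      }
    }
  }
  matches <- data.frame(ngram = m_ngram, position = m_pos,
                        score = m_score, stringsAsFactors = FALSE)
  list(score = sum(matches$score), matches = matches, policy = policy)
}

#' Score a corpus of narratives
#'
#' Applies [score_narrative()] to every narrative and summarises the
#' distribution of openness scores (sample SD, n - 1 denominator; for a
#' single narrative the SD is reported as 0 and flagged degenerate).
#'
#' @param narratives Data.frame as from [read_narratives()].
#' @param lexicon An [openness_lexicon()].
#' @param stopwords Stopword list for [tokenize()].
#' @param policy Overlap policy, see [score_narrative()].
#' @return List with `scores` (data.frame: `narrative_id`, `subject_id`,
#'   `openness_score`, `n_matches`) and `summary` (`mean`, `sd`, `min`,
#'   `max`, `n`, `degenerate`).
#' @export
score_corpus <- function(narratives, lexicon,
                         stopwords = default_stopwords(),
                         policy = c("greedy", "all")) {
  policy <- match.arg(policy)
  res <- lapply(narratives$text, function(tx) {
    score_narrative(tokenize(tx, stopwords), lexicon, policy = policy)
  })
  sc <- vapply(res, function(r) r$score, numeric(1))
  nm <- vapply(res, function(r) nrow(r$matches), integer(1))
  scores <- data.frame(narrative_id = narratives$id,
                       subject_id = narratives$subject_id,
                       openness_score = as.integer(sc),
                       n_matches = nm, stringsAsFactors = FALSE)
  n <- length(sc)
  degenerate <- n < 2L
  summ <- list(mean = if (n > 0) mean(sc) else NA_real_,
               sd = if (degenerate) 0 else stats::sd(sc),
               min = if (n > 0) min(sc) else NA_real_,
               max = if (n > 0) max(sc) else NA_real_,
               n = n, degenerate = degenerate)
  list(scores = scores, summary = summ)
}
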