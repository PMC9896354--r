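#' Construct an openness-of-communication lexicon
#'
#' The openness lexicon maps N-grams (1 to 3 space-joined lowercase
#' tokens) to integer scores on a seven-point scale from -3 (extremely
#' strong negative with respect to open communication) to +3 (extremely
#' strong positive).  When two independent rater scores are supplied, the
#' consensus score must equal [merge_rater_scores()] applied to them.
#'
#' @param ngram Character vector of N-gram keys (normalized as by
#'   [normalize_ngram()]; keys must be unique and have 1-3 tokens).
#' @param score Integer scores in `[-3, 3]`.
#' @param rater1,rater2 Optional per-rater scores in `[-3, 3]`.
#' @param source Optional provenance tag per entry
#'   (`"corpus"`, `"enrichment"`, or `"thesaurus"`).
#' @return An object of class `openness_lexicon`: a data.frame with
#'   columns `ngram`, `score` (and `rater1`, `rater2`, `source` when
#'   given) plus a `counts` attribute giving entries per N-gram order.
#' @export
#' @examples
#' openness_lexicon(c("open conversation", "not talk"), c(3L, -2L))
openness_lexicon <- function(ngram, score, rater1 = NULL, rater2 = NULL,
                             source = NULL) {
  ngram <- as.character(ngram)
  score <- as.integer(score)
  if (length(ngram) != length(score)) {
    stop("ngram and score must have equal length")
  }
  norm <- normalize_ngram(ngram)
  bad <- which(norm != ngram)
  if (length(bad) > 0L) {
    stop("ngram not normalized to tokenizer convention: ",
         paste(utils::head(ngram[bad], 5), collapse = ", "))
  }
  ord <- lengths(strsplit(ngram, " ", fixed = TRUE))
  if (any(ord < 1L | ord > 3L)) {
    stop("each ngram must have 1, 2, or 3 tokens")
  }
  dup <- ngram[duplicated(ngram)]
  if (length(dup) > 0L) {
    stop("duplicate ngram key(s): ", paste(unique(dup), collapse = ", "))
  }
  if (any(is.na(score) | score < -3L | score > 3L)) {
    stop("scores must be integers in [-3, 3]")
  }
  lex <- data.frame(ngram = ngram, score = score, stringsAsFactors = FALSE)
  if (!is.null(rater1) || !is.null(rater2)) {
    if (is.null(rater1) || is.null(rater2)) {
      stop("rater1 and rater2 must be supplied together")
    }
    rater1 <- as.integer(rater1); rater2 <- as.integer(rater2)
    if (any(is.na(rater1) | rater1 < -3L | rater1 > 3L) ||
        any(is.na(rater2) | rater2 < -3L | rater2 > 3L)) {
      stop("rater scores must be integers in [-3, 3]")
    }
    merged <- mapply(merge_rater_scores, rater1, rater2)
    bad <- which(merged != score)
    if (length(bad) > 0L) {
      stop("score inconsistent with rater merge rule for: ",
           paste(ngram[bad], collapse = ", "))
    }
    lex$rater1 <- rater1
    lex$rater2 <- rater2
  }
  if (!is.null(source)) {
    source <- as.character(source)
    ok <- is.na(source) | source %in% c("corpus", "enrichment", "thesaurus")
    if (!all(ok)) {
      stop("source must be one of corpus, enrichment, thesaurus")
    }
    lex$source <- source
  }
  rownames(lex) <- NULL
  attr(lex, "counts") <- c(`1` = sum(ord == 1L), `2` = sum(ord == 2L),
                           `3` = sum(ord == 3L))
  class(lex) <- c("openness_lexicon", "data.frame")
  lex
}

#' @export
print.openness_lexicon <- function(x, ...) {
  cnt <- attr(x, "counts")
  cat("Openness-of-communication lexicon: ", nrow(x), " entries (",
      cnt[["1"]], " unigrams, ", cnt[["2"]], " bigrams, ", cnt[["3"]],
      " trigrams)\n", sep = "")
  cat("Score range observed: [", min(x$score), ", ", max(x$score), "]\n",
      sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more entries\n")
  invisible(x)
}

#' Merge two rater scores into a consensus score
#'
#' Disagreements are resolved by averaging the two scores and, when the
#' mean falls between two integers, taking the greater of the two nearest
#' integers (the ceiling): mean 2.5 becomes 3, mean -2.5 becomes -2.
#'
#' @param a,b Integer scores in `[-3, 3]`.
#' @return The consensus integer score in `[-3, 3]`.
#' @export
#' @examples
#' merge_rater_scores(2, 3)    # 3
#' merge_rater_scores(-3, -2)  # -2
merge_rater_scores <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      a < -3L || a > 3L || b < -3L || b > 3L) {
    stop("rater scores must be single integers in [-3, 3]")
  }
  as.integer(ceiling((a + b) / 2))
}

#' List candidate N-grams for manual rating
#'
#' Returns every N-gram whose total corpus count reaches `min_count`,
#' ordered by count descending with lexicographic tie-break.  The output
#' is intended for human raters; no scores are assigned.
#'
#' @param profiles Named list of N-gram count vectors
#'   (see [corpus_profiles()]).
#' @param min_count Minimum total occurrence count (>= 1).
#' @return Data.frame with columns `ngram`, `count`.
#' @export
build_candidates <- function(profiles, min_count = 1L) {
  min_count <- as.integer(min_count)
  if (is.na(min_count) || min_count < 1L) stop("min_count must be >= 1")
  all_terms <- unlist(lapply(profiles, names), use.names = FALSE)
  all_counts <- unlist(profiles, use.names = FALSE)
  if (length(all_terms) == 0L) {
    return(data.frame(ngram = character(), count = integer(),
                      stringsAsFactors = FALSE))
  }
  totals <- tapply(all_counts, all_terms, sum)
  keep <- totals >= min_count
  terms <- names(totals)[keep]
  counts <- as.integer(totals[keep])
  o <- order(-counts, terms)
  data.frame(ngram = terms[o], count = counts[o], stringsAsFactors = FALSE)
}

#' Read / write an openness lexicon as TSV
#'
#' The file format is UTF-8 tab-separated text with a header line
#' `ngram<TAB>score` and optional `rater1`, `rater2`, `source` columns.
#' Save followed by load reproduces the lexicon exactly.  Malformed rows,
#' out-of-range scores, duplicate keys and rater/score inconsistencies
#' are reported with their line number.
#'
#' @param path File path.
#' @return `load_lexicon()` returns an [openness_lexicon()];
#'   `save_lexicon()` returns `path` invisibly.
#' @export
load_lexicon <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           fileEncoding = "UTF-8", quote = "")
  if (!all(c("ngram", "score") %in% names(raw))) {
    stop("lexicon TSV must have columns ngram and score")
  }
  line_of <- function(i) i + 1L  # header occupies line 1
  if (any(is.na(raw$ngram) | !nzchar(raw$ngram))) {
    i <- which(is.na(raw$ngram) | !nzchar(raw$ngram))[1]
    stop("line ", line_of(i), ": empty ngram")
  }
  sc <- suppressWarnings(as.integer(raw$score))
  if (any(is.na(sc))) {
    stop("line ", line_of(which(is.na(sc))[1]), ": non-integer score")
  }
  if (any(sc < -3L | sc > 3L)) {
    stop("line ", line_of(which(sc < -3L | sc > 3L)[1]),
         ": score outside [-3, 3]")
  }
  dup <- which(duplicated(raw$ngram))
  if (length(dup) > 0L) {
    stop("line ", line_of(dup[1]), ": duplicate ngram '",
         raw$ngram[dup[1]], "'")
  }
  has_raters <- all(c("rater1", "rater2") %in% names(raw))
  if (has_raters) {
    r1 <- as.integer(raw$rater1); r2 <- as.integer(raw$rater2)
    merged <- mapply(merge_rater_scores, r1, r2)
    bad <- which(merged != sc)
    if (length(bad) > 0L) {
      stop("line ", line_of(bad[1]), ": score ", sc[bad[1]],
           " inconsistent with raters (", r1[bad[1]], ", ", r2[bad[1]],
           ") -> ", merged[bad[1]])
    }
    openness_lexicon(raw$ngram, sc, rater1 = r1, rater2 = r2,
                     source = if ("source" %in% names(raw)) raw$source)
  } else {
    openness_lexicon(raw$ngram, sc,
                     source = if ("source" %in% names(raw)) raw$source)
  }
}

#' @param lexicon An [openness_lexicon()].
#' @rdname load_lexicon
#' @export
save_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "openness_lexicon"))
  df <- as.data.frame(lexicon)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  if (length(lines) > 0L) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}
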