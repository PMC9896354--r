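#' Read subject records
#'
#' Subject covariates come as CSV with one row per subject.  Expected
#' columns: `subject_id`; `age` (years); `sex` (`female`/`male`);
#' `education` (`elementary_high_school`, `high_school_graduate`,
#' `technical_school_graduate`, `university_postgraduate`);
#' `marital_status` (`married`, `single`, `divorced_separated_widowed`);
#' `employed` (0/1); `cancer_status` (`affected`/`unaffected`);
#' `test_result` (`positive`/`negative`); the 7-point Likert items
#' `informational_support`, `communication_preference`,
#' `perceived_utility`; optionally `iri_total`.
#'
#' @param path CSV file path.
#' @return Data.frame of subject records.
#' @export
read_subjects <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- c("subject_id", "age", "sex", "education", "marital_status",
            "employed", "cancer_status", "test_result",
            "informational_support", "communication_preference",
            "perceived_utility")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("subjects CSV missing column(s): ", paste(miss, collapse = ", "))
  }
  for (lik in c("informational_support", "communication_preference",
                "perceived_utility")) {
    v <- df[[lik]]
    if (any(!is.na(v) & (v < 1 | v > 7))) {
      stop(lik, " must lie in 1..7")
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' Assemble the subject-level feature table
#'
#' Joins subject covariates, per-narrative sentiment features and the
#' openness outcome into one modelling table (one row per subject).
#' Categorical covariates are collapsed to indicators: `single` (vs any
#' other marital status), `academic` (university/postgraduate education
#' vs the rest), `sex_female`, `cancer`, `test_positive`.  Column order
#' is fixed: `subject_id`, `single`, `academic`, `age`, `sex_female`,
#' `employed`, `cancer`, `test_positive`, the three Likert items, the
#' sentiment features, optional `iri_total`, then `openness`.
#'
#' Every subject must have exactly one narrative's scores; mismatches are
#' reported by id.  Rows with missing covariates are dropped
#' (complete-case analysis) with a message.
#'
#' @param subjects Data.frame from [read_subjects()].
#' @param sentiment Data.frame from [sentiment_features()].
#' @param scores Scores data.frame from [score_corpus()] (`$scores`).
#' @param include_valence Keep `valence_sum`/`polarity_pos`/
#'   `polarity_neg` columns if present.  Default `FALSE`: the emotion
#'   lexicon family drives the default model (the valence and polarity
#'   families are near-duplicates of each other and add collinearity).
#' @return Data.frame feature table.
#' @export
assemble_features <- function(subjects, sentiment, scores,
                              include_valence = FALSE) {
  sid <- subjects$subject_id
  no_score <- setdiff(sid, scores$subject_id)
  no_subj <- setdiff(scores$subject_id, sid)
  if (length(no_score) > 0L) {
    stop("subject(s) without narrative scores: ",
         paste(no_score, collapse = ", "))
  }
  if (length(no_subj) > 0L) {
    stop("narrative scores without subject record: ",
         paste(no_subj, collapse = ", "))
  }
  if (anyDuplicated(scores$subject_id)) {
    stop("multiple narratives per subject: ",
         paste(unique(scores$subject_id[duplicated(scores$subject_id)]),
               collapse = ", "))
  }
  no_sent <- setdiff(sid, sentiment$subject_id)
  if (length(no_sent) > 0L) {
    stop("subject(s) without sentiment features: ",
         paste(no_sent, collapse = ", "))
  }
  srow <- match(sid, scores$subject_id)
  erow <- match(sid, sentiment$subject_id)
  tab <- data.frame(
    subject_id = sid,
    single = as.integer(subjects$marital_status == "single"),
    academic = as.integer(subjects$education == "university_postgraduate"),
    age = subjects$age,
    sex_female = as.integer(subjects$sex == "female"),
    employed = as.integer(subjects$employed),
    cancer = as.integer(subjects$cancer_status == "affected"),
    test_positive = as.integer(subjects$test_result == "positive"),
    informational_support = subjects$informational_support,
    communication_preference = subjects$communication_preference,
    perceived_utility = subjects$perceived_utility,
    stringsAsFactors = FALSE
  )
  sent_cols <- c("anger", "anticipation", "disgust", "fear", "joy",
                 "sadness", "surprise", "trust", "nrc_pos", "nrc_neg",
                 "net_sentiment")
  if (include_valence) {
    sent_cols <- c(sent_cols,
                   intersect(c("valence_sum", "polarity_pos",
                               "polarity_neg"), names(sentiment)))
  }
  for (cc in sent_cols) tab[[cc]] <- sentiment[[cc]][erow]
  if ("iri_total" %in% names(subjects)) {
    tab$iri_total <- subjects$iri_total
  }
  tab$openness <- scores$openness_score[srow]
  if (any(is.na(tab$openness))) {
    stop("missing openness outcome for subject(s): ",
         paste(tab$subject_id[is.na(tab$openness)], collapse = ", "))
  }
  core <- setdiff(names(tab), "iri_total")
  cc_ok <- stats::complete.cases(tab[core])
  if (!all(cc_ok)) {
    message("dropping ", sum(!cc_ok),
            " subject(s) with missing covariates (complete-case)")
    tab <- tab[cc_ok, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Default model candidate predictors
#'
#' The candidate set offered to the stepwise fit: the encoded
#' demographic/clinical covariates, the Likert survey items, the eight
#' emotion counts and the net sentiment.  The raw positive/negative
#' totals are excluded (net sentiment is their difference) as are id,
#' outcome and any external-validation column.
#'
#' @param table Feature table from [assemble_features()].
#' @return Character vector of column names.
#' @export
default_predictors <- function(table) {
  setdiff(names(table),
          c("subject_id", "openness", "iri_total", "nrc_pos", "nrc_neg",
            "valence_sum", "polarity_pos", "polarity_neg"))
}

#' Filter collinear predictors
#'
#' Removes predictors so that no remaining unordered pair has absolute
#' Pearson correlation above `threshold` (strictly greater; a pair at
#' exactly the threshold is kept).  Constant (zero-variance) columns are
#' dropped first with a warning.  Offending pairs are processed from the
#' largest |r| down; within a pair, the member with the larger mean
#' absolute correlation to all other predictors is dropped, with ties
#' going against the later column in schema order.  The procedure only
#' looks at the correlation matrix, so the result is invariant to row
#' order.
#'
#' @param table Feature table (or any data.frame).
#' @param predictors Columns to consider.  Defaults to
#'   [default_predictors()].
#' @param threshold Absolute-correlation cutoff in (0, 1]; default 0.60.
#' @return List with `kept` (character), `dropped` (data.frame:
#'   `dropped`, `kept_partner`, `r`), and `constant` (character,
#'   zero-variance columns removed up front).
#' @export
collinearity_filter <- function(table, predictors = default_predictors(table),
                                threshold = 0.60) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must lie in (0, 1]")
  }
  x <- as.matrix(table[predictors])
  storage.mode(x) <- "double"
  sds <- apply(x, 2, stats::sd)
  constant <- predictors[sds == 0 | is.na(sds)]
  if (length(constant) > 0L) {
    warning("dropping zero-variance column(s): ",
            paste(constant, collapse = ", "))
  }
  active <- setdiff(predictors, constant)
  dropped <- data.frame(dropped = character(), kept_partner = character(),
                        r = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(active) < 2L) break
    cm <- stats::cor(x[, active, drop = FALSE])
    diag(cm) <- 0
    amax <- max(abs(cm))
    # strict comparison with a float guard: a pair at exactly the
    # threshold is kept
    if (amax <= threshold + 1e-9) break
    hit <- which(abs(cm) == amax, arr.ind = TRUE)
    # first offending pair in schema order (row-major over upper triangle)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    hit <- hit[order(hit[, 1], hit[, 2]), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    mean_abs <- rowMeans(abs(cm)) * length(active) / (length(active) - 1)
    victim <- if (mean_abs[i] > mean_abs[j]) i
              else if (mean_abs[j] > mean_abs[i]) j
              else j  # tie: later column in schema order
    dropped <- rbind(dropped, data.frame(
      dropped = active[victim],
      kept_partner = active[if (victim == i) j else i],
      r = cm[i, j], stringsAsFactors = FALSE))
    active <- active[-victim]
  }
  rownames(dropped) <- NULL
  list(kept = active, dropped = dropped, constant = constant)
}
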