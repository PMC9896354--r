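#' Bundled fixture corpus
#'
#' A small frozen synthetic cohort (12 subjects) committed with the
#' package and used for golden-file tests and examples.  The files were
#' produced by [simulate_cohort()] under [fixture_sim_config()] and are
#' byte-identical to what that call regenerates.
#'
#' @return `fixture_corpus()`: list with `subjects`, `narratives`,
#'   `truth` (data.frames read from the committed files).
#'   `fixture_sim_config()`: the [sim_config()] that generated them — a
#'   deliberately scaled-down configuration (400-token narratives,
#'   smaller planted counts) so the fixture stays small.
#' @export
fixture_sim_config <- function() {
  sim_config(n_subjects = 12L, seed = 104729L, mean_tokens = 400L,
             filler_vocab_size = 1500L,
             emotion_lambda = c(anger = 3, anticipation = 10, disgust = 4,
                                joy = 9, sadness = 11, surprise = 2,
                                trust = 18),
             fear_mean = 20, fear_sd = 8, net_mean = 10, net_sd = 8,
             polarity_base = 8L)
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "famcomm")
  if (!nzchar(p)) stop("fixture file not found: ", file)
  p
}

#' @rdname fixture_sim_config
#' @export
fixture_corpus <- function() {
  list(subjects = read_subjects(fixture_path("fixture_subjects.csv")),
       narratives = read_narratives(fixture_path("fixture_narratives.jsonl")),
       truth = utils::read.csv(fixture_path("fixture_truth.csv"),
                               stringsAsFactors = FALSE))
}

# Regenerate the committed fixture files into `dir` (canonical
# formatting, LF endings).  Used once to create inst/extdata and by the
# tests to prove the committed files match the generator.
write_fixture_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- simulate_cohort(fixture_sim_config())
  write_canonical_csv(co$subjects, file.path(dir, "fixture_subjects.csv"))
  write_narratives(co$narratives, file.path(dir, "fixture_narratives.jsonl"))
  tr <- co$truth
  tr$latent_openness <- sprintf("%.10g", tr$latent_openness)
  write_canonical_csv(tr, file.path(dir, "fixture_truth.csv"))
  save_lexicon(demo_openness_lexicon(),
               file.path(dir, "demo_openness_lexicon.tsv"))
  emo <- demo_emotion_lexicon()
  emo_df <- data.frame(word = rep(names(emo), lengths(emo)),
                       category = unlist(emo, use.names = FALSE),
                       flag = 1L, stringsAsFactors = FALSE)
  write_canonical_tsv(emo_df, file.path(dir, "demo_emotion_lexicon.tsv"))
  val <- demo_valence_lexicon()
  write_canonical_tsv(data.frame(word = names(val), score = as.integer(val),
                                 stringsAsFactors = FALSE),
                      file.path(dir, "demo_valence_lexicon.tsv"))
  pol <- demo_polarity_lexicon()
  write_canonical_tsv(data.frame(word = names(pol),
                                 polarity = unname(pol),
                                 stringsAsFactors = FALSE),
                      file.path(dir, "demo_polarity_lexicon.tsv"))
  invisible(dir)
}

write_canonical_csv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = ","), con, useBytes = TRUE)
  lines <- do.call(paste, c(lapply(df, as.character), sep = ","))
  if (length(lines) > 0L) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

write_canonical_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con, useBytes = TRUE)
  lines <- do.call(paste, c(lapply(df, as.character), sep = "\t"))
  if (length(lines) > 0L) writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Deterministic JSON report for a pipeline run
#'
#' Serializes the openness scores, the selected model and the
#' split-sample metrics of a [run_pipeline()] result into a canonical
#' JSON string (fixed digit count, stable key order), so that identical
#' analyses produce byte-identical reports.  Used for golden-file
#' regression tests.
#'
#' @param result A [run_pipeline()] result with `evaluation`.
#' @return A single JSON string.
#' @export
pipeline_report_json <- function(result) {
  ev <- result$evaluation
  fit <- ev$fit
  metr <- function(m) {
    if (is.null(m)) return(NULL)
    list(n = m$n, rmse = m$rmse, auc = m$auc,
         sensitivity = m$sensitivity, specificity = m$specificity,
         accuracy = m$accuracy, cut = m$cut)
  }
  rep <- list(
    scores = result$scores$scores[c("narrative_id", "subject_id",
                                    "openness_score", "n_matches")],
    score_summary = result$scores$summary[c("mean", "sd", "min", "max",
                                            "n")],
    collinearity_dropped = fit$collinearity$dropped,
    selected = as.list(fit$selected),
    coefficients = fit$coefficients,
    r_squared = fit$r.squared,
    adj_r_squared = fit$adj.r.squared,
    threshold = ev$threshold,
    split = list(seed = ev$split$seed,
                 train_fraction = ev$split$train_fraction,
                 train_ids = ev$split$train_ids,
                 test_ids = ev$split$test_ids),
    train = metr(ev$train),
    test = metr(ev$test)
  )
  as.character(jsonlite::toJSON(rep, digits = NA, auto_unbox = TRUE,
                                pretty = TRUE, na = "null"))
}
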