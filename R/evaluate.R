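#' Random train/test split of subject ids
#'
#' Draws a uniform random split, deterministic given (ids, seed).  The
#' training set has `floor(train_fraction * n)` members.
#'
#' @param ids Character vector of subject ids.
#' @param train_fraction Fraction assigned to training (default 0.70).
#' @param seed Integer seed.
#' @return List of class `split_spec`: `train_ids`, `test_ids`,
#'   `train_fraction`, `seed`, `empty_test` flag.
#' @export
make_split <- function(ids, train_fraction = 0.70, seed = 1L) {
  n <- length(ids)
  if (n < 3L) stop("need at least 3 subjects to split")
  if (!(train_fraction > 0 && train_fraction <= 1)) {
    stop("train_fraction must lie in (0, 1]")
  }
  n_train <- floor(train_fraction * n)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  train <- sort(sample.int(n, n_train))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out <- list(train_ids = ids[train], test_ids = ids[-train],
              train_fraction = train_fraction, seed = as.integer(seed),
              empty_test = n_train == n)
  if (out$empty_test) warning("train_fraction leaves an empty test set")
  class(out) <- "split_spec"
  out
}

#' Root mean square error
#'
#' @param predicted,observed Equal-length numeric vectors (length >= 1).
#' @return `sqrt(mean((predicted - observed)^2))`.
#' @export
rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed) || length(predicted) < 1L) {
    stop("predicted and observed must have equal length >= 1")
  }
  sqrt(mean((predicted - observed)^2))
}

#' Rank-based AUC (probability of concordance)
#'
#' Mann-Whitney AUC: the probability that a randomly chosen positive
#' receives a higher prediction than a randomly chosen negative, with
#' ties counted half.
#'
#' @param predicted Numeric prediction scores.
#' @param labels Logical (or 0/1) class labels; `TRUE` = positive.
#' @return AUC in `[0, 1]`, or `NA` if one class is absent.
#' @export
auc_rank <- function(predicted, labels) {
  labels <- as.logical(labels)
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) return(NA_real_)
  r <- rank(predicted)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classification metrics for a continuous outcome
#'
#' Binarizes the observed outcome at `threshold` (positive class =
#' strictly above), then reports the rank-based AUC of the predictions
#' and sensitivity/specificity/accuracy at the prediction cut that
#' maximizes Youden's J (sensitivity + specificity - 1).  Candidate cuts
#' are midpoints between adjacent distinct prediction values plus
#' outside sentinels; ties on J resolve to the lowest cut.
#'
#' @param predicted Numeric predictions.
#' @param observed Numeric observed outcomes.
#' @param threshold Outcome binarization threshold (e.g. the
#'   training-set median openness).
#' @return List: `auc`, `sensitivity`, `specificity`, `accuracy`,
#'   `cut` (the operating point on the prediction scale), `threshold`,
#'   `n_pos`, `n_neg`, `degenerate` (TRUE when one class is absent, in
#'   which case the metrics are `NA`).
#' @export
binary_metrics <- function(predicted, observed, threshold) {
  if (length(predicted) != length(observed)) stop("length mismatch")
  labels <- observed > threshold
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    return(list(auc = NA_real_, sensitivity = NA_real_,
                specificity = NA_real_, accuracy = NA_real_,
                cut = NA_real_, threshold = threshold,
                n_pos = n_pos, n_neg = n_neg, degenerate = TRUE))
  }
  auc <- auc_rank(predicted, labels)
  sp <- sort(unique(predicted))
  cuts <- c(sp[1] - 1, if (length(sp) > 1) (sp[-1] + sp[-length(sp)]) / 2,
            sp[length(sp)] + 1)
  best <- list(j = -Inf, cut = NA_real_, sens = NA_real_, spec = NA_real_,
               acc = NA_real_)
  for (ct in cuts) {
    pred_pos <- predicted > ct
    sens <- sum(pred_pos & labels) / n_pos
    spec <- sum(!pred_pos & !labels) / n_neg
    j <- sens + spec - 1
    if (j > best$j) {
      best <- list(j = j, cut = ct, sens = sens, spec = spec,
                   acc = mean(pred_pos == labels))
    }
  }
  list(auc = auc, sensitivity = best$sens, specificity = best$spec,
       accuracy = best$acc, cut = best$cut, threshold = threshold,
       n_pos = n_pos, n_neg = n_neg, degenerate = FALSE)
}

#' Pearson correlation with an external scale
#'
#' Validates the lexicon-derived openness score against an externally
#' supplied total (e.g. a disclosure-intention inventory).
#'
#' @param openness_scores,external_totals Paired numeric vectors
#'   (n >= 3; pairs with a missing external total are dropped).
#' @return List: `r` (sample Pearson correlation, `NA` if either side
#'   has zero variance), `n`, `degenerate`.
#' @export
external_correlation <- function(openness_scores, external_totals) {
  if (length(openness_scores) != length(external_totals)) {
    stop("length mismatch")
  }
  ok <- stats::complete.cases(openness_scores, external_totals)
  x <- openness_scores[ok]; y <- external_totals[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, n = length(x), degenerate = TRUE))
  }
  list(r = stats::cor(x, y), n = length(x), degenerate = FALSE)
}

#' Split-sample evaluation of the openness model
#'
#' Splits the feature table, fits [openness_fit()] on the training rows,
#' and reports RMSE plus classification metrics ([binary_metrics()]) on
#' both splits.  The outcome is binarized at the *training-set median*
#' openness for both splits.
#'
#' @param table Feature table from [assemble_features()].
#' @param split_seed Seed for [make_split()].
#' @param train_fraction Training fraction (default 0.70).
#' @param ... Passed to [openness_fit()] (candidates, criterion, ...).
#' @return List of class `openness_eval`: `fit` (training
#'   [openness_fit()]), `split`, `threshold`, and `train` / `test`
#'   metric lists (`rmse`, `auc`, `sensitivity`, `specificity`,
#'   `accuracy`, `cut`, `n`).
#' @export
evaluate_openness <- function(table, split_seed = 1L,
                              train_fraction = 0.70, ...) {
  split <- make_split(table$subject_id, train_fraction = train_fraction,
                      seed = split_seed)
  tr <- table[table$subject_id %in% split$train_ids, , drop = FALSE]
  te <- table[table$subject_id %in% split$test_ids, , drop = FALSE]
  fit <- openness_fit(tr, ...)
  threshold <- stats::median(tr$openness)
  eval_one <- function(dd) {
    if (nrow(dd) == 0L) return(NULL)
    pred <- predict(fit, newdata = dd)
    m <- binary_metrics(pred, dd$openness, threshold)
    c(list(rmse = rmse(pred, dd$openness)), m, list(n = nrow(dd)))
  }
  structure(list(fit = fit, split = split, threshold = threshold,
                 train = eval_one(tr), test = eval_one(te)),
            class = "openness_eval")
}

#' @export
print.openness_eval <- function(x, ...) {
  cat("Split-sample evaluation (train fraction ",
      x$split$train_fraction, ", seed ", x$split$seed, ")\n", sep = "")
  cat("Outcome binarized at training-median openness =", x$threshold, "\n")
  fmt <- function(lbl, m) {
    if (is.null(m)) { cat(lbl, ": empty split\n", sep = ""); return() }
    cat(sprintf(
      "%s (n=%d): RMSE %.3f | AUC %.3f | sens %.3f | spec %.3f | acc %.3f\n",
      lbl, m$n, m$rmse, m$auc, m$sensitivity, m$specificity, m$accuracy))
  }
  fmt("train", x$train)
  fmt("test", x$test)
  invisible(x)
}
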