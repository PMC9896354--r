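#' Stepwise ordinary-least-squares fit
#'
#' Selects predictors of an outcome by stepwise linear regression,
#' starting from the intercept-only model.  Two stepping criteria are
#' available:
#'
#' * `"p"` (default): significance-threshold stepping.  Each forward
#'   step adds the candidate with the smallest two-tailed t-test p-value
#'   provided it is below `alpha_enter`; after every addition, included
#'   predictors whose p-value exceeds `alpha_remove` are removed
#'   (largest first).  Iterates until stable.  This matches the common
#'   description of stepwise regression as removing nonsignificant
#'   independent variables.
#' * `"aic"`: bidirectional AIC stepping via [stats::step()].
#'
#' Ties on the entry p-value are broken by candidate order, so the whole
#' trace is a deterministic function of (table, predictors, criterion).
#'
#' @param table Data.frame holding outcome and candidate columns.
#' @param outcome Name of the outcome column.
#' @param predictors Candidate predictor columns.
#' @param criterion `"p"` or `"aic"`.
#' @param alpha_enter,alpha_remove Entry/removal p-value thresholds for
#'   the `"p"` criterion (defaults 0.05 / 0.10).
#' @return List of class `stepwise_fit`: `model` (the final [stats::lm()]
#'   fit), `selected`, `coefficients` (data.frame: term, estimate, se,
#'   t, p), `r.squared`, `adj.r.squared`, `trace` (data.frame of steps),
#'   `criterion`.
#' @export
stepwise_fit <- function(table, outcome = "openness",
                         predictors, criterion = c("p", "aic"),
                         alpha_enter = 0.05, alpha_remove = 0.10) {
  criterion <- match.arg(criterion)
  stopifnot(outcome %in% names(table), all(predictors %in% names(table)))
  n <- nrow(table)
  if (n < length(predictors) + 2L) {
    stop("need at least ", length(predictors) + 2L,
         " rows for ", length(predictors), " candidates; got ", n)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(table[predictors]))
  storage.mode(X) <- "double"
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; linearly dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  dat <- table[c(outcome, predictors)]
  fmla <- function(vars) {
    stats::as.formula(paste(outcome, "~",
                            if (length(vars) == 0L) "1"
                            else paste(vars, collapse = " + ")))
  }
  if (criterion == "aic") {
    m0 <- stats::lm(fmla(character(0)), data = dat)
    full <- fmla(predictors)
    fit <- stats::step(m0, scope = list(lower = ~1, upper = full),
                       direction = "both", trace = 0)
    selected <- setdiff(attr(stats::terms(fit), "term.labels"), character(0))
    anv <- fit$anova
    trace <- data.frame(step = seq_len(nrow(anv)) - 1L,
                        action = trimws(as.character(anv$Step)),
                        value = anv$AIC, stringsAsFactors = FALSE)
    trace$action[1] <- "start"
  } else {
    selected <- character(0)
    trace <- data.frame(step = 0L, action = "start", variable = "",
                        p = NA_real_, stringsAsFactors = FALSE)
    step_no <- 0L
    term_p <- function(vars) {
      m <- stats::lm(fmla(vars), data = dat)
      ct <- stats::coef(summary(m))
      p <- ct[, "Pr(>|t|)"]
      p[setdiff(rownames(ct), "(Intercept)")]
    }
    repeat {
      changed <- FALSE
      cands <- setdiff(predictors, selected)
      if (length(cands) > 0L && n >= length(selected) + 3L) {
        entry_p <- vapply(cands, function(v) {
          term_p(c(selected, v))[[v]]
        }, numeric(1))
        best <- which.min(entry_p)
        if (entry_p[best] < alpha_enter) {
          selected <- c(selected, cands[best])
          step_no <- step_no + 1L
          trace <- rbind(trace, data.frame(step = step_no, action = "add",
                                           variable = cands[best],
                                           p = unname(entry_p[best]),
                                           stringsAsFactors = FALSE))
          changed <- TRUE
        }
      }
      repeat {
        if (length(selected) == 0L) break
        cur_p <- term_p(selected)
        worst <- which.max(cur_p)
        if (cur_p[worst] > alpha_remove) {
          step_no <- step_no + 1L
          trace <- rbind(trace, data.frame(step = step_no,
                                           action = "remove",
                                           variable = selected[worst],
                                           p = unname(cur_p[worst]),
                                           stringsAsFactors = FALSE))
          selected <- selected[-worst]
          changed <- TRUE
        } else break
      }
      if (!changed) break
    }
    fit <- stats::lm(fmla(selected), data = dat)
  }
  sm <- summary(fit)
  ct <- stats::coef(sm)
  coefs <- data.frame(term = rownames(ct), estimate = ct[, "Estimate"],
                      se = ct[, "Std. Error"], t = ct[, "t value"],
                      p = ct[, "Pr(>|t|)"], stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(model = fit, selected = selected, coefficients = coefs,
                 r.squared = sm$r.squared,
                 adj.r.squared = sm$adj.r.squared, trace = trace,
                 criterion = criterion, outcome = outcome,
                 candidates = predictors),
            class = "stepwise_fit")
}

#' Fit the openness-of-communication prediction model
#'
#' The central model of the package: ordinary least squares predicting
#' the lexicon-derived openness score from subject covariates and
#' narrative sentiment features, after (1) excluding predictors with
#' pairwise absolute Pearson correlation above `threshold` (default
#' 0.60) to avoid multicollinearity, and (2) stepwise selection of the
#' remaining candidates ([stepwise_fit()]).
#'
#' @param data Feature table from [assemble_features()] (or any
#'   data.frame with the outcome and candidate columns).
#' @param outcome Outcome column name (default `"openness"`).
#' @param predictors Candidate predictors; defaults to
#'   [default_predictors()].
#' @param threshold Collinearity cutoff, see [collinearity_filter()].
#' @param criterion,alpha_enter,alpha_remove Stepping controls, see
#'   [stepwise_fit()].
#' @return Object of class `openness_fit` with components `model` (final
#'   [stats::lm()]), `selected`, `coefficients`, `r.squared`,
#'   `adj.r.squared`, `collinearity` (exclusion report), `trace`,
#'   `criterion`, `n`, `call`.  Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals`, `simulate` and `plot`.
#' @export
#' @examples
#' set.seed(1)
#' d <- data.frame(x1 = rnorm(60), x2 = rnorm(60), x3 = rnorm(60))
#' d$openness <- 5 + 2 * d$x1 + rnorm(60, sd = 0.5)
#' fit <- openness_fit(d, predictors = c("x1", "x2", "x3"))
#' coef(fit)
openness_fit <- function(data, outcome = "openness",
                         predictors = default_predictors(data),
                         threshold = 0.60, criterion = c("p", "aic"),
                         alpha_enter = 0.05, alpha_remove = 0.10) {
  criterion <- match.arg(criterion)
  flt <- collinearity_filter(data, predictors = predictors,
                             threshold = threshold)
  sw <- stepwise_fit(data, outcome = outcome, predictors = flt$kept,
                     criterion = criterion, alpha_enter = alpha_enter,
                     alpha_remove = alpha_remove)
  structure(list(model = sw$model, selected = sw$selected,
                 coefficients = sw$coefficients,
                 r.squared = sw$r.squared,
                 adj.r.squared = sw$adj.r.squared,
                 collinearity = flt, trace = sw$trace,
                 criterion = criterion, outcome = outcome,
                 candidates = predictors, n = nrow(data),
                 call = match.call()),
            class = "openness_fit")
}

#' @export
print.openness_fit <- function(x, ...) {
  cat("Openness-of-communication prediction model\n")
  cat("  n =", x$n, "subjects;", length(x$candidates), "candidates;",
      nrow(x$collinearity$dropped), "excluded as collinear;",
      length(x$selected), "selected\n")
  cat("  criterion:", if (x$criterion == "p")
    "stepwise p-value (enter 0.05 / remove 0.10)" else
      "stepwise bidirectional AIC", "\n")
  cat("  selected:", if (length(x$selected) == 0L) "(intercept only)"
      else paste(x$selected, collapse = ", "), "\n")
  cat(sprintf("  R-squared %.4f (adjusted %.4f)\n",
              x$r.squared, x$adj.r.squared))
  invisible(x)
}

#' @export
summary.openness_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.openness_fit")
}

#' @export
print.summary.openness_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  if (nrow(f$collinearity$dropped) > 0L) {
    cat("\nExcluded for collinearity (|r| > threshold):\n")
    print(f$collinearity$dropped, row.names = FALSE)
  }
  cat("\nCoefficients:\n")
  ct <- f$coefficients
  ct$estimate <- sprintf("%10.3f", ct$estimate)
  ct$se <- sprintf("%8.3f", ct$se)
  ct$t <- sprintf("%7.3f", ct$t)
  ct$p <- format.pval(ct$p, digits = 3)
  print(ct, row.names = FALSE)
  invisible(x)
}

#' @export
coef.openness_fit <- function(object, ...) stats::coef(object$model)

#' @export
predict.openness_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) stats::predict(object$model, ...)
  else stats::predict(object$model, newdata = newdata, ...)
}

#' @export
fitted.openness_fit <- function(object, ...) stats::fitted(object$model)

#' @export
residuals.openness_fit <- function(object, ...) stats::residuals(object$model)

#' @export
simulate.openness_fit <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$model, nsim = nsim, seed = seed, ...)
}

#' @export
plot.openness_fit <- function(x, ...) {
  obs <- stats::model.response(stats::model.frame(x$model))
  prd <- stats::fitted(x$model)
  graphics::plot(prd, obs, xlab = "Predicted openness score",
                 ylab = "Observed openness score",
                 main = "Openness model: observed vs predicted", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
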