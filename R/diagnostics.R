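#' @title Diagnostic accuracy against the any-HAI reference standard
#' @description
#' Confusion-matrix construction from tri-state test calls and any-HAI
#' truth, the seven standard accuracy metrics (sensitivity, specificity,
#' negative and positive likelihood ratios, predictive values, accuracy),
#' rank-based ROC AUC, and binomial confidence intervals. Episodes whose
#' test call is not evaluable are excluded from the denominator and
#' counted, never imputed.
#' @name diagnostics
NULL

#' Build a confusion matrix from tri-state predictions and truth
#'
#' @param predictions character vector over `"positive"`, `"negative"`,
#'   `"not_evaluable"` (logical vectors are accepted, `TRUE` = positive).
#' @param truth logical vector: any HAI present (the reference standard).
#'   Must be free of missing values.
#' @return object of class `confusion_matrix`: list with `tp`, `tn`, `fp`,
#'   `fn`, `n_evaluable`, `n_excluded`.
#' @export
confusion_matrix <- function(predictions, truth) {
  if (is.logical(predictions))
    predictions <- ifelse(is.na(predictions), "not_evaluable",
                          ifelse(predictions, "positive", "negative"))
  if (length(predictions) != length(truth))
    stop("predictions and truth must have equal length", call. = FALSE)
  if (anyNA(truth))
    stop("truth must have no missing values", call. = FALSE)
  ok <- predictions %in% c("positive", "negative", "not_evaluable")
  if (!all(ok))
    stop("predictions must be 'positive', 'negative' or 'not_evaluable'",
         call. = FALSE)
  eval_idx <- predictions != "not_evaluable"
  p <- predictions[eval_idx] == "positive"
  t <- as.logical(truth)[eval_idx]
  structure(list(
    tp = sum(p & t), tn = sum(!p & !t), fp = sum(p & !t), fn = sum(!p & t),
    n_evaluable = sum(eval_idx), n_excluded = sum(!eval_idx)
  ), class = "confusion_matrix")
}

#' Assemble a confusion matrix from its four cell counts
#'
#' @param tp,tn,fp,fn non-negative cell counts.
#' @param n_excluded episodes excluded as not evaluable (default 0).
#' @return object of class `confusion_matrix`.
#' @export
confusion_counts <- function(tp, tn, fp, fn, n_excluded = 0) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0, n_excluded >= 0)
  structure(list(tp = tp, tn = tn, fp = fp, fn = fn,
                 n_evaluable = tp + tn + fp + fn,
                 n_excluded = n_excluded),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d evaluable, %d excluded)\n",
              x$n_evaluable, x$n_excluded))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              disease = c("present", "absent")))
  print(m)
  invisible(x)
}

# Percentages are rounded in two stages (2 dp then 1 dp, half away from
# zero at each stage), the display convention of common clinical statistics
# software; a single-stage rounding would print 60/79 as 75.9 rather than
# the conventional 76.0.
.pct <- function(p, digits = 1) {
  round_half_away(round_half_away(100 * p, digits + 1), digits)
}

#' Diagnostic accuracy metrics from a confusion matrix
#'
#' Sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV tp/(tp+fp), NPV
#' tn/(tn+fn), accuracy (tp+tn)/n, negative likelihood ratio
#' (1-sens)/spec, positive likelihood ratio sens/(1-spec). Percentages are
#' reported to one decimal, likelihood ratios to two, rounded half away
#' from zero (two-stage for percentages; see Details in the package
#' vignette). A metric whose denominator is zero is `NA` ("undefined"),
#' never coerced to 0.
#'
#' @param cm a `confusion_matrix`.
#' @param percent_digits decimals for percentage metrics (default 1).
#' @param ratio_digits decimals for likelihood ratios (default 2).
#' @return object of class `diagnostic_metrics`: list of rounded values
#'   (`sensitivity`, `specificity`, `nlr`, `plr`, `ppv`, `npv`, `accuracy`,
#'   percentages on the 0-100 scale) plus `raw` (unrounded proportions and
#'   ratios) and the counts.
#' @export
diagnostic_metrics <- function(cm, percent_digits = 1, ratio_digits = 2) {
  stopifnot(inherits(cm, "confusion_matrix"))
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- safe_div(cm$tp, cm$tp + cm$fn)
  spec <- safe_div(cm$tn, cm$tn + cm$fp)
  ppv <- safe_div(cm$tp, cm$tp + cm$fp)
  npv <- safe_div(cm$tn, cm$tn + cm$fn)
  acc <- safe_div(cm$tp + cm$tn, cm$n_evaluable)
  nlr <- if (!is.na(sens) && !is.na(spec) && spec > 0) (1 - sens) / spec else NA_real_
  plr <- if (!is.na(sens) && !is.na(spec) && spec < 1) sens / (1 - spec) else NA_real_
  rnd_ratio <- function(x) if (is.na(x)) NA_real_ else
    round_half_away(round_half_away(x, ratio_digits + 2), ratio_digits)
  structure(list(
    sensitivity = .pct(sens, percent_digits),
    specificity = .pct(spec, percent_digits),
    nlr = rnd_ratio(nlr),
    plr = rnd_ratio(plr),
    ppv = .pct(ppv, percent_digits),
    npv = .pct(npv, percent_digits),
    accuracy = .pct(acc, percent_digits),
    raw = list(sensitivity = sens, specificity = spec, nlr = nlr, plr = plr,
               ppv = ppv, npv = npv, accuracy = acc),
    counts = cm
  ), class = "diagnostic_metrics")
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  cm <- x$counts
  cat(sprintf("n = %d (tp %d, tn %d, fp %d, fn %d; %d not evaluable)\n",
              cm$n_evaluable, cm$tp, cm$tn, cm$fp, cm$fn, cm$n_excluded))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
              x$sensitivity, x$specificity, x$accuracy))
  cat(sprintf("  PPV %.1f%%  NPV %.1f%%  NLR %.2f  PLR %s\n",
              x$ppv, x$npv, x$nlr,
              ifelse(is.na(x$plr), "undefined", sprintf("%.2f", x$plr))))
  invisible(x)
}

#' Area under the ROC curve by the rank (Mann-Whitney) formula
#'
#' AUC = U / (n_pos * n_neg) where U is the Mann-Whitney statistic of the
#' scores between classes; midranks make tied scores contribute 1/2,
#' equivalent to trapezoidal integration of the empirical ROC curve.
#'
#' @param scores numeric vector of test scores (higher = more disease-like).
#' @param truth logical vector, disease present.
#' @return AUC in `[0, 1]`.
#' @export
score_auc <- function(scores, truth) {
  stopifnot(length(scores) == length(truth), !anyNA(scores), !anyNA(truth))
  truth <- as.logical(truth)
  n_pos <- sum(truth); n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  r <- rank(scores)  # midranks for ties
  (sum(r[truth]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Binomial confidence intervals for the proportion metrics
#'
#' Two-sided 95% (by default) intervals for sensitivity, specificity, PPV,
#' NPV and accuracy, by the Wilson score method or the exact
#' Clopper-Pearson method. Metrics with zero denominator are undefined
#' (`NA` bounds).
#'
#' @param cm a `confusion_matrix`.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param conf_level confidence level, default 0.95.
#' @return `data.frame` with `metric`, `estimate`, `lower`, `upper`
#'   (proportions in `[0, 1]`), `x`, `n`.
#' @export
metric_ci <- function(cm, method = c("wilson", "clopper_pearson"),
                      conf_level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  method <- match.arg(method)
  cells <- list(
    sensitivity = c(cm$tp, cm$tp + cm$fn),
    specificity = c(cm$tn, cm$tn + cm$fp),
    ppv = c(cm$tp, cm$tp + cm$fp),
    npv = c(cm$tn, cm$tn + cm$fn),
    accuracy = c(cm$tp + cm$tn, cm$n_evaluable)
  )
  rows <- lapply(names(cells), function(nm) {
    x <- cells[[nm]][1]; n <- cells[[nm]][2]
    if (n == 0)
      return(data.frame(metric = nm, estimate = NA_real_, lower = NA_real_,
                        upper = NA_real_, x = x, n = n))
    ci <- binom_ci(x, n, method, conf_level)
    data.frame(metric = nm, estimate = x / n, lower = ci[1], upper = ci[2],
               x = x, n = n)
  })
  do.call(rbind, rows)
}

#' Binomial proportion confidence interval
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param method `"wilson"` or `"clopper_pearson"`.
#' @param conf_level confidence level.
#' @return numeric `c(lower, upper)`.
#' @export
binom_ci <- function(x, n, method = c("wilson", "clopper_pearson"),
                     conf_level = 0.95) {
  method <- match.arg(method)
  stopifnot(n >= 1, x >= 0, x <= n)
  alpha <- 1 - conf_level
  if (method == "wilson") {
    z <- stats::qnorm(1 - alpha / 2)
    p <- x / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    c(max(0, centre - half), min(1, centre + half))
  } else {
    lower <- if (x == 0) 0 else stats::qbeta(alpha / 2, x, n - x + 1)
    upper <- if (x == n) 1 else stats::qbeta(1 - alpha / 2, x + 1, n - x)
    c(lower, upper)
  }
}

#' Reference confusion counts for the five candidate tests
#'
#' The per-test true/false positive/negative counts reported by the
#' derivation cohort (214 suspected-HAI episodes, 78 with any HAI), used to
#' calibrate the synthetic cohort and to reproduce the published accuracy
#' table. Tests with missing t24 CRP measurements have fewer evaluable
#' episodes (205 and 209).
#'
#' @return `data.frame` with one row per test: `test`, `tp`, `tn`, `fp`,
#'   `fn`, `n`.
#' @export
reference_test_counts <- function() {
  data.frame(
    test = c("crp_t0", "neohop_t0", "crp_t24",
             "crp_t0_and_t24_combined", "neohop_t0_and_crp_t24_combined"),
    tp = c(60, 70, 65, 76, 77),
    tn = c(135, 133, 131, 131, 133),
    fp = c(0, 3, 0, 0, 3),
    fn = c(19, 8, 9, 2, 1),
    n = c(214, 214, 205, 209, 214),
    stringsAsFactors = FALSE
  )
}

#' Accuracy-table layout (tests as columns, metrics as rows)
#'
#' Recomputes the seven metric rows for each test from a counts table such
#' as [reference_test_counts()] or cohort-derived counts.
#'
#' @param counts `data.frame` with columns `test`, `tp`, `tn`, `fp`, `fn`.
#' @return `data.frame` with metrics as rows and one column per test.
#' @export
metrics_table <- function(counts = reference_test_counts()) {
  metric_rows <- c("tp", "tn", "fp", "fn", "sensitivity", "specificity",
                   "nlr", "ppv", "npv", "accuracy")
  cols <- lapply(seq_len(nrow(counts)), function(i) {
    cm <- confusion_counts(counts$tp[i], counts$tn[i], counts$fp[i],
                           counts$fn[i])
    m <- diagnostic_metrics(cm)
    c(cm$tp, cm$tn, cm$fp, cm$fn, m$sensitivity, m$specificity, m$nlr,
      m$ppv, m$npv, m$accuracy)
  })
  out <- data.frame(metric = metric_rows, stringsAsFactors = FALSE)
  for (i in seq_along(cols)) out[[counts$test[i]]] <- cols[[i]]
  out
}
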