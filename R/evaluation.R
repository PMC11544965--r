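#' Confusion counts for a binary classifier
#'
#' @param labels true labels, coercible to 0/1 (1 / `TRUE` / `"Yes"` is
#'   positive).
#' @param predicted predicted classes, same coding and length.
#' @return list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(labels, predicted) {
  labels <- as_binary(labels)
  predicted <- as_binary(predicted)
  if (length(labels) != length(predicted))
    stop("labels and predictions have different lengths")
  if (!length(labels)) stop("empty input")
  structure(list(tp = sum(labels == 1 & predicted == 1),
                 fp = sum(labels == 0 & predicted == 1),
                 tn = sum(labels == 0 & predicted == 0),
                 fn = sum(labels == 1 & predicted == 0)),
            class = "confusion_counts")
}

as_binary <- function(x) {
  if (is.logical(x)) return(as.integer(x))
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    if (!all(x %in% c("Yes", "No", "1", "0", "at_risk", "not_at_risk")))
      stop("labels must be binary (Yes/No, 1/0, at_risk/not_at_risk)")
    return(as.integer(x %in% c("Yes", "1", "at_risk")))
  }
  if (!all(x %in% c(0, 1))) stop("labels must be binary 0/1")
  as.integer(x)
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' Classification metrics with normal-approximation intervals
#'
#' Computes TPR, TNR, PPV, NPV, accuracy, balanced accuracy and the
#' Matthews correlation coefficient from confusion counts, with a
#' normal-approximation confidence interval for each proportion metric.
#' Metrics whose denominator is empty are reported as `NA` (explicitly
#' undefined), never coerced to zero — rare-event confusion tables often
#' have empty cells. MCC is 0 when any of its four marginal factors is 0.
#'
#' @param counts a [confusion()] result.
#' @param level confidence level for the intervals.
#' @return data frame of class `metric_report`: one row per metric with
#'   `value`, `ci_low`, `ci_high`, `n` (denominator).
#' @export
classification_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion table")
  tpr <- safe_ratio(tp, tp + fn)
  tnr <- safe_ratio(tn, tn + fp)
  ppv <- safe_ratio(tp, tp + fp)
  npv <- safe_ratio(tn, tn + fn)
  acc <- (tp + tn) / n
  ba <- (tpr + tnr) / 2
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den)
  rows <- list(
    tpr = c(tpr, tp + fn), tnr = c(tnr, tn + fp),
    ppv = c(ppv, tp + fp), npv = c(npv, tn + fn),
    accuracy = c(acc, n),
    balanced_accuracy = c(ba, n),
    mcc = c(mcc, n))
  out <- data.frame(metric = names(rows),
                    value = vapply(rows, `[`, numeric(1), 1),
                    ci_low = NA_real_, ci_high = NA_real_,
                    n = vapply(rows, `[`, numeric(1), 2),
                    row.names = NULL)
  prop <- out$metric %in% c("tpr", "tnr", "ppv", "npv", "accuracy")
  for (i in which(prop)) {
    if (!is.na(out$value[i]) && out$n[i] > 0) {
      ci <- normal_ci(out$value[i], out$n[i], level)
      out$ci_low[i] <- ci[1]; out$ci_high[i] <- ci[2]
    }
  }
  class(out) <- c("metric_report", class(out))
  out
}

#' Area under the ROC curve
#'
#' Mann-Whitney rank statistic with midranks for ties: equals the
#' all-pairs concordance fraction (ties counted 1/2).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels (see [confusion()] for accepted codings).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as_binary(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be present to compute the AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Normal-approximation confidence interval for a proportion
#'
#' `p +/- z * sqrt(p (1 - p) / n)`, clamped to `[0, 1]`; `z` is the
#' standard normal quantile for the requested level.
#'
#' @param p observed proportion.
#' @param n denominator (>= 1).
#' @param level confidence level.
#' @return numeric vector `c(low, high)`.
#' @export
#' @examples
#' round(normal_ci(0.5, 100), 3)  # 0.402 0.598
normal_ci <- function(p, n, level = 0.95) {
  stopifnot(p >= 0, p <= 1, n >= 1)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

#' Cumulative-gain (lift) curve
#'
#' Patients are sorted in descending score order (stable: ties keep
#' their original order, or are pooled with `ties = "pooled"`); point
#' `k` of the curve is (fraction of patients considered `k/n`,
#' cumulative TPR = positives among the top `k` over all positives).
#'
#' @param scores numeric risk scores.
#' @param labels binary labels; at least one positive required.
#' @param ties `"stable"` (default) or `"pooled"` (tied scores share
#'   their pooled average gain).
#' @return list of class `lift_curve` with `fractions` and
#'   `cumulative_tpr`.
#' @export
lift_curve <- function(scores, labels, ties = c("stable", "pooled")) {
  ties <- match.arg(ties)
  labels <- as_binary(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("at least one positive label is required")
  ord <- order(-scores)  # stable for ties (order() preserves input order)
  gains <- cumsum(labels[ord]) / n_pos
  if (ties == "pooled") {
    s_sorted <- scores[ord]
    grp <- cumsum(!duplicated(s_sorted))
    last_of_grp <- rev(!duplicated(rev(grp)))
    pooled <- gains
    pooled[] <- gains[which(last_of_grp)][grp]
    gains <- pooled
  }
  n <- length(scores)
  structure(list(fractions = seq_len(n) / n, cumulative_tpr = gains),
            class = "lift_curve")
}

#' Gain at a patient fraction
#'
#' Cumulative TPR achieved when the top-`q` fraction of patients (by
#' predicted risk) is examined, using the step-function convention: the
#' value at the largest tabulated fraction not exceeding `q` (0 when
#' `q` is below the first tabulated fraction).
#'
#' @param curve a [lift_curve()].
#' @param q fraction in `(0, 1]`.
#' @return cumulative TPR in `[0, 1]`.
#' @export
gain_at_fraction <- function(curve, q) {
  stopifnot(inherits(curve, "lift_curve"))
  if (!(q > 0 && q <= 1)) stop("q must lie in (0, 1]")
  i <- findInterval(q + 1e-12, curve$fractions)
  if (i == 0) 0 else curve$cumulative_tpr[i]
}

#' Bar plot of a metric report (classification performance summary)
#'
#' @param report a [classification_metrics()] result.
#' @param main plot title.
#' @return invisibly, the report.
#' @export
plot_metric_report <- function(report, main = "Classification performance") {
  vals <- report$value
  ok <- !is.na(vals)
  bp <- graphics::barplot(vals[ok], names.arg = toupper(report$metric[ok]),
                          ylim = c(min(0, min(vals[ok])), 1.05),
                          ylab = "value", main = main, las = 2)
  has_ci <- ok & !is.na(report$ci_low)
  if (any(has_ci)) {
    idx <- which(has_ci[ok])
    graphics::arrows(bp[idx], report$ci_low[has_ci], bp[idx],
                     report$ci_high[has_ci],
                     angle = 90, code = 3, length = 0.04)
  }
  invisible(report)
}

#' Plot a cumulative-gain curve against the chance diagonal
#'
#' @param curve a [lift_curve()].
#' @param main plot title.
#' @return invisibly, the curve.
#' @export
plot_lift_curve <- function(curve, main = "Cumulative gain") {
  graphics::plot(c(0, curve$fractions), c(0, curve$cumulative_tpr),
                 type = "s", lwd = 2, xlab = "fraction of patients (by risk)",
                 ylab = "cumulative TPR", main = main)
  graphics::abline(0, 1, lty = 2, col = "grey50")
  invisible(curve)
}
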