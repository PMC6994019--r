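# Classifier evaluation: confusion-matrix metrics, percentile-bootstrap
# confidence intervals, and ROC/AUC with a DeLong interval.

#' Confusion counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `mbc_confusion`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("confusion counts must be finite and non-negative")
  }
  structure(as.list(counts), class = "mbc_confusion")
}

confusion_from_predictions <- function(y, yhat) {
  confusion_counts(tp = sum(y == 1 & yhat == 1),
                   fp = sum(y == 0 & yhat == 1),
                   tn = sum(y == 0 & yhat == 0),
                   fn = sum(y == 1 & yhat == 0))
}

#' Point-estimate performance metrics from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV, F1 and accuracy. A ratio with a zero
#' denominator is reported as `NA` (absent), never as 0.
#'
#' @param counts An [confusion_counts()] object.
#' @return List: sensitivity, specificity, ppv, npv, f1, accuracy, n,
#'   prevalence.
#' @examples
#' # 146 reviewed patients (72 cases, 74 controls), 15 FP and 8 FN labels:
#' unlist(confusion_metrics(confusion_counts(tp = 64, fp = 15,
#'                                           tn = 59, fn = 8)))
#' @export
confusion_metrics <- function(counts) {
  stopifnot(inherits(counts, "mbc_confusion"))
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  n <- tp + fp + tn + fn
  if (n == 0) stop("empty confusion matrix")
  ratio <- function(num, den) if (den > 0) num / den else NA_real_
  list(sensitivity = ratio(tp, tp + fn),
       specificity = ratio(tn, tn + fp),
       ppv = ratio(tp, tp + fp),
       npv = ratio(tn, tn + fn),
       f1 = ratio(2 * tp, 2 * tp + fp + fn),
       accuracy = (tp + tn) / n,
       n = n,
       prevalence = (tp + fn) / n)
}

METRIC_FUNS <- list(
  sensitivity = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$sensitivity,
  specificity = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$specificity,
  ppv = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$ppv,
  npv = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$npv,
  f1 = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$f1,
  accuracy = function(y, s, cut) confusion_metrics(
    confusion_from_predictions(y, as.integer(s >= cut)))$accuracy,
  auc = function(y, s, cut) roc_auc(s, y)
)

#' Percentile bootstrap confidence interval for a performance metric
#'
#' Resamples patients with replacement `B` times, recomputes the metric on
#' each resample, and returns the empirical 2.5th and 97.5th percentiles
#' (linear-interpolation quantiles). Resamples where the metric is undefined
#' (zero denominator, or a single class for AUC) are skipped and counted; if
#' more than half are undefined the interval is an error.
#'
#' @param y 0/1 labels.
#' @param scores Predicted probabilities, scores, or 0/1 labels.
#' @param metric One of "sensitivity", "specificity", "ppv", "npv", "f1",
#'   "accuracy", "auc".
#' @param B Number of resamples (default 1000).
#' @param seed Integer seed.
#' @param cutoff Threshold applied to `scores` for thresholded metrics
#'   (default 0.5; irrelevant for 0/1 `scores` and for AUC).
#' @param level Confidence level (default 0.95).
#' @return List: lo, hi, n_undefined.
#' @export
bootstrap_ci <- function(y, scores, metric = "accuracy", B = 1000L,
                         seed = 1L, cutoff = 0.5, level = 0.95) {
  stopifnot(length(y) == length(scores), B >= 1L)
  fun <- METRIC_FUNS[[match.arg(metric, names(METRIC_FUNS))]]
  n <- length(y)
  set.seed(seed)
  vals <- numeric(B)
  undef <- 0L
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    v <- tryCatch(fun(y[idx], scores[idx], cutoff), error = function(e) NA_real_)
    if (is.na(v)) { undef <- undef + 1L; vals[b] <- NA } else vals[b] <- v
  }
  if (undef > B / 2) {
    stop("metric undefined in ", undef, " of ", B, " bootstrap resamples")
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(vals, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  list(lo = q[1], hi = q[2], n_undefined = undef)
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' AUC as the probability that a random case scores above a random control,
#' counting ties as one half — computed from average ranks, identical to the
#' concordant-pair count over all case-control pairs.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param y 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, y) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required for AUC")
  if (any(!is.finite(scores))) stop("scores must be finite")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for AUC
#'
#' Nonparametric variance from placement values: each case's placement is the
#' fraction of controls it outscores (ties one half) and vice versa; the AUC
#' variance is `var(case placements)/n1 + var(control placements)/n0`. The
#' normal-approximation interval is truncated to \[0, 1\].
#'
#' @inheritParams roc_auc
#' @param level Confidence level (default 0.95).
#' @return List: auc, lo, hi, se.
#' @export
delong_ci <- function(scores, y, level = 0.95) {
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("both classes required for AUC")
  cases <- scores[y == 1]; controls <- scores[y == 0]
  n1 <- length(cases); n0 <- length(controls)
  placement <- function(x, other) {
    vapply(x, function(v) {
      (sum(other < v) + 0.5 * sum(other == v)) / length(other)
    }, numeric(1))
  }
  v10 <- placement(cases, controls)    # per-case placement values
  v01 <- 1 - placement(controls, cases)
  auc <- mean(v10)
  se <- sqrt(stats::var(v10) / n1 + stats::var(v01) / n0)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = auc, lo = max(0, auc - z * se), hi = min(1, auc + z * se),
       se = se)
}

#' ROC curve points
#'
#' True/false positive rates at every distinct score threshold, for plotting.
#'
#' @inheritParams roc_auc
#' @return Data.frame (threshold, tpr, fpr), thresholds descending.
#' @export
roc_points <- function(scores, y) {
  y <- as.integer(y)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & y == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & y == 0) / n0, numeric(1))
  data.frame(threshold = thr, tpr = tpr, fpr = fpr)
}

#' Full evaluation report for binary predictions or scores
#'
#' Computes all confusion metrics at the given cutoff, bootstrap CIs for
#' each, and (when `scores` is not already binary) AUC with a DeLong CI.
#'
#' @inheritParams bootstrap_ci
#' @param with_auc Include AUC/DeLong (default: TRUE iff scores are not 0/1).
#' @return List of class `mbc_eval_report`.
#' @export
evaluate_predictions <- function(y, scores, cutoff = 0.5, B = 1000L,
                                 seed = 1L,
                                 with_auc = !all(scores %in% c(0, 1))) {
  yhat <- as.integer(scores >= cutoff)
  est <- confusion_metrics(confusion_from_predictions(y, yhat))
  metrics <- c("sensitivity", "specificity", "ppv", "npv", "f1", "accuracy")
  ci <- lapply(stats::setNames(metrics, metrics), function(m) {
    tryCatch(bootstrap_ci(y, scores, m, B = B, seed = seed, cutoff = cutoff),
             error = function(e) {
               warning("bootstrap CI unavailable for ", m, ": ",
                       conditionMessage(e), call. = FALSE)
               list(lo = NA_real_, hi = NA_real_, n_undefined = NA_integer_)
             })
  })
  out <- c(est, list(ci = ci))
  if (with_auc) {
    out$auc <- roc_auc(scores, y)
    out$auc_ci <- delong_ci(scores, y)
  }
  structure(out, class = "mbc_eval_report")
}

#' @export
print.mbc_eval_report <- function(x, digits = 3, ...) {
  cat("<mbc_eval_report> n =", x$n, " prevalence =",
      round(x$prevalence, digits), "\n")
  for (m in c("sensitivity", "specificity", "ppv", "npv", "f1", "accuracy")) {
    ci <- x$ci[[m]]
    cat(sprintf("  %-11s %.3f (%.3f, %.3f)\n", m, x[[m]], ci$lo, ci$hi))
  }
  if (!is.null(x$auc)) {
    cat(sprintf("  %-11s %.3f (%.3f, %.3f) [DeLong]\n", "auc", x$auc,
                x$auc_ci$lo, x$auc_ci$hi))
  }
  invisible(x)
}
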