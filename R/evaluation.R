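# Classifier benchmarking: confusion counts at a threshold, Matthews
# correlation, ROC/AUC (trapezoid; equals the Mann-Whitney pair statistic),
# optimal-threshold selection from half-sample-resampled MCC curves, and a
# rank-sum comparison helper for composition analyses.

#' Confusion counts at a threshold
#'
#' A case is called positive when its statistic is strictly greater than
#' the threshold (the same strict rule used by [classify_chain()]).
#'
#' @param pos Statistic values of the positive class (e.g. known ID
#'   segments).
#' @param neg Statistic values of the negative class.
#' @param threshold Decision threshold.
#' @return A `confusion_counts` named integer vector (TP, FP, TN, FN).
#' @export
confusion_at <- function(pos, neg, threshold) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("confusion_at: both classes must be non-empty")
  out <- c(TP = sum(pos > threshold), FP = sum(neg > threshold),
           TN = sum(neg <= threshold), FN = sum(pos <= threshold))
  structure(as.integer(out), names = names(out), class = "confusion_counts")
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' convention MCC = 0 when any factor of the denominator is zero.
#'
#' @param counts Counts from [confusion_at()], or any vector/list with
#'   named elements TP, FP, TN, FN.
#' @return Value in \[-1, 1\].
#' @export
mcc <- function(counts) {
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / sqrt(den)
}

#' False discovery rate and sensitivity at a threshold
#'
#' @inheritParams confusion_at
#' @return Named vector `fdr = FP/(FP+TP)`, `sensitivity = TP/(TP+FN)`.
#' @export
fdr_sensitivity <- function(pos, neg, threshold) {
  ct <- confusion_at(pos, neg, threshold)
  tp <- ct[["TP"]]; fp <- ct[["FP"]]; fn <- ct[["FN"]]
  c(fdr = if (tp + fp == 0) 0 else fp / (fp + tp),
    sensitivity = if (tp + fn == 0) 0 else tp / (tp + fn))
}

#' ROC curve and AUC
#'
#' Sweeps the decision threshold over all distinct statistic values and
#' integrates TPR over FPR by the trapezoid rule.  With the half-credit tie
#' convention this equals the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs ranked correctly, ties counting one half.
#'
#' @inheritParams confusion_at
#' @return A `roc_result`: list with `points` (data frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_auc <- function(pos, neg) {
  if (length(pos) == 0L || length(neg) == 0L)
    stop("roc_auc: both classes must be non-empty")
  th <- sort(unique(c(pos, neg)), decreasing = TRUE)
  # thresholds: above the max (no positives called) down through each value
  cuts <- c(Inf, th)
  tpr <- vapply(cuts, function(t) mean(pos >= t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(neg >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = data.frame(threshold = cuts, fpr = fpr, tpr = tpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat("roc_result: AUC =", format(x$auc, digits = 4),
      "over", nrow(x$points) - 1L, "distinct thresholds\n")
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "l",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Half-sample-resampled MCC curve and threshold selection
#'
#' For each of `n_reps` repetitions, half of each class is drawn without
#' replacement and the MCC is computed over the threshold grid; the curve
#' reports mean and standard deviation per threshold.  The selected
#' operating point is the grid threshold with the highest mean MCC (lowest
#' threshold on ties).
#'
#' @inheritParams confusion_at
#' @param thresholds Threshold grid; defaults to an even grid spanning the
#'   pooled statistic range.
#' @param n_reps Number of half-sample repetitions.
#' @param seed Integer seed; resampling is fully reproducible.
#' @return An `mcc_curve`: list with `curve` (data frame `threshold`,
#'   `mean_mcc`, `sd_mcc`), `best_threshold`, `best_mcc`, `best_sd`,
#'   `full_mcc` (MCC on the complete data at the selected threshold),
#'   `fdr`, `sensitivity`, `n_reps`, `seed`.
#' @export
resampled_mcc_curve <- function(pos, neg, thresholds = NULL, n_reps = 1000L,
                                seed = 1L) {
  if (length(pos) < 2L || length(neg) < 2L)
    stop("resampled_mcc_curve: each class needs >= 2 members")
  if (is.null(thresholds)) {
    rng <- range(c(pos, neg))
    thresholds <- seq(rng[1], rng[2], length.out = 101L)
  }
  thresholds <- sort(thresholds)
  hp <- max(1L, floor(length(pos) / 2))
  hn <- max(1L, floor(length(neg) / 2))
  set.seed(seed)
  acc <- matrix(0, n_reps, length(thresholds))
  for (r in seq_len(n_reps)) {
    p <- sample(pos, hp)
    q <- sample(neg, hn)
    # counts over the grid via sorted cumulative tallies
    tp <- hp - findInterval(thresholds, sort(p))
    fp <- hn - findInterval(thresholds, sort(q))
    fn <- hp - tp
    tn <- hn - fp
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    v <- ifelse(den == 0, 0, (tp * tn - fp * fn) / sqrt(den))
    acc[r, ] <- v
  }
  mean_mcc <- colMeans(acc)
  sd_mcc <- apply(acc, 2, stats::sd)
  best <- which(mean_mcc == max(mean_mcc))[1]
  bt <- thresholds[best]
  fs <- fdr_sensitivity(pos, neg, bt)
  structure(list(curve = data.frame(threshold = thresholds,
                                    mean_mcc = mean_mcc, sd_mcc = sd_mcc),
                 best_threshold = bt, best_mcc = mean_mcc[best],
                 best_sd = sd_mcc[best],
                 full_mcc = mcc(confusion_at(pos, neg, bt)),
                 fdr = unname(fs["fdr"]),
                 sensitivity = unname(fs["sensitivity"]),
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "mcc_curve")
}

#' Select the optimal threshold from a resampled MCC curve
#'
#' @param curve An `mcc_curve` from [resampled_mcc_curve()].
#' @return Named vector `best_threshold`, `best_mcc`, `best_sd`.
#' @export
choose_threshold <- function(curve) {
  stopifnot(inherits(curve, "mcc_curve"))
  c(best_threshold = curve$best_threshold, best_mcc = curve$best_mcc,
    best_sd = curve$best_sd)
}

#' @export
print.mcc_curve <- function(x, ...) {
  cat("mcc_curve (", x$n_reps, " half-sample repetitions, seed ", x$seed,
      "):\n", sep = "")
  cat(sprintf("  best threshold %.4g with mean MCC %.3f +/- %.3f\n",
              x$best_threshold, x$best_mcc, x$best_sd))
  cat(sprintf("  at this threshold (full data): MCC %.3f, FDR %.3f, sensitivity %.3f\n",
              x$full_mcc, x$fdr, x$sensitivity))
  invisible(x)
}

#' @export
plot.mcc_curve <- function(x, ...) {
  cv <- x$curve
  graphics::plot(cv$threshold, cv$mean_mcc, type = "l",
                 xlab = "Threshold", ylab = "Mean MCC",
                 ylim = range(c(cv$mean_mcc - cv$sd_mcc,
                                cv$mean_mcc + cv$sd_mcc)), ...)
  graphics::lines(cv$threshold, cv$mean_mcc + cv$sd_mcc, lty = 3)
  graphics::lines(cv$threshold, cv$mean_mcc - cv$sd_mcc, lty = 3)
  graphics::abline(v = x$best_threshold, col = 2, lty = 2)
  invisible(x)
}

#' Two-sample rank-sum comparison
#'
#' Wilcoxon rank-sum test of two groups, as used for composition and
#' energetics comparisons: exact enumeration when both groups are small
#' (combined n <= 12) and tie-free, otherwise the normal approximation with
#' tie correction.
#'
#' @param a,b Numeric vectors.
#' @return List with `statistic` (rank-sum W) and `p_value` (two-sided).
#' @export
rank_sum_compare <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L)
    stop("rank_sum_compare: both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  exact <- (length(a) + length(b)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = !exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}
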