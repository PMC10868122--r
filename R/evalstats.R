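# Confusion-matrix metrics, AUROC, split protocols, and the three
# model-comparison significance tests.

check_binary <- function(x, what) {
  if (!all(x %in% c(0, 1)))
    stop(what, " must be binary 0/1")
  as.integer(x)
}

#' Confusion counts of a binary prediction
#'
#' TP counts correctly called m1A (positive) sites, TN correctly called
#' non-m1A sites; FP and FN the two error kinds.
#'
#' @param y_true,y_pred Equal-length binary 0/1 vectors.
#' @return Named integer vector `c(TP, TN, FP, FN)`.
#' @export
confusion_counts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred lengths differ")
  y_true <- check_binary(y_true, "y_true")
  y_pred <- check_binary(y_pred, "y_pred")
  c(TP = sum(y_true == 1L & y_pred == 1L),
    TN = sum(y_true == 0L & y_pred == 0L),
    FP = sum(y_true == 0L & y_pred == 1L),
    FN = sum(y_true == 1L & y_pred == 0L))
}

safe_div <- function(num, den) if (den == 0) 0 else num / den

#' Classification metrics from confusion counts
#'
#' Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc = (TP+TN)/total,
#' MCC = (TP*TN - FP*FN)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' F1 = 2TP/(2TP+FP+FN). Any zero denominator yields 0 (the standard
#' degenerate-table convention). AUROC is added when scores are given.
#'
#' @param counts Named vector from [confusion_counts()].
#' @param y_true,scores Optional: true labels and class-1 scores for
#'   AUROC.
#' @return An `evaluation_report`: list of `counts` and the metric
#'   values `Acc`, `Sp`, `Sn`, `MCC`, `F1`, `AUROC` (NA without scores).
#' @export
classification_metrics <- function(counts, y_true = NULL, scores = NULL) {
  TP <- counts[["TP"]]; TN <- counts[["TN"]]
  FP <- counts[["FP"]]; FN <- counts[["FN"]]
  total <- TP + TN + FP + FN
  if (total == 0) stop("no evaluated samples")
  mcc_den <- sqrt(prod(c(TP + FP, TP + FN, TN + FP, TN + FN)))
  auc <- if (!is.null(scores) && !is.null(y_true))
    auroc(y_true, scores) else NA_real_
  structure(list(
    counts = counts,
    Acc = (TP + TN) / total,
    Sp = safe_div(TN, TN + FP),
    Sn = safe_div(TP, TP + FN),
    MCC = safe_div(TP * TN - FP * FN, mcc_den),
    F1 = safe_div(2 * TP, 2 * TP + FP + FN),
    AUROC = auc), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("confusion: TP=%d TN=%d FP=%d FN=%d\n",
              x$counts[["TP"]], x$counts[["TN"]],
              x$counts[["FP"]], x$counts[["FN"]]))
  cat(sprintf("Acc=%.4f Sp=%.4f Sn=%.4f MCC=%.4f F1=%.4f AUROC=%s\n",
              x$Acc, x$Sp, x$Sn, x$MCC, x$F1,
              ifelse(is.na(x$AUROC), "NA", sprintf("%.4f", x$AUROC))))
  invisible(x)
}

#' Evaluate predictions against true labels in one call
#' @param y_true Binary labels.
#' @param scores Class-1 scores in \[0, 1\].
#' @param threshold Call threshold (default 0.5).
#' @return An `evaluation_report` including AUROC.
#' @export
evaluate_predictions <- function(y_true, scores, threshold = 0.5) {
  y_pred <- as.integer(scores >= threshold)
  classification_metrics(confusion_counts(y_true, y_pred),
                         y_true = y_true, scores = scores)
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outranks a random negative, ties counted one half.
#'
#' @param y_true Binary labels with both classes present.
#' @param scores Numeric scores.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(y_true, scores) {
  y_true <- check_binary(y_true, "y_true")
  n1 <- sum(y_true == 1L); n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified 70/30 independent split
#'
#' Train size is round(0.7 n) overall, allocated per class by largest
#' remainder so class proportions in the train partition track the full
#' set to within one sample per class.
#'
#' @param labels Binary 0/1 labels (length n >= 2, both classes present).
#' @param seed Integer seed.
#' @param train_frac Training fraction (default 0.7).
#' @return List `train`, `test` of disjoint exhaustive index vectors.
#' @export
split_70_30 <- function(labels, seed = 1L, train_frac = 0.7) {
  labels <- check_binary(labels, "labels")
  n <- length(labels)
  if (n < 2L || length(unique(labels)) < 2L)
    stop("need both classes present to split")
  set.seed(seed)
  target <- round(train_frac * n)
  cls <- split(seq_len(n), labels)
  base <- vapply(cls, function(idx) floor(train_frac * length(idx)),
                 numeric(1L))
  rem <- vapply(cls, function(idx) train_frac * length(idx),
                numeric(1L)) - base
  extra <- target - sum(base)
  if (extra > 0) {
    ord <- order(rem, decreasing = TRUE)
    base[ord[seq_len(extra)]] <- base[ord[seq_len(extra)]] + 1
  }
  train <- unlist(lapply(seq_along(cls), function(i) {
    sample(cls[[i]], base[i])
  }), use.names = FALSE)
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
}

#' k-fold assignment plan
#'
#' Disjoint folds covering 1..n with sizes differing by at most one;
#' each fold in turn serves as the test partition.
#'
#' @param n Number of samples (n >= k).
#' @param k Number of folds (default 10).
#' @param seed Integer seed.
#' @return Integer vector of fold assignments in 1..k, length n.
#' @export
kfold_plan <- function(n, k = 10L, seed = 1L) {
  if (n < k) stop("n must be at least k")
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Two-proportion z test (pooled)
#'
#' @param x1,n1 Successes and trials of the first sample.
#' @param x2,n2 Successes and trials of the second sample.
#' @return List `z`, `p` (two-sided).
#' @export
z_two_proportion <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("trial counts must be positive")
  p1 <- x1 / n1; p2 <- x2 / n2
  pool <- (x1 + x2) / (n1 + n2)
  den <- sqrt(pool * (1 - pool) * (1 / n1 + 1 / n2))
  z <- if (den == 0) 0 else (p1 - p2) / den
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' McNemar test on discordant counts
#'
#' Exact two-sided binomial p for b + c below `exact_limit`, otherwise
#' the continuity-corrected chi-square with statistic
#' max(|b-c| - 1, 0)^2 / (b + c), so equal discordant counts give
#' statistic 0 and p 1.
#'
#' @param b,c Discordant pair counts (model A right / B wrong, and the
#'   converse).
#' @param exact_limit Switch point between exact and corrected forms.
#' @return List `statistic`, `p`, `method`.
#' @export
mcnemar_test <- function(b, c, exact_limit = 25L) {
  if (b < 0 || c < 0) stop("discordant counts must be nonnegative")
  n <- b + c
  if (n == 0) stop("McNemar test undefined with no discordant pairs")
  if (n < exact_limit) {
    p <- min(1, 2 * stats::pbinom(min(b, c), n, 0.5))
    list(statistic = min(b, c), p = p, method = "exact binomial")
  } else {
    stat <- max(abs(b - c) - 1, 0)^2 / n
    list(statistic = stat,
         p = stats::pchisq(stat, df = 1L, lower.tail = FALSE),
         method = "continuity-corrected chi-square")
  }
}

#' Resampled paired t test between two model configurations
#'
#' Repeatedly re-splits the data 70/30, trains both configurations on
#' each training partition, and applies a paired t test (df = trials-1)
#' to the per-trial test-accuracy differences.
#'
#' @param X Feature matrix.
#' @param y Binary labels.
#' @param model_a,model_b Registry names (see [model_registry()]) or
#'   `model_spec` objects.
#' @param trials Number of resampled splits (>= 2).
#' @param seed Integer seed; trial t uses seed + t.
#' @return List `t`, `p`, `diffs` (per-trial accuracy differences).
#' @export
resampled_paired_ttest <- function(X, y, model_a, model_b, trials = 10L,
                                   seed = 1L) {
  if (trials < 2L) stop("need at least two trials")
  diffs <- vapply(seq_len(trials), function(tr) {
    s <- seed + tr
    sp <- split_70_30(y, seed = s)
    acc <- vapply(list(model_a, model_b), function(m) {
      fit <- m1a_fit(X[sp$train, , drop = FALSE], y[sp$train],
                     model = m, seed = s)
      mean(predict(fit, X[sp$test, , drop = FALSE]) == y[sp$test])
    }, numeric(1L))
    acc[[1L]] - acc[[2L]]
  }, numeric(1L))
  m <- mean(diffs); sdev <- stats::sd(diffs)
  if (sdev == 0) {
    if (m == 0) return(list(t = 0, p = 1, diffs = diffs))
    return(list(t = sign(m) * Inf, p = 0, diffs = diffs))
  }
  t <- m / (sdev / sqrt(trials))
  list(t = t, p = 2 * stats::pt(-abs(t), df = trials - 1L),
       diffs = diffs)
}
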