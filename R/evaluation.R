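#' Confusion counts at a threshold
#'
#' Scores greater than or equal to the threshold are called positive
#' (boundary inclusive).
#'
#' @param scores numeric prediction scores.
#' @param labels binary truth (1/TRUE = positive).
#' @param threshold decision threshold.
#' @return named list with `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_counts <- function(scores, labels, threshold = 0) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  call_pos <- scores >= threshold
  list(TP = sum(call_pos & labels), FP = sum(call_pos & !labels),
       TN = sum(!call_pos & !labels), FN = sum(!call_pos & labels))
}

#' Threshold-dependent performance metrics
#'
#' Sensitivity `100*TP/(TP+FN)`, specificity `100*TN/(TN+FP)`, accuracy
#' `100*(TP+TN)/total` and the Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`. When any factor
#' of the MCC denominator is zero the MCC is reported as 0 (the usual
#' degenerate-table convention).
#'
#' @param counts list with `TP`, `FP`, `TN`, `FN` (see [confusion_counts()]).
#' @return named numeric vector `Sens`, `Spec`, `Acc`, `MCC`.
#' @export
compute_metrics <- function(counts) {
  tp <- as.numeric(counts$TP); fp <- as.numeric(counts$FP)
  tn <- as.numeric(counts$TN); fn <- as.numeric(counts$FN)
  stopifnot(all(c(tp, fp, tn, fn) >= 0))
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion table")
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  c(Sens = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    Spec = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    Acc = 100 * (tp + tn) / total,
    MCC = mcc)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve over all distinct score
#' thresholds; with ties this equals the tie-corrected Mann-Whitney
#' pair-counting statistic (concordant pairs plus half the tied pairs over
#' all positive x negative pairs).
#'
#' @param scores numeric prediction scores.
#' @param labels binary truth (1/TRUE = positive); both classes required.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  r <- roc_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + r$tpr[-1]) / 2)
}

# ROC curve points (FPR, TPR) at every distinct score cut, from (0,0) to
# (1,1), scores sorted decreasing so both coordinates are nondecreasing.
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  if (!any(labels) || all(labels))
    stop("ROC needs both positive and negative labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # last element of each tie block -> one ROC point per distinct score
  keep <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[keep]; fp <- cumsum(!y)[keep]
  list(fpr = c(0, fp / sum(!labels)), tpr = c(0, tp / sum(labels)),
       cut = c(Inf, s[keep]))
}

#' Metrics across a set of thresholds
#'
#' One row per threshold with the counts and metrics at that cut (score >=
#' threshold is positive). Sensitivity is nonincreasing and specificity
#' nondecreasing as the threshold rises.
#'
#' @inheritParams roc_auc
#' @param thresholds numeric vector of decision thresholds.
#' @return data.frame with columns `threshold`, `TP`, `FP`, `TN`, `FN`,
#'   `Sens`, `Spec`, `Acc`, `MCC`.
#' @export
threshold_table <- function(scores, labels, thresholds) {
  if (!length(thresholds)) stop("empty threshold list")
  rows <- lapply(thresholds, function(t) {
    cc <- confusion_counts(scores, labels, t)
    c(threshold = t, unlist(cc), compute_metrics(cc))
  })
  as.data.frame(do.call(rbind, rows))
}

# Threshold maximizing MCC over the observed score cuts (ties -> lowest
# such threshold). Candidate cuts are the distinct scores plus +Inf.
best_mcc_threshold <- function(scores, labels) {
  cand <- sort(unique(scores))
  tab <- threshold_table(scores, labels, cand)
  best <- which.max(tab$MCC)
  list(threshold = tab$threshold[best], metrics = tab[best, ])
}

#' Stratified k-fold cross-validation
#'
#' Partitions the dataset into `folds` stratified parts; each peptide is
#' scored exactly once by a model trained without it. Any data-dependent
#' encoder artifact (the AAP propensity scale, feature standardisation) is
#' refitted inside each training fold, so no information leaks from the
#' test fold. Pooled test-fold scores give the AUC and a single
#' maximum-MCC operating point; per-fold AUCs are reported alongside.
#'
#' @param ds `labeled_dataset`.
#' @param cfg `train_config`.
#' @param folds number of folds (5 and 10 are the conventional choices).
#' @param seed integer seed for the fold assignment.
#' @return object of class `cv_report`: list with `scores`, `labels`,
#'   `fold`, `auc`, `best` (threshold + metrics at the pooled maximum-MCC
#'   cut) and `per_fold` (fold-wise AUC).
#' @export
cross_validate <- function(ds, cfg, folds = 5L, seed = 1L) {
  stopifnot(inherits(ds, "labeled_dataset"), folds >= 2L)
  xy <- dataset_xy(ds)
  n <- length(xy$seq)
  fold <- integer(n)
  if (folds == n) {          # leave-one-out: every peptide its own fold
    fold <- seq_len(n)
  } else {
    fold[xy$y == 1L] <- with_seed(seed, strat_folds(sum(xy$y == 1L), folds))
    fold[xy$y == 0L] <- with_seed(seed + 1L,
                                  strat_folds(sum(xy$y == 0L), folds))
  }
  # every training complement must keep both classes (test folds may be
  # single-class, e.g. leave-one-out)
  if (max(tabulate(fold[xy$y == 1L], folds)) >= sum(xy$y == 1L) ||
      max(tabulate(fold[xy$y == 0L], folds)) >= sum(xy$y == 0L))
    stop("a class is too small for ", folds, "-fold stratification")
  scores <- numeric(n)
  for (k in seq_len(folds)) {
    te <- fold == k
    if (!any(te)) next   # a fold can be empty when folds > n
    sub <- new_dataset(ds$class_name, ds$design,
                       ds$positives[fold[xy$y == 1L] != k, , drop = FALSE],
                       ds$negatives[fold[xy$y == 0L] != k, , drop = FALSE])
    bundle <- train_model(sub, cfg, threshold = 0)
    scores[te] <- score_peptides(bundle, xy$seq[te])
  }
  per_fold <- vapply(seq_len(folds), function(k) {
    yk <- xy$y[fold == k]
    if (length(unique(yk)) < 2L) return(NA_real_)  # single-class test fold
    roc_auc(scores[fold == k], yk)
  }, numeric(1))
  structure(list(scores = scores, labels = xy$y, fold = fold,
                 auc = roc_auc(scores, xy$y),
                 best = best_mcc_threshold(scores, xy$y),
                 per_fold = data.frame(fold = seq_len(folds),
                                       AUC = per_fold)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  m <- x$best$metrics
  cat(sprintf(
    "<cv_report> %d-fold | AUC %.3f | at threshold %.3f: Acc %.2f MCC %.3f\n",
    max(x$fold), x$auc, x$best$threshold, m$Acc, m$MCC))
  invisible(x)
}

# Balanced fold labels for n instances (sizes differ by at most one);
# which folds take the extra instances is itself random. Call under a
# set seed.
strat_folds <- function(n, folds) {
  sample(rep_len(sample(folds), n))
}
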