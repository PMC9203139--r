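.check_labels <- function(labels) {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (length(unique(labels)) < 2) stop("both classes must be present")
  labels
}

#' Area under the precision-recall curve (average precision)
#'
#' Uses the step-wise average-precision convention: scores are sorted
#' decreasing, equal scores are grouped into a single threshold step, and the
#' area is `sum(delta_recall * precision)` across steps. Under this convention
#' a constant-score (no-skill) classifier attains exactly the event
#' prevalence, the anchor used when training under the PR curve in imbalanced
#' cohorts. No linear interpolation is applied (linear PR interpolation is
#' biased and would break the prevalence identity).
#'
#' @param scores numeric risk scores (larger = more likely positive).
#' @param labels binary labels (1 = event/death).
#' @return scalar in (0, 1].
#' @export
prAUC <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  P <- sum(labels)
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  prec <- tp / n_at
  d_tp <- diff(c(0, tp))
  sum(d_tp / P * prec)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with ties counted one
#' half.
#'
#' @inheritParams prAUC
#' @return scalar in \[0, 1\].
#' @export
rocAUC <- function(scores, labels) {
  labels <- .check_labels(labels)
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))
  n1 <- sum(labels); n0 <- sum(!labels)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity and specificity at a probability threshold
#'
#' Predicts positive (death) iff `score >= threshold`. Sensitivity is
#' TP/(TP+FN) on the event class, specificity TN/(TN+FP). An empty class
#' yields `NaN` with a warning.
#'
#' @param scores probability-scale scores.
#' @param labels binary labels (1 = event).
#' @param threshold classification threshold in \[0, 1\] (default 0.5).
#' @return named numeric: `sensitivity`, `specificity`.
#' @export
confusionMetrics <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  stopifnot(all(labels %in% c(0L, 1L)), threshold >= 0, threshold <= 1)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0); fp <- sum(pred == 1 & labels == 0)
  sens <- if (tp + fn == 0) { warning("no positives; sensitivity undefined"); NaN
  } else tp / (tp + fn)
  spec <- if (tn + fp == 0) { warning("no negatives; specificity undefined"); NaN
  } else tn / (tn + fp)
  c(sensitivity = sens, specificity = spec)
}

#' Repeated stratified k-fold plan
#'
#' Builds `n_repeats` independent stratified partitions of the cohort into
#' `n_folds` folds. Within each repeat, each class is shuffled and dealt
#' round-robin, so per-fold event counts differ by at most one from
#' proportional allocation (a 60-sample, 25-event cohort in 5 folds gives
#' exactly 12 samples and 5 events per fold). Deterministic given the seed;
#' each repeat uses its own derived substream.
#'
#' @param outcomes binary vector or survived/died factor, one per sample.
#' @param n_folds folds per repeat (default 5).
#' @param n_repeats repeats (default 50).
#' @param stratified stratify on the outcome (default `TRUE`).
#' @param seed integer seed.
#' @return list of class `FoldPlan`: `splits` (list of lists with
#'   `repeat_index`, `fold_index`, `train`, `test` integer indices), `n`,
#'   `n_folds`, `n_repeats`.
#' @export
makeFoldPlan <- function(outcomes, n_folds = 5L, n_repeats = 50L,
                         stratified = TRUE, seed = 1L) {
  if (is.factor(outcomes)) outcomes <- as.integer(outcomes == "died")
  outcomes <- .check_labels(outcomes)
  stopifnot(n_folds >= 2, n_repeats >= 1)
  n <- length(outcomes)
  if (min(table(outcomes)) < n_folds)
    stop("each class needs at least n_folds members")
  splits <- vector("list", n_folds * n_repeats)
  k <- 0L
  for (r in seq_len(n_repeats)) {
    fold_of <- integer(n)
    .with_seed(.substream(seed, 100L + r), {
      if (stratified) {
        for (cls in unique(outcomes)) {
          idx <- sample(which(outcomes == cls))
          fold_of[idx] <- rep_len(seq_len(n_folds), length(idx))
        }
      } else {
        fold_of[sample.int(n)] <- rep_len(seq_len(n_folds), n)
      }
    })
    for (f in seq_len(n_folds)) {
      k <- k + 1L
      splits[[k]] <- list(repeat_index = r, fold_index = f,
                          train = which(fold_of != f),
                          test = which(fold_of == f))
    }
  }
  structure(list(splits = splits, n = n, n_folds = as.integer(n_folds),
                 n_repeats = as.integer(n_repeats)),
            class = "FoldPlan")
}

#' @export
print.FoldPlan <- function(x, ...) {
  cat("FoldPlan:", x$n_repeats, "repeats x", x$n_folds, "folds over",
      x$n, "samples (", length(x$splits), "splits )\n")
  invisible(x)
}
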