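# Performance metrics and evaluation protocols.
#
# Holdout evaluation uses positives only: with no labeled negatives there
# is nothing to hold out from the unlabeled pool, so sensitivity is the
# metric that remains meaningful (on a positives-only holdout it coincides
# with accuracy).

#' Confusion counts
#'
#' @param tp,tn,fp,fn Non-negative integer tallies.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp = 0L, tn = 0L, fp = 0L, fn = 0L) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  v <- as.integer(v)
  structure(list(tp = v[1L], tn = v[2L], fp = v[3L], fn = v[4L]),
            class = "confusion_counts")
}

#' Accuracy
#'
#' Ratio of correct predictions to the total number of predictions:
#' (tp + tn) / (tp + tn + fp + fn).
#'
#' @param c A [confusion_counts()].
#' @return Fraction in \[0, 1\].
#' @export
accuracy <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  total <- c$tp + c$tn + c$fp + c$fn
  if (total == 0L) stop("no predictions", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Sensitivity (recall, true-positive rate)
#'
#' Fraction of true positives predicted positive: tp / (tp + fn).
#'
#' @param c A [confusion_counts()].
#' @return Fraction in \[0, 1\].
#' @export
sensitivity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$tp + c$fn == 0L) stop("no positive examples", call. = FALSE)
  c$tp / (c$tp + c$fn)
}

#' Holdout evaluation on left-out positives
#'
#' Scores a holdout set assumed all-positive with the final model.  Only
#' tp/fn are populated (fp = tn = 0) and sensitivity is the reported
#' metric; misclassified ids are listed.
#'
#' @param model A `pu_model` from [run_pu()].
#' @param holdout Non-empty sequence records, all positive by assumption.
#' @return List with `counts` ([confusion_counts()]), `sensitivity`,
#'   `predictions` (per-sequence data frame) and `misclassified` (ids
#'   predicted negative).
#' @export
evaluate_holdout <- function(model, holdout) {
  holdout <- .as_records(holdout)
  if (nrow(holdout) == 0L) stop("empty holdout set", call. = FALSE)
  pred <- predict(model, holdout)
  tp <- sum(pred$label == "positive")
  fn <- sum(pred$label == "negative")
  counts <- confusion_counts(tp = tp, fn = fn)
  list(counts = counts,
       sensitivity = sensitivity(counts),
       predictions = pred,
       misclassified = pred$id[pred$label == "negative"])
}

#' Stratified k-fold cross-validation
#'
#' Splits positives and negatives separately into k seeded folds, trains
#' the factory's classifier on the complement of each fold and reports
#' per-fold accuracy and sensitivity plus their means.
#'
#' @param X_pos Feature matrix of positive examples.
#' @param X_neg Feature matrix of negative examples.
#' @param k Number of folds (>= 2).
#' @param factory A [classifier_factory()].
#' @param seed Integer seed for the fold assignment.
#' @return List with `folds` (per-fold data frame) and `mean_accuracy`,
#'   `mean_sensitivity`.
#' @export
cross_validate <- function(X_pos, X_neg, k = 5L,
                           factory = classifier_factory(), seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  n_p <- nrow(X_pos)
  n_n <- nrow(X_neg)
  if (n_p < k || n_n < k) {
    stop("a fold would be missing a class: need >= k examples per class",
         call. = FALSE)
  }
  assign_p <- .with_seed(seed, sample(rep_len(seq_len(k), n_p)))
  assign_n <- .with_seed(seed + 1L, sample(rep_len(seq_len(k), n_n)))

  rows <- lapply(seq_len(k), function(f) {
    Xtr <- rbind(X_pos[assign_p != f, , drop = FALSE],
                 X_neg[assign_n != f, , drop = FALSE])
    ytr <- c(rep("c1", sum(assign_p != f)), rep("c2", sum(assign_n != f)))
    clf <- factory$train(Xtr, ytr, seed = seed + f)
    p_pos <- predict_proba(clf, X_pos[assign_p == f, , drop = FALSE])
    p_neg <- predict_proba(clf, X_neg[assign_n == f, , drop = FALSE])
    cc <- confusion_counts(tp = sum(p_pos >= 0.5), fn = sum(p_pos < 0.5),
                           tn = sum(p_neg < 0.5), fp = sum(p_neg >= 0.5))
    data.frame(fold = f, n_pos = sum(assign_p == f), n_neg = sum(assign_n == f),
               accuracy = accuracy(cc), sensitivity = sensitivity(cc))
  })
  folds <- do.call(rbind, rows)
  list(folds = folds,
       mean_accuracy = mean(folds$accuracy),
       mean_sensitivity = mean(folds$sensitivity))
}
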