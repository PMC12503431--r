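## Self-contained evaluation statistics and leak-free patient-level
## splitting. The four headline metrics (accuracy, weighted F1, AUROC,
## AUPRC) are implemented directly from their definitions so that tests can
## hold them against brute-force oracles and an independent reference.

#' Classification accuracy
#' @param labels,predictions equal-length vectors of class labels.
#' @return fraction of exact matches.
#' @export
accuracy <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) < 1)
    err("labels and predictions must have equal length >= 1",
        "endoscreen_argument_error")
  mean(labels == predictions)
}

#' Support-weighted F1 score
#'
#' Per-class F1 (taken as 0 when precision + recall is 0) averaged with
#' weights equal to each class's share of the true labels.
#'
#' @param labels,predictions equal-length vectors of class labels.
#' @return real in `[0, 1]`.
#' @export
weighted_f1 <- function(labels, predictions) {
  if (length(labels) != length(predictions) || length(labels) < 1)
    err("labels and predictions must have equal length >= 1",
        "endoscreen_argument_error")
  classes <- sort(unique(labels))
  total <- 0
  for (cl in classes) {
    tp <- sum(labels == cl & predictions == cl)
    fp <- sum(labels != cl & predictions == cl)
    fn <- sum(labels == cl & predictions != cl)
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    total <- total + f1 * sum(labels == cl) / length(labels)
  }
  total
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly drawn positive outscores a uniformly
#' drawn negative, with ties counted one half. Computed from midranks.
#'
#' @param labels binary labels (0/1 or logical).
#' @param scores numeric scores, higher = more positive.
#' @return real in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    err("labels and scores must have equal length", "endoscreen_argument_error")
  np <- sum(labels == 1)
  nn <- sum(labels == 0)
  if (np == 0 || nn == 0)
    err("AUROC is undefined with a single class", "endoscreen_metric_error")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * nn)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-interpolated average precision: the sum over score-descending
#' thresholds of (recall increment x precision at that threshold), with
#' equal scores grouped into a single threshold.
#'
#' @param labels binary labels (0/1 or logical).
#' @param scores numeric scores.
#' @return real in `(0, 1]`.
#' @export
auprc <- function(labels, scores) {
  labels <- as.integer(labels)
  if (length(labels) != length(scores))
    err("labels and scores must have equal length", "endoscreen_argument_error")
  np <- sum(labels == 1)
  if (np == 0)
    err("AUPRC is undefined without positives", "endoscreen_metric_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- which(s != c(s[-1], NA_real_) | seq_along(s) == length(s))
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / np
  rec_prev <- c(0, recall[-length(recall)])
  sum((recall - rec_prev) * precision)
}

#' Bundle the four headline metrics into one report
#'
#' @param labels binary labels.
#' @param scores positive-class probabilities.
#' @param threshold decision threshold applied to `scores` for accuracy and
#'   weighted F1.
#' @param level `"frame"` or `"patient"`.
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(labels, scores, threshold = 0.5,
                           level = c("frame", "patient")) {
  level <- match.arg(level)
  preds <- as.integer(scores >= threshold)
  structure(list(accuracy = accuracy(labels, preds),
                 weighted_f1 = weighted_f1(labels, preds),
                 auroc = auroc(labels, scores),
                 auprc = auprc(labels, scores),
                 n_samples = length(labels),
                 level = level),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> %s level, n = %d\n  accuracy %.3f  weighted F1 %.3f  AUROC %.3f  AUPRC %.3f\n",
    x$level, x$n_samples, x$accuracy, x$weighted_f1, x$auroc, x$auprc))
  invisible(x)
}

#' Leak-free patient-level train/test split
#'
#' Splits patients (never frames) into disjoint, exhaustive train and test
#' sets. Under stratification the test set has `round(test_fraction * n)`
#' patients allocated across classes by largest remainder, with at least one
#' test patient per class.
#'
#' @param patient_ids vector of unique patient identifiers.
#' @param labels per-patient binary labels (required when `stratify = TRUE`).
#' @param test_fraction fraction of patients held out.
#' @param stratify preserve class proportions.
#' @param seed integer seed; the split is deterministic given it.
#' @return list with `train` and `test` id vectors.
#' @export
patient_split <- function(patient_ids, labels = NULL, test_fraction = 0.2,
                          stratify = TRUE, seed = 1L) {
  patient_ids <- as.character(patient_ids)
  if (anyDuplicated(patient_ids))
    err("patient_ids must be unique", "endoscreen_argument_error")
  n <- length(patient_ids)
  n_test <- round(test_fraction * n)
  if (!stratify) {
    test <- with_seed(seed, sample(patient_ids, n_test))
    return(list(train = setdiff(patient_ids, test), test = test))
  }
  if (is.null(labels) || length(labels) != n)
    err("stratified splitting needs one label per patient",
        "endoscreen_argument_error")
  classes <- sort(unique(labels))
  counts <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  if (any(counts < 2))
    err("stratification needs at least 2 patients per class",
        "endoscreen_argument_error")
  n_test <- max(n_test, length(classes))
  exact <- test_fraction * counts
  base <- pmax(floor(exact), 1L)
  while (sum(base) > n_test) {
    i <- which(base == max(base[base > 1L]) & base > 1L)[1]
    base[i] <- base[i] - 1L
  }
  rem <- exact - base
  while (sum(base) < n_test) {
    i <- which.max(rem)
    base[i] <- base[i] + 1L
    rem[i] <- -Inf
  }
  test <- with_seed(seed, {
    unlist(lapply(seq_along(classes), function(i) {
      ids <- patient_ids[labels == classes[i]]
      sample(ids, base[i])
    }))
  })
  list(train = setdiff(patient_ids, test), test = test)
}
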