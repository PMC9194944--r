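#' @name evaluation
#' @title Classification metrics, ROC/AUC and validation protocols
#'
#' @description
#' Threshold metrics follow the standard confusion-matrix definitions:
#' recall (sensitivity) `TP/(TP+FN)`, precision `TP/(TP+FP)`, accuracy
#' `(TP+TN)/(TP+FP+TN+FN)`, F1 the harmonic mean of precision and recall;
#' specificity `TN/(TN+FP)` is reported alongside. The AUC is the area
#' under the ROC curve by the trapezoidal rule, which with tie handling is
#' the normalised Mann-Whitney statistic (0.5 credit for ties).
NULL

#' Confusion counts from labels and predictions
#'
#' @param truth binary truth labels (0/1).
#' @param predicted binary predicted labels (0/1).
#' @return Named integer vector `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(truth, predicted) {
  truth <- as.integer(truth)
  predicted <- as.integer(predicted)
  stopifnot(length(truth) == length(predicted),
            all(truth %in% 0:1), all(predicted %in% 0:1))
  c(tp = sum(truth == 1L & predicted == 1L),
    tn = sum(truth == 0L & predicted == 0L),
    fp = sum(truth == 0L & predicted == 1L),
    fn = sum(truth == 1L & predicted == 0L))
}

#' Threshold classification metrics
#'
#' Metrics with a zero denominator (e.g. precision with no positive
#' predictions) are reported as `NA` and named in the `undefined`
#' attribute, never silently coerced to 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts; alternatively pass a
#'   named vector from [confusion_counts()] as `tp`.
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`,
#'   `specificity`, with attribute `undefined`.
#' @export
compute_metrics <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (length(tp) == 4L && is.null(tn)) {
    counts <- tp
    tp <- counts[["tp"]]; tn <- counts[["tn"]]
    fp <- counts[["fp"]]; fn <- counts[["fn"]]
  }
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  if (sum(counts) == 0) stop("no evaluated samples (all counts zero)")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  recall <- safe_div(tp, tp + fn)
  precision <- safe_div(tp, tp + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0)
    NA_real_ else 2 * precision * recall / (precision + recall)
  out <- c(accuracy = (tp + tn) / sum(counts),
           precision = precision, recall = recall, f1 = f1,
           specificity = safe_div(tn, tn + fp))
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' ROC curve and trapezoidal AUC
#'
#' Scores tied at the same value move along the curve together, so the
#' trapezoidal area equals the Mann-Whitney statistic with half credit for
#' tied positive/negative pairs.
#'
#' @param scores per-sample positive-class scores or probabilities.
#' @param labels binary truth labels (0/1); both classes must be present.
#' @return List with `auc` and `curve` (data frame of `fpr`, `tpr`,
#'   `threshold`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% 0:1))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("AUC needs both classes present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # collapse tied scores into single curve steps
  grp <- cumsum(!duplicated(s))
  tp_steps <- tapply(l == 1L, grp, sum)
  fp_steps <- tapply(l == 0L, grp, sum)
  tpr <- c(0, cumsum(tp_steps) / n_pos)
  fpr <- c(0, cumsum(fp_steps) / n_neg)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  curve <- data.frame(fpr = fpr, tpr = tpr,
                      threshold = c(Inf, unique(s)))
  list(auc = unname(auc), curve = curve)
}

#' Stratified train/test hold-out split
#'
#' Splits per class at the given train fraction (floor of the per-class
#' train counts, matching an 8:2 protocol in which 456 samples at 1:2
#' class balance give 364 train and 92 test).
#'
#' @param records list of labelled `protein_record`s, or a bare 0/1 label
#'   vector.
#' @param ratio train fraction in (0, 1); default 0.8.
#' @param seed RNG seed.
#' @return List with `train` and `test`: record lists (or index vectors if
#'   `records` was a label vector).
#' @export
holdout_split <- function(records, ratio = 0.8, seed = 1L) {
  if (!is.numeric(ratio) || ratio <= 0 || ratio >= 1)
    stop("'ratio' must be a train fraction strictly between 0 and 1")
  bare <- !is.list(records)
  y <- if (bare) as.integer(records) else record_labels(records)
  if (length(unique(y)) < 2L) stop("hold-out split needs both classes")
  set.seed(seed)
  train_idx <- integer(0)
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    n_train <- floor(length(idx) * ratio)
    train_idx <- c(train_idx, sample(idx, n_train))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  if (bare) return(list(train = train_idx, test = test_idx))
  list(train = records[train_idx], test = records[test_idx])
}
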