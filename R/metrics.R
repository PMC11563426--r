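# Confusion-matrix metrics, ROC/AUC, and stratified splitting.

#' Confusion counts for binary predictions
#'
#' Standard 2x2 cross-tabulation with 1 = positive class.
#'
#' @param truth,pred 0/1 vectors of equal length.
#' @return Named list with integer `TP`, `FP`, `TN`, `FN`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stop("length mismatch")
  if (!all(truth %in% c(0, 1)) || !all(pred %in% c(0, 1))) {
    stop("truth and pred must be 0/1")
  }
  truth <- as.integer(truth); pred <- as.integer(pred)
  list(TP = sum(truth == 1L & pred == 1L),
       FP = sum(truth == 0L & pred == 1L),
       TN = sum(truth == 0L & pred == 0L),
       FN = sum(truth == 1L & pred == 0L))
}

#' Metrics from confusion counts
#'
#' Sensitivity (true positive rate) TP/(TP+FN), specificity (true negative
#' rate) TN/(TN+FP), accuracy (TP+TN)/total, and the Matthews correlation
#' coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' All reported as fractions (accuracy 0.917, not 91.7). Zero denominators:
#' sensitivity/specificity become `NA` (undefined), MCC is defined as 0.
#'
#' @param c Confusion counts from [confusion()].
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `mcc`.
#' @export
metrics_from_confusion <- function(c) {
  stopifnot(all(c(c$TP, c$FP, c$TN, c$FN) >= 0))
  total <- c$TP + c$FP + c$TN + c$FN
  if (total == 0) stop("empty confusion")
  sn <- if (c$TP + c$FN > 0) c$TP / (c$TP + c$FN) else NA_real_
  sp <- if (c$TN + c$FP > 0) c$TN / (c$TN + c$FP) else NA_real_
  acc <- (c$TP + c$TN) / total
  denom <- as.numeric(c$TP + c$FP) * (c$TP + c$FN) * (c$TN + c$FP) * (c$TN + c$FN)
  mcc <- if (denom > 0) {
    (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) / sqrt(denom)
  } else 0
  list(sensitivity = sn, specificity = sp, accuracy = acc, mcc = mcc)
}

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a uniformly chosen
#' positive outscores a uniformly chosen negative, with ties counted half.
#' Invariant under strictly monotone transforms of the scores.
#'
#' @param truth 0/1 vector; both classes must be present.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% c(0, 1)))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' False/true positive rates over all score thresholds, for plotting or
#' export. Points are ordered from (0, 0) to (1, 1).
#'
#' @inheritParams roc_auc
#' @return data.frame with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(truth, scores) {
  stopifnot(length(truth) == length(scores), all(truth %in% c(0, 1)))
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  pts <- t(vapply(thr, function(t) {
    pred <- scores >= t
    c(fpr = sum(pred & truth == 0) / n0, tpr = sum(pred & truth == 1) / n1)
  }, numeric(2)))
  data.frame(threshold = thr, fpr = pts[, "fpr"], tpr = pts[, "tpr"])
}

#' Stratified k-fold partition
#'
#' Shuffles each class independently (seed-deterministic) and deals members
#' round-robin into k folds, so per-fold class counts differ from perfect
#' proportionality by at most one instance. Folds partition all indices.
#'
#' @param labels 0/1 vector.
#' @param k Number of folds (each class must have at least k members).
#' @param seed Integer seed.
#' @return List of k integer index vectors (the held-out sets).
#' @export
stratified_kfold <- function(labels, k = 10L, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(k >= 2L, all(labels %in% c(0L, 1L)))
  if (any(table(factor(labels, levels = 0:1)) < k)) {
    stop("each class needs at least k = ", k, " members")
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- vector("list", k)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    assignment <- rep_len(seq_len(k), length(idx))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], idx[assignment == f])
  }
  lapply(folds, sort)
}

#' Stratified train/test split
#'
#' @param labels 0/1 vector.
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed.
#' @return List with integer vectors `train` and `test`; per-class test
#'   proportions match `1 - train_fraction` within one instance.
#' @export
train_test_split <- function(labels, train_fraction = 0.8, seed = 1L) {
  labels <- as.integer(labels)
  stopifnot(train_fraction > 0, train_fraction < 1)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  train <- integer(0)
  for (cls in c(0L, 1L)) {
    idx <- sample(which(labels == cls))
    n_tr <- round(length(idx) * train_fraction)
    train <- c(train, idx[seq_len(n_tr)])
  }
  train <- sort(train)
  list(train = train, test = setdiff(seq_along(labels), train))
}
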