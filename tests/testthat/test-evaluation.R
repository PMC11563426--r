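test_that("confusion counts match a brute-force recount", {
  expect_equal(confusion(rep(1, 10), rep(1, 10)),
               list(TP = 10L, FP = 0L, TN = 0L, FN = 0L))
  expect_equal(confusion(c(1, 0, 1), c(0, 1, 0)),
               list(TP = 0L, FP = 1L, TN = 0L, FN = 2L))
  set.seed(31)
  for (i in 1:25) {
    n <- sample(5:50, 1)
    tr <- sample(0:1, n, replace = TRUE)
    pr <- sample(0:1, n, replace = TRUE)
    cc <- confusion(tr, pr)
    o <- oracle_confusion(tr, pr)
    expect_equal(unlist(cc), o)
    expect_equal(sum(unlist(cc)), n)
  }
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("metrics reproduce worked confusion examples exactly", {
  m1 <- metrics_from_confusion(list(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(m1), c(sensitivity = 1, specificity = 1,
                             accuracy = 1, mcc = 1))
  m2 <- metrics_from_confusion(list(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$mcc, 0)
  m3 <- metrics_from_confusion(list(TP = 90, FN = 10, TN = 80, FP = 20))
  expect_equal(m3$sensitivity, 0.9)
  expect_equal(m3$specificity, 0.8)
  expect_equal(m3$accuracy, 0.85)
  expect_equal(m3$mcc, 7000 / sqrt(110 * 100 * 100 * 90))
  expect_equal(m3$mcc, 0.7035, tolerance = 1e-4)
})

test_that("metrics agree with independent recomputation on 1000 random tables", {
  set.seed(17)
  for (i in 1:1000) {
    cts <- as.list(sample(0:40, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    if (sum(unlist(cts)) == 0) cts$TP <- 1L
    m <- metrics_from_confusion(cts)
    tp <- cts$TP; fp <- cts$FP; tn <- cts$TN; fn <- cts$FN
    expect_equal(m$accuracy, (tp + tn) / (tp + fp + tn + fn))
    if (tp + fn > 0) expect_equal(m$sensitivity, tp / (tp + fn))
    if (tn + fp > 0) expect_equal(m$specificity, tn / (tn + fp))
    den <- sqrt(as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
    expect_equal(m$mcc, if (den > 0) (tp * tn - fp * fn) / den else 0)
    expect_true(m$mcc >= -1 && m$mcc <= 1)
  }
})

test_that("MCC is symmetric under simultaneous class swap", {
  set.seed(3)
  for (i in 1:50) {
    cts <- as.list(sample(1:30, 4, replace = TRUE))
    names(cts) <- c("TP", "FP", "TN", "FN")
    swapped <- list(TP = cts$TN, FP = cts$FN, TN = cts$TP, FN = cts$FP)
    expect_equal(metrics_from_confusion(cts)$mcc,
                 metrics_from_confusion(swapped)$mcc)
  }
})

test_that("AUC matches pairwise enumeration and is rank-invariant", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 1, 0, 0), rep(0.5, 4)), 0.5)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.5, 0.1)), 0.75)
  set.seed(8)
  for (i in 1:30) {
    n <- sample(6:30, 1)
    tr <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    sc <- round(runif(n), 2)   # rounding forces ties
    a <- roc_auc(tr, sc)
    expect_equal(a, oracle_auc(tr, sc))
    # strictly monotone transforms leave AUC unchanged
    expect_equal(roc_auc(tr, exp(3 * sc) - 1), a)
    expect_equal(roc_auc(tr, rank(sc, ties.method = "average")), a)
  }
  expect_error(roc_auc(rep(1, 5), runif(5)), "both classes")
})

test_that("ROC points run from (0,0) to (1,1) with matching trapezoid area", {
  set.seed(9)
  tr <- sample(0:1, 40, replace = TRUE, prob = c(0.6, 0.4))
  sc <- runif(40)
  pts <- roc_points(tr, sc)
  expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
  expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
  area <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  expect_equal(area, roc_auc(tr, sc))
})

test_that("stratified folds partition indices with balanced class counts", {
  y <- c(rep(1L, 394), rep(0L, 848))
  folds <- stratified_kfold(y, k = 10, seed = 99)
  expect_length(folds, 10)
  expect_identical(sort(unlist(folds)), seq_along(y))
  pos_per_fold <- vapply(folds, function(f) sum(y[f] == 1L), integer(1))
  expect_true(all(pos_per_fold %in% c(39L, 40L)))
  neg_per_fold <- vapply(folds, function(f) sum(y[f] == 0L), integer(1))
  expect_true(all(abs(neg_per_fold - 84.8) <= 1))

  y2 <- rep(c(0L, 1L), 50)
  f2 <- stratified_kfold(y2, k = 10, seed = 1)
  expect_true(all(lengths(f2) == 10))
  expect_identical(stratified_kfold(y2, k = 10, seed = 1), f2)
  expect_error(stratified_kfold(c(rep(0, 20), rep(1, 3)), k = 5), "at least k")
})

test_that("80/20 split preserves class proportions within one instance", {
  y <- c(rep(1L, 394), rep(0L, 848))
  sp <- train_test_split(y, 0.8, seed = 5)
  expect_identical(sort(c(sp$train, sp$test)), seq_along(y))
  expect_equal(sum(y[sp$train] == 1L), 315)  # round(394 * 0.8)
  expect_equal(sum(y[sp$train] == 0L), 678)  # round(848 * 0.8)
})

test_that("evaluation reports round-trip through JSON", {
  d <- small_dataset(n_pos = 15, n_neg = 25, delta = 2, seed = 2)
  rep_ <- run_protocol(d, encoders = "AAC",
                       model = single_config("decision-tree"),
                       protocol = "cv10", folds = 3, seed = 4)
  expect_s3_class(rep_, "eval_report")
  expect_equal(nrow(rep_$folds), 3)
  expect_true(all(rep_$folds$accuracy >= 0 & rep_$folds$accuracy <= 1))
  expect_equal(rep_$aggregate$accuracy, mean(rep_$folds$accuracy))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep_, path)
  back <- read_eval_report(path)
  expect_equal(back$protocol$name, "cv10")
  expect_equal(back$protocol$folds, 3)
  expect_equal(back$protocol$seed, 4)
  expect_equal(back$aggregate$accuracy, rep_$aggregate$accuracy)
  expect_equal(back$folds$mcc, rep_$folds$mcc)
})

test_that("fold-internal balancing changes training only, not the test rows", {
  d <- small_dataset(n_pos = 12, n_neg = 36, delta = 2, seed = 6)
  m <- encode_dataset(d, "AAC")
  rep_ <- evaluate_matrix(m, d$label, model = single_config("decision-tree"),
                          balance = balance_config("ADASYN"),
                          protocol = "cv10", folds = 3, seed = 2)
  # every fold still evaluates only original rows: counts sum to dataset size
  expect_equal(sum(rep_$folds$TP + rep_$folds$FP + rep_$folds$TN + rep_$folds$FN),
               nrow(d))
})
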