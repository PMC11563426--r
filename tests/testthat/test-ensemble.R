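test_that("default hyperparameters carry the tuned configuration", {
  rf <- default_hyperparameters("random-forest")
  expect_equal(rf$n_estimators, 300L)
  expect_equal(rf$max_depth, 30L)
  expect_equal(rf$min_samples_split, 5L)
  dt <- default_hyperparameters("decision-tree")
  expect_equal(dt$criterion, "entropy")
  expect_equal(dt$min_samples_split, 5L)
  expect_error(default_hyperparameters("quantum-leap"), "unknown")
  expect_identical(default_base_learners(),
                   c("random-forest", "decision-tree", "support-vector-machine",
                     "k-nearest-neighbors", "gradient-boosting-machine"))
})

test_that("single learners reach training accuracy 1 on separable data", {
  d <- separable_matrix()
  for (kind in c("decision-tree", "random-forest", "gradient-boosting-machine")) {
    fit <- fit_single(d$m, d$y, kind, seed = 3)
    p <- predict_single(fit, d$m)
    expect_true(all(p >= 0 & p <= 1))
    expect_equal(as.integer(p >= 0.5), d$y)
  }
  # 1-NN memorises its training set
  knn1 <- fit_single(d$m, d$y, "k-nearest-neighbors",
                     hyperparameters = list(k = 1L), seed = 1)
  expect_equal(as.integer(predict_single(knn1, d$m) >= 0.5), d$y)
})

test_that("same-seed refits are deterministic for stochastic learners", {
  d <- separable_matrix(n_per_class = 15, seed = 2)
  for (kind in c("random-forest", "support-vector-machine",
                 "gradient-boosting-machine")) {
    f1 <- fit_single(d$m, d$y, kind, seed = 42)
    f2 <- fit_single(d$m, d$y, kind, seed = 42)
    expect_identical(predict_single(f1, d$m), predict_single(f2, d$m))
  }
})

test_that("stacking trains a cross-fitted meta-learner over 5 base columns", {
  d <- separable_matrix(n_per_class = 25, seed = 8)
  fit <- fit_stacking(d$m, d$y, seed = 5)
  expect_s3_class(fit, "stacking_model")
  expect_length(fit$base_fits, 5)
  expect_length(stats::coef(fit$meta), 6)   # intercept + one per base learner
  pr <- predict_stacking(fit, d$m)
  expect_true(all(pr$score >= 0 & pr$score <= 1))
  expect_equal(pr$label, d$y)               # separable => perfect training fit

  refit <- fit_stacking(d$m, d$y, seed = 5)
  expect_identical(predict_stacking(refit, d$m)$score, pr$score)
})

test_that("prediction realigns feature columns by name and rejects mismatches", {
  d <- separable_matrix(n_per_class = 15, seed = 9)
  fit <- fit_stacking(d$m, d$y, seed = 1)
  perm <- d$m[, c(3, 1, 4, 2)]
  expect_identical(predict_stacking(fit, perm)$score,
                   predict_stacking(fit, d$m)$score)
  bad <- d$m[, 1:3]
  expect_error(predict_stacking(fit, bad), "missing feature column")
  single <- fit_single(d$m, d$y, "random-forest", seed = 1)
  expect_identical(predict_single(single, perm), predict_single(single, d$m))
})

test_that("fitted models never see held-out labels", {
  d <- separable_matrix(n_per_class = 25, seed = 12)
  tr <- c(1:15, 26:40); te <- setdiff(seq_len(50), tr)
  fit <- fit_stacking(d$m[tr, ], d$y[tr], seed = 3)
  before <- predict_stacking(fit, d$m[te, ])$score
  y2 <- d$y; y2[te] <- 1L - y2[te]          # corrupt held-out labels
  fit2 <- fit_stacking(d$m[tr, ], y2[tr], seed = 3)
  expect_identical(predict_stacking(fit2, d$m[te, ])$score, before)
})

test_that("persisted models reload with bit-identical scores", {
  d <- separable_matrix(n_per_class = 15, seed = 4)
  fit <- fit_stacking(d$m, d$y, seed = 7)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(fit, path)
  back <- load_model(path)
  expect_identical(predict_stacking(back, d$m)$score,
                   predict_stacking(fit, d$m)$score)
  junk <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), junk)
  expect_error(load_model(junk), "artifact")
})

test_that("degenerate training inputs are rejected", {
  d <- separable_matrix()
  expect_error(fit_stacking(d$m, rep(1L, nrow(d$m))), "2 rows per class")
  mm <- d$m; mm[1, 1] <- NA
  expect_error(fit_stacking(mm, d$y), "missing values")
  expect_error(fit_single(d$m, d$y, "nonexistent"), "unknown")
  expect_error(fit_stacking(d$m, d$y, base_learners = "nonexistent"), "unknown")
})

test_that("hard-label meta-feature mode fits and predicts", {
  d <- separable_matrix(n_per_class = 15, seed = 5)
  fit <- fit_stacking(d$m, d$y, meta_feature_mode = "hard-label", seed = 2)
  pr <- predict_stacking(fit, d$m)
  expect_equal(pr$label, d$y)
})
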