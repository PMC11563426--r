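# Base-learner wrappers. Each learner kind is backed by the standard R
# implementation (ranger, rpart, e1071, class, xgboost, glm) behind a small
# uniform interface: fit_single() -> "pep_learner", predict_single() ->
# positive-class probabilities. All stochastic learners are seeded from one
# master seed through derive_seed().

LEARNER_KINDS <- c("random-forest", "decision-tree", "support-vector-machine",
                   "k-nearest-neighbors", "gradient-boosting-machine",
                   "extreme-gradient-boosting", "logistic-regression")

#' Default base ensemble
#'
#' The five base-learner kinds enabled by default in the stacking model:
#' random forest, decision tree, RBF support vector machine, k-nearest
#' neighbours and a gradient boosting machine, with logistic regression as
#' the meta-learner.
#' @return Character vector of learner kinds.
#' @export
default_base_learners <- function() {
  c("random-forest", "decision-tree", "support-vector-machine",
    "k-nearest-neighbors", "gradient-boosting-machine")
}

#' Default hyperparameters per learner kind
#'
#' The tuned values used throughout the package: the random forest runs 300
#' trees with depth cap 30 and minimum node size 5; the decision tree splits
#' on information gain (entropy) with `minsplit = 5`; the SVM is an RBF
#' kernel with probability calibration at library defaults; the gradient
#' boosting machine and k-nearest neighbours use documented library
#' defaults; logistic regression is an unpenalised binomial GLM.
#'
#' @param kind One of the learner kinds in `LEARNER_KINDS`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(kind) {
  switch(kind,
    "random-forest" = list(n_estimators = 300L, max_depth = 30L,
                           min_samples_split = 5L),
    "decision-tree" = list(criterion = "entropy", min_samples_split = 5L),
    "support-vector-machine" = list(kernel = "radial", cost = 1),
    "k-nearest-neighbors" = list(k = 5L),
    "gradient-boosting-machine" = list(nrounds = 100L, eta = 0.3,
                                       max_depth = 6L),
    "extreme-gradient-boosting" = list(nrounds = 100L, eta = 0.3,
                                       max_depth = 6L),
    "logistic-regression" = list(),
    stop("unknown learner kind: ", kind))
}

# Deterministic per-component seed from one master seed (kept under 2^31).
derive_seed <- function(master, salt) {
  ((as.integer(master) %% 100003L) * 10007L + as.integer(salt) * 97L) %% 2147483647L
}

check_training_input <- function(m, labels) {
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (anyNA(m)) stop("feature matrix contains missing values")
  if (nrow(m) != length(labels)) stop("row count != label count")
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  if (min(table(factor(labels, levels = 0:1))) < 2L) {
    stop("need at least 2 rows per class")
  }
  labels
}

# Align a prediction matrix to the training feature columns by name.
align_columns <- function(m, feature_names) {
  stopifnot(is.matrix(m))
  if (is.null(colnames(m))) stop("prediction matrix has no column names")
  missing_cols <- setdiff(feature_names, colnames(m))
  extra <- setdiff(colnames(m), feature_names)
  if (length(missing_cols)) {
    stop("missing feature column(s): ", paste(missing_cols, collapse = ", "),
         if (length(extra)) paste0("; unexpected: ", paste(extra, collapse = ", ")))
  }
  m[, feature_names, drop = FALSE]
}

#' Fit a single base learner
#'
#' @param m Numeric feature matrix with column names.
#' @param labels 0/1 vector.
#' @param kind Learner kind (see [default_hyperparameters()]).
#' @param hyperparameters Overrides merged over the kind's defaults.
#' @param seed Integer seed for stochastic learners.
#' @return A fitted `pep_learner`.
#' @export
fit_single <- function(m, labels, kind = "random-forest",
                       hyperparameters = list(), seed = 1L) {
  labels <- check_training_input(m, labels)
  if (!kind %in% LEARNER_KINDS) stop("unknown learner kind: ", kind)
  hp <- utils::modifyList(default_hyperparameters(kind), hyperparameters)
  y <- factor(labels, levels = c(0L, 1L))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fit <- switch(kind,
    "random-forest" = {
      df <- data.frame(.y = y, m, check.names = FALSE)
      ranger::ranger(dependent.variable.name = ".y", data = df,
                     num.trees = hp$n_estimators, max.depth = hp$max_depth,
                     min.node.size = hp$min_samples_split,
                     probability = TRUE, seed = seed, num.threads = 1L)
    },
    "decision-tree" = {
      df <- data.frame(.y = y, m, check.names = FALSE)
      split <- if (identical(hp$criterion, "entropy")) "information" else "gini"
      rpart::rpart(.y ~ ., data = df, method = "class",
                   parms = list(split = split),
                   control = rpart::rpart.control(minsplit = hp$min_samples_split,
                                                  cp = 0.001))
    },
    "support-vector-machine" =
      e1071::svm(x = m, y = y, kernel = hp$kernel, cost = hp$cost,
                 probability = TRUE, scale = FALSE),
    "k-nearest-neighbors" = list(train = m, cl = y, k = hp$k),
    "gradient-boosting-machine" = ,
    "extreme-gradient-boosting" = {
      booster <- xgboost::xgb.train(
        params = list(objective = "binary:logistic", eta = hp$eta,
                      max_depth = hp$max_depth, nthread = 1L, seed = seed),
        data = xgboost::xgb.DMatrix(m, label = labels, nthread = 1L),
        nrounds = hp$nrounds, verbose = 0)
      list(raw = xgboost::xgb.save.raw(booster))
    },
    "logistic-regression" = {
      df <- data.frame(.y = labels, m, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    })
  structure(list(kind = kind, hyperparameters = hp, model = fit,
                 feature_names = colnames(m), seed = seed),
            class = "pep_learner")
}

#' Positive-class probabilities from a fitted base learner
#'
#' Prediction columns are aligned to the training columns by name; missing
#' or extra columns are an error.
#'
#' @param object A `pep_learner` from [fit_single()].
#' @param m Feature matrix to score.
#' @return Numeric vector of positive-class probabilities in \[0, 1\].
#' @export
predict_single <- function(object, m) {
  stopifnot(inherits(object, "pep_learner"))
  m <- align_columns(m, object$feature_names)
  kind <- object$kind
  fit <- object$model
  p <- switch(kind,
    "random-forest" = {
      df <- data.frame(m, check.names = FALSE)
      stats::predict(fit, data = df, num.threads = 1L)$predictions[, "1"]
    },
    "decision-tree" = {
      df <- data.frame(m, check.names = FALSE)
      stats::predict(fit, newdata = df, type = "prob")[, "1"]
    },
    "support-vector-machine" = {
      pr <- stats::predict(fit, m, probability = TRUE)
      attr(pr, "probabilities")[, "1"]
    },
    "k-nearest-neighbors" = {
      pred <- class::knn(train = fit$train, test = m, cl = fit$cl,
                         k = fit$k, prob = TRUE)
      pv <- attr(pred, "prob")
      ifelse(pred == "1", pv, 1 - pv)
    },
    "gradient-boosting-machine" = ,
    "extreme-gradient-boosting" = {
      booster <- xgboost::xgb.load.raw(fit$raw)
      stats::predict(booster, xgboost::xgb.DMatrix(m, nthread = 1L))
    },
    "logistic-regression" = {
      df <- data.frame(m, check.names = FALSE)
      suppressWarnings(stats::predict(fit, newdata = df, type = "response"))
    })
  as.numeric(pmin(pmax(p, 0), 1))
}
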