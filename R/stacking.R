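# Stacking ensemble: base learners' cross-fitted predictions feed a
# logistic-regression meta-learner. Base learners are refit on the full
# training data for deployment; the meta-learner only ever sees out-of-fold
# base predictions, so it is trained without leakage.

#' Fit a stacking ensemble
#'
#' Trains the configured base learners and a logistic-regression
#' meta-learner. The meta-feature matrix has one column per enabled base
#' learner. In `"probability"` mode (default) each column holds the
#' learner's out-of-fold positive-class probability, obtained by
#' `internal_folds`-fold stratified cross-fitting over the training rows;
#' `"hard-label"` mode thresholds those probabilities at 0.5 first. After
#' the meta-learner is fitted, every base learner is refit on the full
#' training data for use at prediction time.
#'
#' @param m Numeric feature matrix with column names.
#' @param labels 0/1 vector (1 = positive class).
#' @param base_learners Character vector of learner kinds (default the
#'   five-learner ensemble of [default_base_learners()]).
#' @param hyperparameters Named list (by kind) of hyperparameter overrides.
#' @param internal_folds Folds for meta-feature cross-fitting (default 5).
#' @param meta_feature_mode `"probability"` or `"hard-label"`.
#' @param seed Master seed; per-learner and per-fold seeds are derived from
#'   it deterministically.
#' @return A fitted `stacking_model`.
#' @export
fit_stacking <- function(m, labels,
                         base_learners = default_base_learners(),
                         hyperparameters = list(),
                         internal_folds = 5L,
                         meta_feature_mode = c("probability", "hard-label"),
                         seed = 1L) {
  meta_feature_mode <- match.arg(meta_feature_mode)
  labels <- check_training_input(m, labels)
  stopifnot(length(base_learners) >= 1L, internal_folds >= 2L)
  unknown <- setdiff(base_learners, LEARNER_KINDS)
  if (length(unknown)) stop("unknown learner kind(s): ", paste(unknown, collapse = ", "))

  folds <- stratified_kfold(labels, k = internal_folds,
                            seed = derive_seed(seed, 1L))
  meta_x <- matrix(NA_real_, nrow(m), length(base_learners),
                   dimnames = list(NULL, base_learners))
  for (f in seq_along(folds)) {
    hold <- folds[[f]]
    for (b in seq_along(base_learners)) {
      kind <- base_learners[b]
      fit <- fit_single(m[-hold, , drop = FALSE], labels[-hold], kind,
                        hyperparameters[[kind]] %||% list(),
                        seed = derive_seed(seed, 100L * b + f))
      meta_x[hold, b] <- predict_single(fit, m[hold, , drop = FALSE])
    }
  }
  if (meta_feature_mode == "hard-label") meta_x <- (meta_x >= 0.5) * 1

  meta_df <- data.frame(.y = labels, meta_x, check.names = FALSE)
  meta <- suppressWarnings(stats::glm(.y ~ ., data = meta_df,
                                      family = stats::binomial()))
  base_fits <- lapply(seq_along(base_learners), function(b) {
    fit_single(m, labels, base_learners[b],
               hyperparameters[[base_learners[b]]] %||% list(),
               seed = derive_seed(seed, 100L * b))
  })
  names(base_fits) <- base_learners
  structure(list(base_learners = base_learners,
                 base_fits = base_fits,
                 meta = meta,
                 meta_feature_mode = meta_feature_mode,
                 internal_folds = internal_folds,
                 feature_names = colnames(m),
                 seed = seed),
            class = "stacking_model")
}

#' Predict with a fitted stacking ensemble
#'
#' Scores are the meta-learner's positive-class probabilities over the base
#' learners' predictions; labels threshold the score at 0.5. Input columns
#' are realigned to the training columns by name.
#'
#' @param object A fitted `stacking_model`.
#' @param m Feature matrix to score.
#' @return List with `score` (probabilities in \[0, 1\]) and `label`
#'   (0/1 integer vector).
#' @export
predict_stacking <- function(object, m) {
  stopifnot(inherits(object, "stacking_model"))
  m <- align_columns(m, object$feature_names)
  meta_x <- vapply(object$base_fits, function(f) predict_single(f, m),
                   numeric(nrow(m)))
  if (nrow(m) == 1L) meta_x <- matrix(meta_x, 1L, dimnames = list(NULL, object$base_learners))
  if (object$meta_feature_mode == "hard-label") meta_x <- (meta_x >= 0.5) * 1
  df <- data.frame(meta_x, check.names = FALSE)
  score <- suppressWarnings(
    as.numeric(stats::predict(object$meta, newdata = df, type = "response")))
  score <- pmin(pmax(score, 0), 1)
  list(score = score, label = as.integer(score >= 0.5))
}

#' @export
print.stacking_model <- function(x, ...) {
  cat("stacking_model:", length(x$base_learners), "base learners (",
      paste(x$base_learners, collapse = ", "),
      ") -> logistic-regression meta-learner\n")
  cat("  meta-features:", x$meta_feature_mode,
      "| internal folds:", x$internal_folds,
      "| training features:", length(x$feature_names), "\n")
  invisible(x)
}

#' Persist / restore a fitted model
#'
#' Saves the full model object (configuration, feature-column names, seeds
#' and fitted state) to a single versioned artifact file; reloading
#' reproduces scores bit-for-bit.
#'
#' @param object A fitted `stacking_model` or `pep_learner`.
#' @param path Artifact file path.
#' @return `path` (for save) or the restored object (for load).
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, c("stacking_model", "pep_learner")))
  saveRDS(list(format_version = 1L,
               package_version = as.character(utils::packageVersion("pepstack")),
               model = object),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!is.list(obj) || is.null(obj$format_version)) {
    stop("not a pepstack model artifact: ", path)
  }
  obj$model
}
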