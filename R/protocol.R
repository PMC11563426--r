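# End-to-end evaluation protocols: encode -> split/fold -> (balance the
# training portion) -> fit -> predict held-out -> metrics.

#' Model configuration helpers
#'
#' `stacking_config()` describes the default five-learner stacking ensemble;
#' `single_config()` a single base learner. Either can be passed as the
#' `model` argument of [run_protocol()] / [evaluate_matrix()].
#'
#' @param base_learners,internal_folds,meta_feature_mode See [fit_stacking()].
#' @param hyperparameters Named list of per-kind hyperparameter overrides.
#' @return A model-config list.
#' @export
stacking_config <- function(base_learners = default_base_learners(),
                            hyperparameters = list(),
                            internal_folds = 5L,
                            meta_feature_mode = "probability") {
  list(type = "stacking", base_learners = base_learners,
       hyperparameters = hyperparameters, internal_folds = internal_folds,
       meta_feature_mode = meta_feature_mode)
}

#' @rdname stacking_config
#' @param kind Learner kind for a single-model baseline.
#' @export
single_config <- function(kind, hyperparameters = list()) {
  list(type = "single", kind = kind, hyperparameters = hyperparameters)
}

#' Balancing configuration
#'
#' @param method `"none"`, `"ADASYN"` or `"SMOTE"`.
#' @param k,target_ratio See [adasyn_oversample()].
#' @param scope `"fold-internal"` (resample inside each training fold only;
#'   the default, so no synthetic point can reach a test fold) or `"global"`
#'   (resample the whole dataset before splitting).
#' @return A balance-config list.
#' @export
balance_config <- function(method = "none", k = 5L, target_ratio = 1.0,
                           scope = c("fold-internal", "global")) {
  scope <- match.arg(scope)
  list(method = method, k = k, target_ratio = target_ratio, scope = scope)
}

fit_model_config <- function(m, labels, model, seed) {
  if (identical(model$type, "stacking")) {
    fit_stacking(m, labels,
                 base_learners = model$base_learners %||% default_base_learners(),
                 hyperparameters = model$hyperparameters %||% list(),
                 internal_folds = model$internal_folds %||% 5L,
                 meta_feature_mode = model$meta_feature_mode %||% "probability",
                 seed = seed)
  } else if (identical(model$type, "single")) {
    fit_single(m, labels, model$kind,
               model$hyperparameters %||% list(), seed = seed)
  } else {
    stop("model config must have type 'stacking' or 'single'")
  }
}

score_model <- function(fit, m) {
  if (inherits(fit, "stacking_model")) predict_stacking(fit, m)$score
  else predict_single(fit, m)
}

#' Evaluate a model configuration on an encoded feature matrix
#'
#' Runs either stratified k-fold cross-validation (`protocol = "cv10"`,
#' `folds` folds) or a stratified train/test split
#' (`protocol = "split80_20"`, fraction `train_fraction`). The balancing
#' step, when enabled with scope `"fold-internal"`, is applied to each
#' training portion only; `"global"` scope resamples the full matrix before
#' any splitting.
#'
#' @param m Numeric feature matrix with column names.
#' @param labels 0/1 vector.
#' @param model Model config from [stacking_config()] or [single_config()].
#' @param balance Balance config from [balance_config()].
#' @param protocol `"cv10"` or `"split80_20"`.
#' @param folds Fold count for the CV protocol (default 10).
#' @param train_fraction Training fraction for the split protocol
#'   (default 0.8).
#' @param seed Master seed; fold assignment, balancing and model fitting all
#'   derive their seeds from it.
#' @return An `eval_report`: per-fold metrics, their unweighted mean
#'   (`aggregate`), pooled-confusion metrics (`pooled`), and the protocol
#'   descriptor.
#' @export
evaluate_matrix <- function(m, labels,
                            model = stacking_config(),
                            balance = balance_config(),
                            protocol = c("cv10", "split80_20"),
                            folds = 10L, train_fraction = 0.8, seed = 1L) {
  protocol <- match.arg(protocol)
  labels <- as.integer(labels)
  stopifnot(nrow(m) == length(labels))

  if (!identical(balance$method, "none") && identical(balance$scope, "global")) {
    rs <- balance_dataset(m, labels, balance$method, balance$k,
                          balance$target_ratio, seed = derive_seed(seed, 7L))
    m <- rs$matrix; labels <- rs$labels
  }

  splits <- if (protocol == "cv10") {
    held <- stratified_kfold(labels, k = folds, seed = derive_seed(seed, 2L))
    lapply(held, function(h) list(train = setdiff(seq_along(labels), h), test = h))
  } else {
    list(train_test_split(labels, train_fraction, seed = derive_seed(seed, 2L)))
  }

  fold_rows <- vector("list", length(splits))
  pooled <- list(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (f in seq_along(splits)) {
    tr <- splits[[f]]$train; te <- splits[[f]]$test
    m_tr <- m[tr, , drop = FALSE]; y_tr <- labels[tr]
    if (!identical(balance$method, "none") &&
        identical(balance$scope, "fold-internal")) {
      rs <- balance_dataset(m_tr, y_tr, balance$method, balance$k,
                            balance$target_ratio,
                            seed = derive_seed(seed, 7L + f))
      m_tr <- rs$matrix; y_tr <- rs$labels
    }
    fit <- fit_model_config(m_tr, y_tr, model, seed = derive_seed(seed, 1000L + f))
    score <- score_model(fit, m[te, , drop = FALSE])
    pred <- as.integer(score >= 0.5)
    cc <- confusion(labels[te], pred)
    met <- metrics_from_confusion(cc)
    auc <- if (length(unique(labels[te])) == 2L) roc_auc(labels[te], score) else NA_real_
    for (nm in names(pooled)) pooled[[nm]] <- pooled[[nm]] + cc[[nm]]
    fold_rows[[f]] <- data.frame(fold = f, TP = cc$TP, FP = cc$FP,
                                 TN = cc$TN, FN = cc$FN,
                                 accuracy = met$accuracy, mcc = met$mcc,
                                 auc = auc, sensitivity = met$sensitivity,
                                 specificity = met$specificity)
  }
  fold_df <- do.call(rbind, fold_rows)
  metric_cols <- c("accuracy", "mcc", "auc", "sensitivity", "specificity")
  aggregate <- as.list(colMeans(fold_df[metric_cols], na.rm = TRUE))
  pooled_met <- metrics_from_confusion(pooled)
  pooled_out <- c(pooled,
                  list(accuracy = pooled_met$accuracy, mcc = pooled_met$mcc,
                       sensitivity = pooled_met$sensitivity,
                       specificity = pooled_met$specificity))
  structure(list(protocol = list(name = protocol,
                                 folds = if (protocol == "cv10") folds else NULL,
                                 train_fraction = if (protocol == "split80_20")
                                   train_fraction else NULL,
                                 seed = seed,
                                 balance = balance,
                                 model = model[setdiff(names(model),
                                                       "hyperparameters")]),
                 folds = fold_df,
                 aggregate = aggregate,
                 pooled = pooled_out),
            class = "eval_report")
}

#' Run the full pipeline on a peptide dataset
#'
#' Convenience wrapper: encodes the dataset with the given encoders, then
#' calls [evaluate_matrix()].
#'
#' @param d A labelled [peptide_dataset].
#' @param encoders Encoder specification for [encode_dataset()]
#'   (default `c("AAC", "DPC")`, the combined feature set).
#' @inheritParams evaluate_matrix
#' @return An `eval_report`.
#' @export
run_protocol <- function(d, encoders = c("AAC", "DPC"),
                         model = stacking_config(),
                         balance = balance_config(),
                         protocol = "cv10",
                         folds = 10L, train_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(d, "peptide_dataset"), "label" %in% names(d))
  m <- encode_dataset(d, encoders)
  evaluate_matrix(m, d$label, model = model, balance = balance,
                  protocol = protocol, folds = folds,
                  train_fraction = train_fraction, seed = seed)
}

#' @export
print.eval_report <- function(x, ...) {
  p <- x$protocol
  cat(sprintf("eval_report: %s (%s)\n", p$name,
              if (p$name == "cv10") paste0(p$folds, " folds")
              else paste0(p$train_fraction * 100, "/",
                          (1 - p$train_fraction) * 100, " split")))
  cat(sprintf("  model: %s | balance: %s (%s) | seed: %d\n",
              if (identical(p$model$type, "stacking")) "stacking" else p$model$kind,
              p$balance$method, p$balance$scope, p$seed))
  a <- x$aggregate
  cat(sprintf("  ACC %.4f | MCC %.4f | AUC %.4f | Sn %.4f | Sp %.4f\n",
              a$accuracy, a$mcc, a$auc, a$sensitivity, a$specificity))
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' The report round-trips: `read_eval_report()` restores the protocol
#' descriptor, per-fold table and aggregates.
#'
#' @param report An `eval_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}

#' @rdname write_eval_report
#' @export
read_eval_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(obj, class = "eval_report")
}
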