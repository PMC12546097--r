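#' Leave-one-subject-out splits
#'
#' One split per unique subject: all of that subject's trials form the test
#' fold, everyone else's form the training fold.
#'
#' @param subject_ids Character vector (one entry per row; duplicates denote
#'   multiple trials of the same subject).
#' @return List of `list(train, test)` subject-id sets, one per subject.
#' @export
loso_splits <- function(subject_ids) {
  subjects <- unique(subject_ids)
  if (length(subjects) < 2)
    stop("leave-one-subject-out needs at least 2 distinct subjects")
  lapply(subjects, function(s)
    list(train = setdiff(subjects, s), test = s))
}

#' Cross-validated mean absolute error under LOSO
#'
#' For each held-out subject: standardize features subject-wise with the
#' requested method, fit the model on the remaining subjects' trials, predict
#' the held-out trials and record the MAE in transformed (log(1+rating))
#' units. Subject-wise standardization only ever uses a subject's own rows,
#' so computing it once up front is identical to recomputing it inside every
#' fold and cannot leak information across the split.
#'
#' @param model_spec `list(type = "lsboost", hp = lsboost_hp(...))`,
#'   `list(type = "mean")` or `list(type = "lasso")` (lasso uses the
#'   dimension-based penalty of [lasso_lambda()] per fold).
#' @param table A [feature_table()].
#' @param attribute Target attribute (column of `table$y`).
#' @param standardizer Standardization method, see [standardize_features()].
#' @param seed Integer seed recorded into per-fold fits.
#' @return A `cv_result`: `fold_mae` (named by held-out subject), `mean`,
#'   `sd`, `objective` (= mean) and metadata.
#' @export
cv_mae <- function(model_spec, table, attribute,
                   standardizer = "none", seed = 1) {
  stopifnot(inherits(table, "feature_table"))
  if (!attribute %in% colnames(table$y))
    stop(sprintf("unknown target attribute '%s'", attribute))
  std <- standardize_features(table, standardizer)
  splits <- loso_splits(std$meta$subject_id)
  fold_mae <- vapply(splits, function(sp) {
    train <- subset_subjects(std, sp$train)
    test <- subset_subjects(std, sp$test)
    y_tr <- train$y[, attribute]
    if (model_spec$type == "lsboost" && nrow(train$X) < model_spec$hp$leaf_min)
      stop(sprintf("fold holding out %s has %d training rows, fewer than leaf_min = %d",
                   sp$test, nrow(train$X), model_spec$hp$leaf_min))
    model <- switch(model_spec$type,
      lsboost = fit_lsboost(train$X, y_tr, model_spec$hp,
                            seed = derive_seed(seed, "fold", sp$test)),
      mean = fit_mean(y_tr),
      lasso = fit_lasso(train$X, y_tr,
                        lasso_lambda(nrow(train$X), ncol(train$X))),
      stop(sprintf("unknown model type '%s'", model_spec$type)))
    mean(abs(stats::predict(model, test$X) - test$y[, attribute]))
  }, numeric(1))
  names(fold_mae) <- vapply(splits, function(sp) sp$test, character(1))
  structure(list(fold_mae = fold_mae, mean = mean(fold_mae),
                 sd = stats::sd(fold_mae), objective = mean(fold_mae),
                 model_type = model_spec$type, attribute = attribute,
                 standardizer = standardizer, tag = table$tag),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s on %s/%s (%s): MAE %.3f +/- %.3f over %d folds\n",
              x$model_type, x$tag, x$attribute, x$standardizer,
              x$mean, x$sd, length(x$fold_mae)))
  invisible(x)
}
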