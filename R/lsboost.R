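#' LSBoost hyperparameters
#'
#' Validates the search bounds of the boosted-tree regressor: number of
#' learners `n` in \[1, 500\], learning rate `rho` in \[0.01, 1\], minimum
#' leaf size `leaf_min` and maximum number of splits per tree `max_splits`
#' both in \[1, 100\].
#'
#' @param n Number of boosting iterations (trees).
#' @param rho Shrinkage / learning rate.
#' @param leaf_min Minimum observations per leaf.
#' @param max_splits Maximum internal (split) nodes per tree, grown
#'   best-first by impurity reduction.
#' @return A validated `lsboost_hp` list.
#' @export
lsboost_hp <- function(n, rho, leaf_min, max_splits) {
  n <- as.integer(round(n)); leaf_min <- as.integer(round(leaf_min))
  max_splits <- as.integer(round(max_splits))
  if (n < 1 || n > 500) stop("hyperparameter out of bounds: n must be in [1, 500]")
  if (rho < 0.01 || rho > 1) stop("hyperparameter out of bounds: rho must be in [0.01, 1]")
  if (leaf_min < 1 || leaf_min > 100)
    stop("hyperparameter out of bounds: leaf_min must be in [1, 100]")
  if (max_splits < 1 || max_splits > 100)
    stop("hyperparameter out of bounds: max_splits must be in [1, 100]")
  structure(list(n = n, rho = rho, leaf_min = leaf_min, max_splits = max_splits),
            class = "lsboost_hp")
}

#' Fit a least-squares boosted-tree regressor
#'
#' Stagewise boosting for squared loss: the initial prediction is `mean(y)`;
#' each of the `n` iterations fits an exact greedy regression tree (best-first
#' growth, at most `max_splits` internal nodes, at least `leaf_min` rows per
#' leaf, squared-error impurity, ties broken toward the lowest feature index
#' then lowest threshold) to the current residuals and adds it with shrinkage
#' `rho`. The procedure is fully deterministic; `seed` is recorded for
#' provenance only.
#'
#' @param X Numeric feature matrix (rows = trials).
#' @param y Numeric targets.
#' @param hp An [lsboost_hp()].
#' @param seed Optional integer recorded in the model metadata.
#' @return An `lsboost` model: `f0`, `rho`, `trees`, per-iteration training
#'   MSE (`train_mse`), raw impurity importances and metadata.
#' @export
fit_lsboost <- function(X, y, hp, seed = NULL) {
  stopifnot(inherits(hp, "lsboost_hp"))
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (anyNA(X) || anyNA(y)) stop("non-finite or missing values in training data")
  if (nrow(X) < 2) stop("fit_lsboost needs at least 2 rows")
  # leaf_min larger than half the rows admits no split: the ensemble
  # degenerates to the training-mean predictor (leaf-only trees)
  fit <- lsboost_fit_cpp(X, as.numeric(y), hp$n, hp$rho, hp$leaf_min, hp$max_splits)
  structure(list(f0 = fit$f0, rho = fit$rho, trees = fit$trees,
                 importance_raw = as.numeric(fit$importance_raw),
                 train_mse = as.numeric(fit$train_mse),
                 hp = hp, feature_names = colnames(X), p = ncol(X),
                 seed = seed),
            class = "lsboost")
}

#' @export
print.lsboost <- function(x, ...) {
  cat(sprintf("<lsboost> %d trees, rho=%.3g, leaf_min=%d, max_splits=%d, p=%d\n",
              x$hp$n, x$rho, x$hp$leaf_min, x$hp$max_splits, x$p))
  invisible(x)
}

#' Predict from a fitted LSBoost model
#' @param object An `lsboost` model.
#' @param newdata Feature matrix with the training feature count.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.lsboost <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("newdata has %d features; model was trained with %d",
                 ncol(newdata), object$p))
  as.numeric(lsboost_predict_cpp(object[c("f0", "rho", "trees")], newdata))
}

#' Impurity-based feature importance
#'
#' Per-feature sum of squared-error impurity reductions over every split node
#' of every tree in the ensemble, normalized to total 1. A model that never
#' split (degenerate ensemble) returns all zeros with a warning.
#'
#' @param model A fitted `lsboost`.
#' @return Named nonnegative numeric vector summing to 1 (or all zeros).
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "lsboost"))
  imp <- model$importance_raw
  names(imp) <- model$feature_names
  tot <- sum(imp)
  if (tot <= 0) {
    warning("model contains no splits; returning zero importances")
    return(imp)
  }
  imp / tot
}

#' Serialize an LSBoost model to JSON
#'
#' Trees are written as nested split/leaf records for audit.
#' @param model A fitted `lsboost`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_lsboost_json <- function(model, path) {
  obj <- list(f0 = model$f0, rho = model$rho,
              hp = unclass(model$hp),
              trees = lapply(model$trees, function(t)
                list(feature = t$feature, threshold = t$threshold,
                     left = t$left, right = t$right, value = t$value)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
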