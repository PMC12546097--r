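#' Constant-mean benchmark regressor
#'
#' Predicts the training set's mean target everywhere.
#' @param y Training targets (length >= 1).
#' @return A `mean_model`.
#' @export
fit_mean <- function(y) {
  if (length(y) < 1) stop("fit_mean needs at least one target value")
  structure(list(mean = mean(y)), class = "mean_model")
}

#' @export
predict.mean_model <- function(object, newdata, ...) {
  n <- if (is.matrix(newdata) || is.data.frame(newdata)) nrow(newdata) else length(newdata)
  rep(object$mean, n)
}

#' Dimension-based lasso penalty
#'
#' `lambda = 2 * log(p) / n` (natural log), the universal-threshold style
#' penalty tied to the training-set dimensions; for a leave-one-subject-out
#' fold of the tasting study (n = 56 rows, p = 306 features) this gives
#' about 0.2044.
#'
#' @param n Training rows (>= 1).
#' @param p Features (>= 2).
#' @return The penalty value.
#' @export
lasso_lambda <- function(n, p) {
  if (n < 1) stop("n must be >= 1")
  if (p < 2) stop("p must be >= 2")
  2 * log(p) / n
}

#' Lasso benchmark regressor
#'
#' L1-penalized least squares with an unpenalized intercept, objective
#' `(1/(2n)) * RSS + lambda * sum(|beta|)` (glmnet's gaussian scaling, which
#' is the convention that makes the dimension-based lambda of
#' [lasso_lambda()] meaningful). Features are used as supplied (no internal
#' re-standardization).
#'
#' @param X Feature matrix.
#' @param y Targets.
#' @param lambda Penalty (>= 0).
#' @return A `lasso_model` wrapping the glmnet fit.
#' @export
fit_lasso <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("fit_lasso needs at least 2 rows")
  if (anyNA(X) || any(!is.finite(X))) stop("non-finite values in features")
  padded <- ncol(X) == 1               # glmnet requires >= 2 columns; a
  if (padded) X <- cbind(X, 0)         # zero column never gets a coefficient
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = lambda,
                        standardize = FALSE, intercept = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  structure(list(fit = fit, lambda = lambda, p = ncol(X) - padded,
                 padded = padded),
            class = "lasso_model")
}

#' @export
predict.lasso_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop(sprintf("newdata has %d features; model was trained with %d",
                 ncol(newdata), object$p))
  if (object$padded) newdata <- cbind(newdata, 0)
  as.numeric(glmnet::predict.glmnet(object$fit, newdata, s = object$lambda))
}

#' @export
coef.lasso_model <- function(object, ...) {
  cf <- as.numeric(glmnet::coef.glmnet(object$fit, s = object$lambda))
  if (object$padded) cf <- cf[-length(cf)]
  cf
}
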