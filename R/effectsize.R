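#' Cohen's d between benchmark and model fold MAEs
#'
#' Two-sample pooled-SD standardized mean difference
#' \deqn{d = (m_{bench} - m_{model}) / \sqrt{(s_{bench}^2 + s_{model}^2)/2},}
#' positive when the model beats the benchmark. The 95% confidence interval
#' is obtained from the noncentral t distribution with
#' `df = 2 * n_folds - 2` and noncentrality `d * sqrt(n_folds / 2)`
#' (equal-n two-sample construction), inverting the CDF in the
#' noncentrality parameter. A d is flagged significant when the CI
#' excludes 0.
#'
#' @param mae_bench,mae_model Fold MAE vectors, or `list(mean=, sd=)`
#'   summaries (then `n_folds` is required).
#' @param n_folds Number of folds per sample (inferred from vectors).
#' @return An `effect_size`: `d`, `ci95`, `significant`, `n_folds`.
#' @export
#' @examples
#' cohens_d(list(mean = 0.604, sd = 0.165),
#'          list(mean = 0.459, sd = 0.178), n_folds = 15)$d  # ~0.845
cohens_d <- function(mae_bench, mae_model, n_folds = NULL) {
  summarize_arg <- function(x) {
    if (is.list(x)) {
      if (inherits(x, "cv_result")) list(m = x$mean, s = x$sd, n = length(x$fold_mae))
      else list(m = x$mean, s = x$sd, n = n_folds)
    } else list(m = mean(x), s = stats::sd(x), n = length(x))
  }
  b <- summarize_arg(mae_bench)
  m <- summarize_arg(mae_model)
  if (is.null(b$n) || is.null(m$n))
    stop("n_folds is required when passing mean/sd summaries")
  if (b$n != m$n) stop("both samples must have the same number of folds")
  n <- b$n
  pooled <- sqrt((b$s^2 + m$s^2) / 2)
  if (pooled == 0) {
    if (b$m == m$m)
      return(structure(list(d = 0, ci95 = c(0, 0), significant = FALSE,
                            n_folds = n), class = "effect_size"))
    stop("zero pooled SD with unequal means: d undefined")
  }
  d <- (b$m - m$m) / pooled
  scale <- sqrt(n / 2)                 # ncp = d * sqrt(n1*n2/(n1+n2)), n1=n2=n
  t_obs <- d * scale
  df <- 2 * n - 2
  ncp_bound <- function(prob) {
    # pt()'s nonconvergence warning for extreme ncp is ~1e-8 absolute,
    # far below the tolerance that matters here
    f <- function(ncp) suppressWarnings(stats::pt(t_obs, df, ncp = ncp)) - prob
    lo <- t_obs - 10 - 10 * abs(t_obs)
    hi <- t_obs + 10 + 10 * abs(t_obs)
    stats::uniroot(f, c(lo, hi), extendInt = "downX", tol = 1e-9)$root
  }
  ci <- c(ncp_bound(0.975), ncp_bound(0.025)) / scale
  structure(list(d = d, ci95 = ci,
                 significant = ci[1] > 0 || ci[2] < 0, n_folds = n),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.3f, 95%% CI [%.3f, %.3f]%s\n",
              x$d, x$ci95[1], x$ci95[2],
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Map a log-scale MAE back toward the rating scale
#'
#' Targets are log(1+rating); `exp(mae) - 1` expresses a log-scale MAE as an
#' equivalent rating-scale error.
#'
#' @param mae_log_scale Nonnegative MAE in transformed units.
#' @return Rating-scale MAE.
#' @export
antilog_mae <- function(mae_log_scale) {
  if (any(mae_log_scale < 0)) stop("MAE must be nonnegative")
  expm1(mae_log_scale)
}
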