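#' Aggregate per-model performance summaries
#'
#' Given one row per significant (dataset, target) model with its
#' cross-validated MAE mean/SD and the two benchmark effect sizes, computes
#' the overall statistics: mean +/- SD of the per-model MAE means, the same
#' for their rating-scale (anti-logged) equivalents, and mean +/- SD of the
#' d scores against the mean and lasso benchmarks.
#'
#' @param per_model data.frame with columns `dataset`, `target`, `mae_mean`,
#'   `mae_sd`, `d_me`, `d_lr`.
#' @return List of `overall_mae`, `overall_mae_antilog`, `d_me`, `d_lr`
#'   (each `c(mean, sd)`), plus `n_models` and the input table with an added
#'   `mae_antilog` column.
#' @export
summarize_performance <- function(per_model) {
  need <- c("dataset", "target", "mae_mean", "mae_sd", "d_me", "d_lr")
  if (!all(need %in% colnames(per_model)))
    stop(sprintf("per_model must have columns: %s", paste(need, collapse = ", ")))
  per_model$mae_antilog <- antilog_mae(per_model$mae_mean)
  ms <- function(v) c(mean = mean(v), sd = stats::sd(v))
  list(per_model = per_model,
       n_models = nrow(per_model),
       overall_mae = ms(per_model$mae_mean),
       overall_mae_antilog = ms(per_model$mae_antilog),
       d_me = ms(per_model$d_me),
       d_lr = ms(per_model$d_lr))
}

#' Filter to significant models and report aggregate performance
#'
#' A (dataset, target) model counts as significant when both its effect
#' sizes against the mean and the lasso benchmark are positive with 95% CIs
#' excluding zero. Returns the aggregate report of
#' [summarize_performance()] over the significant models, or an empty report
#' with `no_significant_models = TRUE` if none qualify.
#'
#' @param results List of per-combination entries, each a list with
#'   `dataset`, `target`, `lsboost` (a `cv_result`), `d_me` and `d_lr`
#'   (`effect_size` objects).
#' @return The [summarize_performance()] report plus a
#'   `no_significant_models` flag.
#' @export
summarize_models <- function(results) {
  keep <- vapply(results, function(r)
    r$d_me$significant && r$d_lr$significant && r$d_me$d > 0 && r$d_lr$d > 0,
    logical(1))
  if (!any(keep)) {
    return(list(per_model = NULL, n_models = 0L, no_significant_models = TRUE,
                overall_mae = c(mean = NA_real_, sd = NA_real_),
                overall_mae_antilog = c(mean = NA_real_, sd = NA_real_),
                d_me = c(mean = NA_real_, sd = NA_real_),
                d_lr = c(mean = NA_real_, sd = NA_real_)))
  }
  per_model <- do.call(rbind, lapply(results[keep], function(r)
    data.frame(dataset = r$dataset, target = r$target,
               mae_mean = r$lsboost$mean, mae_sd = r$lsboost$sd,
               d_me = r$d_me$d, d_lr = r$d_lr$d, stringsAsFactors = FALSE)))
  rep <- summarize_performance(per_model)
  rep$no_significant_models <- FALSE
  rep
}

#' Aggregate feature importances into class scores and a topography
#'
#' For each model, the normalized per-feature importances are collapsed into
#' feature classes by summing across the 38 channels within each of the five
#' normalized band powers (p_delta..p_gamma) and the three Hjorth parameters
#' (A, M, C); Age and Group pass through unchanged, so the ten class scores
#' of each model still sum to 1. The topography sums each channel's eight
#' EEG features and averages across models, yielding one score per channel
#' with its 2-D layout position.
#'
#' @param models List of entries `list(dataset=, target=, importance=)`
#'   where `importance` is a named, normalized 306-long vector.
#' @param montage Channel layout (default [default_montage()]).
#' @return List with `class_table` (one row per model, ten class columns)
#'   and `topography` (data.frame channel, x, y, score).
#' @export
aggregate_importance <- function(models, montage = default_montage()) {
  classes <- c("age", "group",
               paste0("p_", band_names()),
               paste0("hjorth_", c("A", "M", "C")))
  rows <- list()
  topo <- matrix(0, nrow(montage), length(models),
                 dimnames = list(montage$channel, NULL))
  for (k in seq_along(models)) {
    imp <- models[[k]]$importance
    if (abs(sum(imp) - 1) > 1e-6)
      stop("importance vector is not normalized to sum 1")
    nm <- names(imp)
    score <- vapply(classes, function(cl) {
      if (cl %in% c("age", "group")) sum(imp[nm == cl])
      else sum(imp[endsWith(nm, paste0(".", cl))])
    }, numeric(1))
    rows[[k]] <- data.frame(dataset = models[[k]]$dataset,
                            target = models[[k]]$target,
                            t(score), check.names = FALSE,
                            stringsAsFactors = FALSE)
    ch_of <- sub("\\..*$", "", nm)
    eeg <- nm != "age" & nm != "group"
    agg <- tapply(imp[eeg], ch_of[eeg], sum)
    topo[names(agg), k] <- agg
  }
  topography <- data.frame(channel = montage$channel,
                           x = montage$x, y = montage$y,
                           score = rowMeans(topo),
                           stringsAsFactors = FALSE)
  list(class_table = do.call(rbind, rows), topography = topography)
}
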