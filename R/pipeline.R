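#' Configuration of a full pipeline run
#'
#' @param panel A [panel_config()] describing the virtual panel (its `seed`
#'   is the data seed).
#' @param max_evaluations Optimization budget per (dataset, target)
#'   combination (default 100).
#' @param seed Master seed for the optimization stage; per-combination seeds
#'   are derived deterministically from it and the (dataset, target) key.
#' @param datasets Dataset tags to analyze.
#' @param out_dir Optional output directory; when set, all result files are
#'   written there.
#' @param progress Emit per-stage log messages.
#' @return A `run_config`.
#' @export
run_config <- function(panel = panel_config(), max_evaluations = 100,
                       seed = 1, datasets = c("Be", "Co", "BeCo"),
                       out_dir = NULL, progress = FALSE) {
  if (is.null(seed) || !is.finite(seed))
    stop("a master seed is mandatory")
  structure(list(panel = panel, max_evaluations = as.integer(max_evaluations),
                 seed = as.integer(seed), datasets = datasets,
                 out_dir = out_dir, progress = progress),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' simulate -> extract -> build -> optimize -> evaluate -> report:
#' simulates the virtual tasting panel, builds the per-phase feature tables,
#' runs the Bayesian hyperparameter/standardizer search under LOSO for every
#' (dataset, target) combination, scores the mean and lasso benchmarks on
#' the same folds (benchmarks use the optimized standardizer so all three
#' models see identical inputs), computes Cohen's d with noncentral-t CIs,
#' filters and summarizes the significant models, refits them on the
#' complete datasets and aggregates feature importances into class scores
#' and a channel topography. Identical configuration and seeds yield a
#' byte-identical results bundle.
#'
#' @param rc A [run_config()].
#' @return A `results_bundle`: `combos` (per dataset/target: best
#'   hyperparameters, cv results, effect sizes, trial log), `summary`,
#'   `importance`, `iaf_estimates`, `demographics`, `ratings`, `config`.
#'   Written to `rc$out_dir` by [write_bundle()] when configured.
#' @export
run_pipeline <- function(rc) {
  stopifnot(inherits(rc, "run_config"))
  stage <- function(...) if (rc$progress) log_stage(...)

  stage("stage 1-3: simulate panel, extract features, build datasets")
  data <- tryCatch(build_panel_datasets(rc$panel, progress = rc$progress),
                   error = function(e)
                     stop(sprintf("pipeline stage 'build' failed: %s",
                                  conditionMessage(e)), call. = FALSE))

  attributes <- rc$panel$attributes
  combos <- list()
  for (tag in rc$datasets) {
    table <- data$tables[[tag]]
    for (attr in attributes) {
      stage("stage 4: optimizing %s/%s", tag, attr)
      combo_seed <- derive_seed(rc$seed, "cash", tag, attr)
      space <- search_space(max_evaluations = rc$max_evaluations,
                            seed = combo_seed)
      opt <- tryCatch(bayes_optimize(table, attr, space),
                      error = function(e)
                        stop(sprintf("pipeline stage 'optimize' failed at %s/%s: %s",
                                     tag, attr, conditionMessage(e)), call. = FALSE))
      std <- opt$best$standardizer
      ls_cv <- opt$best$cv
      me_cv <- cv_mae(list(type = "mean"), table, attr, std, seed = combo_seed)
      lr_cv <- cv_mae(list(type = "lasso"), table, attr, std, seed = combo_seed)
      combos[[paste(tag, attr, sep = "/")]] <- list(
        dataset = tag, target = attr, seed = combo_seed,
        best = opt$best, log = opt$log,
        lsboost = ls_cv, me = me_cv, lr = lr_cv,
        d_me = cohens_d(me_cv, ls_cv),
        d_lr = cohens_d(lr_cv, ls_cv))
    }
  }

  stage("stage 5: summarize significant models")
  summary <- summarize_models(combos)

  stage("stage 6: refit significant models and aggregate importance")
  importance <- NULL
  if (!summary$no_significant_models) {
    sig <- lapply(seq_len(nrow(summary$per_model)), function(i) {
      row <- summary$per_model[i, ]
      combo <- combos[[paste(row$dataset, row$target, sep = "/")]]
      table <- standardize_features(data$tables[[row$dataset]],
                                    combo$best$standardizer)
      model <- fit_lsboost(table$X, table$y[, row$target], combo$best$hp,
                           seed = combo$seed)
      list(dataset = row$dataset, target = row$target,
           importance = feature_importance(model))
    })
    importance <- aggregate_importance(sig)
  }

  bundle <- structure(list(
    combos = combos, summary = summary, importance = importance,
    iaf_estimates = data$iaf_estimates,
    demographics = data$demographics, ratings = data$ratings,
    config = list(panel_seed = rc$panel$seed, master_seed = rc$seed,
                  n_subjects = rc$panel$n_subjects,
                  max_evaluations = rc$max_evaluations,
                  datasets = rc$datasets)),
    class = "results_bundle")
  if (!is.null(rc$out_dir)) write_bundle(bundle, rc$out_dir)
  bundle
}

#' Serialize a results bundle
#'
#' Writes `results.json` (per-combination best hyperparameters, fold MAEs,
#' d scores with CIs, aggregate summary, resolved configuration and seeds),
#' `importance_classes.csv`, `topography.csv`, `ratings.csv` and
#' `demographics.csv`. The JSON contains no timestamps, so repeated runs of
#' the same configuration are byte-identical.
#'
#' @param bundle A `results_bundle`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  json <- bundle_json(bundle)
  p <- file.path(out_dir, "results.json")
  writeLines(json, p); paths <- c(paths, p)
  if (!is.null(bundle$importance)) {
    p <- file.path(out_dir, "importance_classes.csv")
    utils::write.csv(bundle$importance$class_table, p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "topography.csv")
    utils::write.csv(bundle$importance$topography, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(out_dir, "ratings.csv")
  utils::write.csv(bundle$ratings, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(out_dir, "demographics.csv")
  utils::write.csv(bundle$demographics, p, row.names = FALSE); paths <- c(paths, p)
  invisible(paths)
}

#' JSON serialization of a results bundle (deterministic)
#' @param bundle A `results_bundle`.
#' @return A JSON string.
#' @export
bundle_json <- function(bundle) {
  combo_obj <- function(cb) list(
    dataset = cb$dataset, target = cb$target, seed = cb$seed,
    best = list(n = cb$best$hp$n, rho = cb$best$hp$rho,
                leaf_min = cb$best$hp$leaf_min,
                max_splits = cb$best$hp$max_splits,
                standardizer = cb$best$standardizer,
                objective = cb$best$objective),
    fold_mae = list(lsboost = as.list(cb$lsboost$fold_mae),
                    me = as.list(cb$me$fold_mae),
                    lr = as.list(cb$lr$fold_mae)),
    d_me = list(d = cb$d_me$d, ci95 = cb$d_me$ci95,
                significant = cb$d_me$significant),
    d_lr = list(d = cb$d_lr$d, ci95 = cb$d_lr$ci95,
                significant = cb$d_lr$significant))
  obj <- list(config = bundle$config,
              combos = lapply(bundle$combos, combo_obj),
              summary = bundle$summary[c("n_models", "overall_mae",
                                         "overall_mae_antilog", "d_me", "d_lr")])
  if (!is.null(bundle$summary$per_model))
    obj$summary$per_model <- bundle$summary$per_model
  jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 10, pretty = TRUE,
                   dataframe = "rows")
}
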