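#!/usr/bin/env Rscript
# Stage 5: aggregate report over the significant models.
#
# Reads the optimization bundle written by 04_optimize_models.R and reports
# the per-model and overall statistics: cross-validated MAE (log scale and
# anti-logged back toward the 0-10 rating scale) and the d scores against
# the mean and lasso benchmarks, plus the channel-importance topography.

suppressMessages(library(flavorboost))

res <- jsonlite::read_json("results/pipeline/results.json",
                           simplifyVector = TRUE)
pm <- res$summary$per_model
if (is.null(pm) || res$summary$n_models == 0) {
  cat("no significant models in this run (see results/pipeline/results.json)\n")
} else {
  rep <- summarize_performance(pm)
  write.csv(rep$per_model, "results/significant_models.csv", row.names = FALSE)
  cat(sprintf("%d significant model(s):\n", rep$n_models))
  for (i in seq_len(nrow(rep$per_model)))
    cat(sprintf("  %-4s %-10s MAE %.3f +/- %.3f (anti-log %.3f) d_Me %.3f d_LR %.3f\n",
                rep$per_model$dataset[i], rep$per_model$target[i],
                rep$per_model$mae_mean[i], rep$per_model$mae_sd[i],
                rep$per_model$mae_antilog[i],
                rep$per_model$d_me[i], rep$per_model$d_lr[i]))
  cat(sprintf("overall MAE %.3f +/- %.3f (anti-log %.3f +/- %.3f)\n",
              rep$overall_mae["mean"], rep$overall_mae["sd"],
              rep$overall_mae_antilog["mean"], rep$overall_mae_antilog["sd"]))
  cat(sprintf("d_Me %.3f +/- %.3f, d_LR %.3f +/- %.3f\n",
              rep$d_me["mean"], rep$d_me["sd"],
              rep$d_lr["mean"], rep$d_lr["sd"]))
  topo <- read.csv("results/pipeline/topography.csv")
  top <- topo[order(-topo$score), ][1:5, ]
  cat("top importance channels:",
      paste(sprintf("%s (%.3f)", top$channel, top$score), collapse = ", "), "\n")
  cat("wrote results/significant_models.csv\n")
}
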