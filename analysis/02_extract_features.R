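#!/usr/bin/env Rscript
# Stage 2: spectral/temporal feature extraction.
#
# Per subject: estimate the individual alpha frequency (IAF) from the
# baseline, anchor the five frequency bands to it, compute Welch normalized
# band powers (38 channels x 5 bands) and Hjorth parameters (38 x 3) for
# every tasting and rinse epoch, and normalize tasting features against the
# same trial's rinse features. The full 120 x 304 record matrix is
# regenerated deterministically on demand; this script persists the IAF
# table and per-feature summary statistics.

suppressMessages(library(flavorboost))

SEED <- 42
cfg <- panel_config(n_subjects = 15, seed = SEED)
data <- build_panel_datasets(cfg, progress = TRUE)

dir.create("results", showWarnings = FALSE)
write.csv(data$iaf_estimates, "results/iaf_estimates.csv", row.names = FALSE)

feat <- as.matrix(data$records[, setdiff(colnames(data$records),
                                         c("subject_id", "phase", "trial"))])
summary_df <- data.frame(feature = colnames(feat),
                         mean = colMeans(feat),
                         sd = apply(feat, 2, sd),
                         min = apply(feat, 2, min),
                         max = apply(feat, 2, max))
write.csv(summary_df, "results/feature_summary.csv", row.names = FALSE)

err <- abs(data$iaf_estimates$true_iaf - data$iaf_estimates$estimated_iaf)
cat(sprintf("extracted %d trial records x %d rinse-normalized EEG features\n",
            nrow(feat), ncol(feat)))
cat(sprintf("IAF recovery: max |error| %.3f Hz (median %.3f Hz)\n",
            max(err), median(err)))
cat("wrote results/iaf_estimates.csv, results/feature_summary.csv\n")
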