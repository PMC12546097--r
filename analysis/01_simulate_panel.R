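#!/usr/bin/env Rscript
# Stage 1: simulate the virtual expert tasting panel.
#
# 15 panelists, each with an age, expertise group (T/E), an individual alpha
# peak in 8.5-11.5 Hz and latent attribute intensities per (phase, trial,
# attribute); one 60 s eyes-closed baseline plus 2 phases x 4 tasting trials
# of 10 s water-rinse and 10 s tasting EEG, and noisy 0-10 ratings of the
# four attributes. Everything is reproducible from the single seed below.

suppressMessages(library(flavorboost))

SEED <- 42
cfg <- panel_config(n_subjects = 15, seed = SEED)
panel <- generate_panel(cfg)
demo <- panel_demographics(panel)

dir.create("results", showWarnings = FALSE)
write.csv(demo, "results/demographics.csv", row.names = FALSE)

# ratings require the session simulation; collect them without keeping epochs
ratings <- do.call(rbind, lapply(panel, function(s) {
  do.call(rbind, lapply(cfg$phases, function(ph) {
    do.call(rbind, lapply(seq_len(cfg$n_trials), function(tr) {
      r <- generate_ratings(s, ph, tr,
                            seed = derive_seed(cfg$seed, s$subject_id,
                                               "ratings", ph, tr),
                            noise_sd = cfg$rating_noise_sd)
      data.frame(subject_id = s$subject_id, phase = ph, trial = tr,
                 attribute = names(r), rating = unname(r))
    }))
  }))
}))
write.csv(ratings, "results/ratings.csv", row.names = FALSE)

cat(sprintf("panel: %d subjects (%d trained, %d expert), ages %d-%d\n",
            nrow(demo), sum(demo$group == "T"), sum(demo$group == "E"),
            min(demo$age), max(demo$age)))
cat(sprintf("alpha peaks: %.2f-%.2f Hz\n",
            min(sapply(panel, `[[`, "true_iaf")),
            max(sapply(panel, `[[`, "true_iaf"))))
cat(sprintf("ratings: %d rows, range %.2f-%.2f on the 0-10 scale\n",
            nrow(ratings), min(ratings$rating), max(ratings$rating)))
cat("wrote results/demographics.csv, results/ratings.csv\n")
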