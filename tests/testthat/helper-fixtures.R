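# Shared fixtures: tiny panels keep unit tests fast; study-scale panels are
# built only where a property genuinely needs them.

tiny_config <- function(n_subjects = 3, seed = 101, ...) {
  panel_config(n_subjects = n_subjects, seed = seed,
               baseline_duration = 15, tl_duration = 5, wr_duration = 5, ...)
}

# sinusoidal test epoch
sine_epoch <- function(freq = 10, fs = 512, dur = 10, amp = 1,
                       channels = "Cz", task = "BSL") {
  t <- (seq_len(fs * dur) - 1) / fs
  x <- amp * sin(2 * pi * freq * t)
  epoch(matrix(rep(x, length(channels)), nrow = length(channels), byrow = TRUE),
        fs, channels, task)
}

# hand-built feature table: n_subjects x n_trials rows, p features
toy_table <- function(n_subjects = 3, n_trials = 2, p = 4, seed = 1,
                      y_fun = function(meta, X) rnorm(nrow(X)), tag = "Be") {
  withr::with_seed(seed, {
    meta <- data.frame(
      subject_id = rep(sprintf("S%02d", seq_len(n_subjects)), each = n_trials),
      phase = tag, trial = rep(seq_len(n_trials), n_subjects),
      stringsAsFactors = FALSE)
    X <- matrix(rnorm(nrow(meta) * p), nrow(meta), p,
                dimnames = list(NULL, paste0("f", seq_len(p))))
    y <- matrix(y_fun(meta, X), ncol = 1, dimnames = list(NULL, "acid"))
    feature_table(meta, X, y, tag)
  })
}
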