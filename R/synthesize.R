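#' Synthesize one EEG epoch of a virtual subject
#'
#' The generative model emulates cleaned, band-limited (0.1-40 Hz) scalp EEG:
#' every channel carries broadband noise whose one-sided power spectrum is
#' `noise_amp^2 * (1/f + noise_floor)` (realized by shaping complex Gaussian
#' spectra and inverse FFT), and occipital channels additionally carry an
#' alpha oscillation at the subject's true alpha frequency whose amplitude is
#' slowly (0.3 Hz) modulated. In tasting (TL) epochs, the background spectrum
#' inside each effect-map (region, band) is multiplied by
#' `1 + gain * latent_intensity` for that trial's attribute intensity, so
#' band-power features are coupled to the ratings by construction; rinse (WR)
#' and baseline epochs share the identical law without the multiplier, which
#' is what the tasting-vs-rinse feature normalization later exploits.
#' Bands used for the multiplier are the subject's own IAF-anchored bands.
#'
#' @param subject A `virtual_subject` from [generate_panel()].
#' @param task `"BSL"`, `"WR"` or `"TL"`.
#' @param config The [panel_config()].
#' @param seed Integer seed (mandatory: no hidden global randomness).
#' @param phase,trial Required for `"TL"` (selects the latent intensities).
#' @return An [epoch()].
#' @export
synthesize_epoch <- function(subject, task = c("BSL", "WR", "TL"), config,
                             seed, phase = NULL, trial = NULL) {
  task <- match.arg(task)
  if (missing(seed)) stop("synthesize_epoch requires an explicit seed")
  if (task == "TL" && (is.null(phase) || is.null(trial)))
    stop("TL epochs need phase and trial to resolve the latent intensities")
  dur <- switch(task, BSL = config$baseline_duration,
                WR = config$wr_duration, TL = config$tl_duration)
  fs <- config$fs
  n <- round(dur * fs)
  freqs <- seq(0, fs / 2, by = fs / n)            # half-spectrum grid
  nh <- length(freqs)
  shape <- base_spectrum(freqs, config)           # shared by all channels
  bands <- define_bands(subject$true_iaf)

  # per-channel spectral gain: 1 everywhere; TL multiplies effect regions
  gain <- matrix(1, nrow = config$n_channels, ncol = nh,
                 dimnames = list(config$channel_names, NULL))
  if (task == "TL") {
    for (attr in names(config$effect_map)) {
      e <- config$effect_map[[attr]]
      chans <- if (length(e$region) == 1 && e$region %in% default_montage()$region)
        intersect(region_channels(e$region), config$channel_names)
      else intersect(e$region, config$channel_names)
      iv <- bands$intervals[[e$band]]
      sel <- freqs >= iv[1] & freqs < iv[2]
      intensity <- subject$latent[phase, trial, attr]
      gain[chans, sel] <- gain[chans, sel, drop = FALSE] * (1 + e$gain * intensity)
    }
  }

  t_axis <- (seq_len(n) - 1) / fs
  occ <- intersect(occipital_channels(), config$channel_names)
  data <- with_seed(seed, {
    out <- matrix(0, config$n_channels, n,
                  dimnames = list(config$channel_names, NULL))
    for (ch in seq_len(config$n_channels)) {
      out[ch, ] <- shaped_noise(n, fs, shape * gain[ch, ])
      if (config$channel_names[ch] %in% occ && config$alpha_amp > 0) {
        phi <- stats::runif(2, 0, 2 * pi)
        am <- 1 + config$alpha_modulation * sin(2 * pi * 0.3 * t_axis + phi[2])
        out[ch, ] <- out[ch, ] +
          config$alpha_amp * am * sin(2 * pi * subject$true_iaf * t_axis + phi[1])
      }
    }
    out
  })
  epoch(data, fs = fs, channel_names = config$channel_names, task = task)
}

# one-sided background PSD (uV^2/Hz) on the half-spectrum grid; band-limited
# to the 0.1-40 Hz analysis range, emulating post-filter data
base_spectrum <- function(freqs, config) {
  s <- config$noise_amp^2 * (1 / pmax(freqs, 0.5) + config$noise_floor)
  s[freqs < 0.1 | freqs > 40] <- 0
  s
}

# real time series of length n whose one-sided PSD matches `shape`
shaped_noise <- function(n, fs, shape) {
  nh <- length(shape)                              # n %/% 2 + 1 bins
  amp <- sqrt(shape * fs * n / 2)
  z <- stats::rnorm(nh) + 1i * stats::rnorm(nh)
  half <- amp * z / sqrt(2)
  half[1] <- 0                                     # zero-mean
  if (n %% 2 == 0) half[nh] <- amp[nh] * stats::rnorm(1)
  full <- c(half, Conj(rev(half[2:(nh - 1L + (n %% 2 != 0))])))
  full <- full[seq_len(n)]
  Re(stats::fft(full, inverse = TRUE)) / n
}

#' Simulate the full recording session of one subject
#'
#' One 60 s baseline plus, for each phase (Be, Co) and trial (1..4), a
#' water-rinse and a tasting epoch and the post-trial attribute ratings.
#' All randomness is derived deterministically from `config$seed`, the
#' subject id and the (task, phase, trial) key.
#'
#' @param subject A `virtual_subject`.
#' @param config The [panel_config()].
#' @return A `session_recording`: list with `subject_id`, `baseline`,
#'   `trials` (nested list `[[phase]][[trial]]` of `wr`/`tl` epochs) and
#'   `ratings` (data.frame subject_id, phase, trial, attribute, rating).
#' @export
simulate_session <- function(subject, config) {
  sid <- subject$subject_id
  baseline <- synthesize_epoch(subject, "BSL", config,
                               seed = derive_seed(config$seed, sid, "BSL"))
  trials <- list()
  ratings <- list()
  for (phase in config$phases) {
    trials[[phase]] <- vector("list", config$n_trials)
    for (tr in seq_len(config$n_trials)) {
      wr <- synthesize_epoch(subject, "WR", config,
                             seed = derive_seed(config$seed, sid, "WR", phase, tr))
      tl <- synthesize_epoch(subject, "TL", config,
                             seed = derive_seed(config$seed, sid, "TL", phase, tr),
                             phase = phase, trial = tr)
      r <- generate_ratings(subject, phase, tr,
                            seed = derive_seed(config$seed, sid, "ratings", phase, tr),
                            noise_sd = config$rating_noise_sd)
      trials[[phase]][[tr]] <- list(wr = wr, tl = tl)
      ratings[[length(ratings) + 1]] <- data.frame(
        subject_id = sid, phase = phase, trial = tr,
        attribute = names(r), rating = unname(r), stringsAsFactors = FALSE)
    }
  }
  structure(list(subject_id = sid, baseline = baseline, trials = trials,
                 ratings = do.call(rbind, ratings)),
            class = "session_recording")
}

#' Demographics table of a panel
#' @param panel List of `virtual_subject`s.
#' @return data.frame with subject_id, age, group.
#' @export
panel_demographics <- function(panel) {
  do.call(rbind, lapply(panel, function(s)
    data.frame(subject_id = s$subject_id, age = s$age, group = s$group,
               stringsAsFactors = FALSE)))
}
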