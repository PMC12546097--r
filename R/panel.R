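#' Configuration of a virtual expert tasting panel
#'
#' Bundles every constant of the simulated study: cohort size, montage,
#' protocol durations (60 s eyes-closed baseline; 10 s water-rinse and
#' tasting-liquid epochs per trial; 2 phases of 4 trials), the alpha-peak
#' range, the per-attribute effect map coupling latent intensities to
#' band-power modulations, and the rating noise.
#'
#' The effect map assigns each attribute a scalp region, a frequency band and
#' a multiplicative gain per intensity unit: in tasting epochs the background
#' power in that (region, band) is multiplied by `1 + gain * intensity`,
#' which is what makes the ratings decodable from the EEG by construction.
#'
#' @param n_subjects Number of panelists (>= 2; default 15).
#' @param seed Master seed for the panel (mandatory determinism anchor).
#' @param fs Sampling rate in Hz (default 512).
#' @param channel_names Channel labels (default: the 38-channel 10-10 montage).
#' @param baseline_duration,tl_duration,wr_duration Epoch lengths in seconds
#'   (defaults 60, 10, 10).
#' @param iaf_range Interval the true alpha peaks are drawn from, inside
#'   (7.5, 12.5) Hz; default c(8.5, 11.5).
#' @param effect_map Named list (one entry per attribute) of
#'   `list(region=, band=, gain=)`; region is a region name from
#'   [default_montage()] or a character vector of channels.
#' @param rating_noise_sd SD of the Gaussian rating noise, rating units
#'   (default 1).
#' @param age_range Ages drawn uniformly from this range (default c(24, 59)).
#' @param group_proportions Probability of group T vs E, summing to 1
#'   (default c(T = 0.5, E = 0.5)).
#' @param latent_range Latent attribute intensities drawn uniformly from this
#'   interval (default c(1, 9), keeping clipping rare).
#' @param noise_amp Amplitude scale of the 1/f background (uV; default 1).
#' @param noise_floor White-noise floor relative to the 1/f component
#'   (default 0.01).
#' @param alpha_amp Occipital alpha amplitude (uV; default 3).
#' @param alpha_modulation Depth of the slow (0.3 Hz) alpha amplitude
#'   modulation (default 0.2; 0 gives a pure sinusoid).
#' @return A validated `panel_config` list.
#' @export
panel_config <- function(n_subjects = 15,
                         seed = 1,
                         fs = 512,
                         channel_names = default_montage()$channel,
                         baseline_duration = 60,
                         tl_duration = 10,
                         wr_duration = 10,
                         iaf_range = c(8.5, 11.5),
                         effect_map = default_effect_map(),
                         rating_noise_sd = 1,
                         age_range = c(24, 59),
                         group_proportions = c(T = 0.5, E = 0.5),
                         latent_range = c(1, 9),
                         noise_amp = 1,
                         noise_floor = 0.01,
                         alpha_amp = 3,
                         alpha_modulation = 0.2) {
  cfg <- list(n_subjects = n_subjects, seed = seed, fs = fs,
              n_channels = length(channel_names),
              channel_names = as.character(channel_names),
              baseline_duration = baseline_duration,
              tl_duration = tl_duration, wr_duration = wr_duration,
              iaf_range = iaf_range, effect_map = effect_map,
              rating_noise_sd = rating_noise_sd, age_range = age_range,
              group_proportions = group_proportions,
              latent_range = latent_range,
              noise_amp = noise_amp, noise_floor = noise_floor,
              alpha_amp = alpha_amp, alpha_modulation = alpha_modulation,
              phases = c("Be", "Co"), n_trials = 4L,
              attributes = c("bitter", "sweet", "acid", "astringent"))
  validate_panel_config(cfg)
  structure(cfg, class = "panel_config")
}

#' Default attribute -> (region, band, gain) effect map
#'
#' Each tasted attribute modulates one scalp region in one band, with a 10%
#' power increase per intensity unit. The assignments follow the regions the
#' tasting literature implicates (frontal/central/parietal involvement).
#' @return Named list of effect entries.
#' @export
default_effect_map <- function() {
  list(
    bitter     = list(region = "frontal",  band = "theta", gain = 0.1),
    sweet      = list(region = "central",  band = "alpha", gain = 0.1),
    acid       = list(region = "parietal", band = "beta",  gain = 0.1),
    astringent = list(region = "temporal", band = "gamma", gain = 0.1)
  )
}

validate_panel_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || cfg$n_subjects < 2)
    config_error("n_subjects", "must be >= 2")
  if (is.null(cfg$seed) || !is.numeric(cfg$seed) || !is.finite(cfg$seed))
    config_error("seed", "an integer master seed is mandatory")
  if (cfg$fs <= 2 * 40)
    config_error("fs", "must exceed twice the 40 Hz band limit")
  if (length(cfg$iaf_range) != 2 || cfg$iaf_range[1] > cfg$iaf_range[2] ||
      cfg$iaf_range[1] <= 7.5 || cfg$iaf_range[2] >= 12.5)
    config_error("iaf_range", "must be an interval inside (7.5, 12.5) Hz")
  if (anyDuplicated(cfg$channel_names))
    config_error("channel_names", "must be unique")
  if (length(cfg$channel_names) != cfg$n_channels)
    config_error("channel_names", "length must equal n_channels")
  if (cfg$rating_noise_sd < 0)
    config_error("rating_noise_sd", "must be nonnegative")
  if (length(cfg$group_proportions) != 2 ||
      abs(sum(cfg$group_proportions) - 1) > 1e-9)
    config_error("group_proportions", "must be two proportions summing to 1")
  if (cfg$latent_range[1] < 0 || cfg$latent_range[2] > 10 ||
      cfg$latent_range[1] > cfg$latent_range[2])
    config_error("latent_range", "must be an interval inside [0, 10]")
  for (a in names(cfg$effect_map)) {
    e <- cfg$effect_map[[a]]
    if (!all(c("region", "band", "gain") %in% names(e)))
      config_error("effect_map", sprintf("entry '%s' needs region, band, gain", a))
    if (!e$band %in% band_names())
      config_error("effect_map", sprintf("unknown band '%s' in entry '%s'", e$band, a))
    if (e$gain < 0)
      config_error("effect_map", sprintf("negative gain in entry '%s'", a))
  }
  invisible(cfg)
}

#' Serialize a panel configuration to JSON
#'
#' Writes every field of the configuration (including the resolved effect
#' map and seed) for audit; the file round-trips through
#' [read_panel_config()].
#'
#' @param config A [panel_config()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_panel_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_panel_config
#' @export
read_panel_config <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- structure(obj, class = "panel_config")
  cfg$effect_map <- lapply(obj$effect_map, as.list)
  validate_panel_config(cfg)
  cfg
}

#' Generate the virtual subjects of a panel
#'
#' Draws, deterministically under `config$seed`, each panelist's age (uniform
#' over `age_range`), expertise group (T/E with the configured proportions),
#' true alpha peak frequency (uniform over `iaf_range`) and latent attribute
#' intensities for every (phase, trial, attribute) cell (uniform over
#' `latent_range`).
#'
#' @param config A [panel_config()].
#' @return List of `virtual_subject` objects with fields `subject_id`, `age`,
#'   `group`, `true_iaf` and `latent` (phases x trials x attributes array).
#' @export
generate_panel <- function(config) {
  validate_panel_config(config)
  with_seed(derive_seed(config$seed, "panel"), {
    lapply(seq_len(config$n_subjects), function(i) {
      latent <- array(
        stats::runif(length(config$phases) * config$n_trials * length(config$attributes),
                     config$latent_range[1], config$latent_range[2]),
        dim = c(length(config$phases), config$n_trials, length(config$attributes)),
        dimnames = list(config$phases, NULL, config$attributes))
      structure(list(
        subject_id = sprintf("S%02d", i),
        age = round(stats::runif(1, config$age_range[1], config$age_range[2])),
        group = sample(c("T", "E"), 1, prob = config$group_proportions),
        true_iaf = stats::runif(1, config$iaf_range[1], config$iaf_range[2]),
        latent = latent
      ), class = "virtual_subject")
    })
  })
}

#' Simulate the sensory ratings of one tasting trial
#'
#' rating = clip(latent intensity + Gaussian(0, rating_noise_sd), 0, 10),
#' one value per attribute.
#'
#' @param subject A `virtual_subject`.
#' @param phase `"Be"` or `"Co"`.
#' @param trial Trial index 1..4.
#' @param seed Integer seed for the rating noise (mandatory: there is no
#'   hidden global randomness).
#' @param noise_sd Rating noise SD.
#' @return Named numeric vector, one 0-10 rating per attribute.
#' @export
generate_ratings <- function(subject, phase, trial, seed, noise_sd = 1) {
  if (missing(seed)) stop("generate_ratings requires an explicit seed")
  latent <- subject$latent[phase, trial, ]
  with_seed(seed, {
    pmin(pmax(latent + stats::rnorm(length(latent), 0, noise_sd), 0), 10)
  })
}
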