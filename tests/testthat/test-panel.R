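test_that("panel configuration errors name the offending field", {
  expect_error(panel_config(n_subjects = 1), "n_subjects")
  expect_error(panel_config(fs = 60), "fs")
  expect_error(panel_config(iaf_range = c(7, 11)), "iaf_range")
  expect_error(panel_config(channel_names = c("O1", "O1", "O2")), "channel_names")
  expect_error(panel_config(group_proportions = c(0.2, 0.2)), "group_proportions")
  expect_error(panel_config(effect_map = list(bitter = list(region = "frontal",
                                                            band = "sigma",
                                                            gain = 0.1))),
               "effect_map")
})

test_that("generate_panel draws the configured cohort deterministically", {
  cfg <- tiny_config(n_subjects = 15, seed = 1)
  panel <- generate_panel(cfg)
  expect_length(panel, 15)
  expect_true(all(vapply(panel, function(s) s$group %in% c("T", "E"), logical(1))))
  expect_true(all(vapply(panel, function(s)
    s$true_iaf >= 8.5 && s$true_iaf <= 11.5, logical(1))))
  expect_true(all(vapply(panel, function(s)
    all(s$latent >= 0 & s$latent <= 10), logical(1))))
  expect_true(all(vapply(panel, function(s)
    identical(dim(s$latent), c(2L, 4L, 4L)), logical(1))))
  # determinism: same config, same seed
  expect_identical(panel, generate_panel(cfg))
  # different seed differs
  expect_false(identical(panel, generate_panel(tiny_config(n_subjects = 15, seed = 2))))
})

test_that("a degenerate alpha-range interval pins every subject's alpha peak", {
  cfg <- tiny_config(iaf_range = c(10, 10))
  panel <- generate_panel(cfg)
  expect_equal(vapply(panel, `[[`, numeric(1), "true_iaf"), rep(10, 3))
})

test_that("panel configurations round-trip through JSON", {
  cfg <- tiny_config(n_subjects = 5, seed = 3)
  path <- file.path(withr::local_tempdir(), "config.json")
  write_panel_config(cfg, path)
  back <- read_panel_config(path)
  expect_equal(back$n_subjects, cfg$n_subjects)
  expect_equal(back$channel_names, cfg$channel_names)
  expect_equal(back$effect_map, cfg$effect_map)
  # the round-tripped config drives an identical panel
  expect_identical(generate_panel(back), generate_panel(cfg))
})

test_that("ratings are latent intensities plus clipped Gaussian noise", {
  cfg <- tiny_config()
  s <- generate_panel(cfg)[[1]]
  # zero noise reproduces the latent intensity exactly
  r0 <- generate_ratings(s, "Be", 1, seed = 5, noise_sd = 0)
  expect_equal(unname(r0), unname(s$latent["Be", 1, ]))
  # clipping at the scale ceiling
  s$latent["Be", 1, ] <- 10
  r_hi <- generate_ratings(s, "Be", 1, seed = 5, noise_sd = 100)
  expect_true(all(r_hi >= 0 & r_hi <= 10))
  # determinism under a fixed seed; no hidden global randomness
  s2 <- generate_panel(cfg)[[1]]
  expect_identical(generate_ratings(s2, "Co", 2, seed = 9, noise_sd = 1),
                   generate_ratings(s2, "Co", 2, seed = 9, noise_sd = 1))
  expect_error(generate_ratings(s2, "Co", 2), "seed")
})
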