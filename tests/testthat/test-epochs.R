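test_that("epoch constructor enforces its invariants", {
  expect_error(epoch(matrix(c(1, NA), 1), 2, "Cz", "BSL"), "NA")
  expect_error(epoch(matrix(rnorm(512), 1), 512, c("Cz", "Pz"), "BSL"),
               "channel_names")
  expect_error(epoch(matrix(rnorm(100), 1), 512, "Cz", "BSL"), "1 s")
  e <- epoch(matrix(rnorm(1024), 2), 512, c("Cz", "Pz"), "TL")
  expect_equal(epoch_duration(e), 1)
})

test_that("epoch synthesis is deterministic and refuses to run unseeded", {
  cfg <- tiny_config()
  s <- generate_panel(cfg)[[1]]
  e1 <- synthesize_epoch(s, "WR", cfg, seed = 77)
  e2 <- synthesize_epoch(s, "WR", cfg, seed = 77)
  expect_identical(e1$data, e2$data)
  expect_false(identical(e1$data,
                         synthesize_epoch(s, "WR", cfg, seed = 78)$data))
  expect_error(synthesize_epoch(s, "WR", cfg), "seed")
  expect_error(synthesize_epoch(s, "TL", cfg, seed = 1), "phase")
})

test_that("with background noise silenced the occipital signal is a pure alpha tone", {
  cfg <- tiny_config(noise_amp = 0, alpha_amp = 1, alpha_modulation = 0,
                     iaf_range = c(10, 10))
  s <- generate_panel(cfg)[[1]]
  e <- synthesize_epoch(s, "BSL", cfg, seed = 3)
  x <- e$data["Oz", ]
  t_axis <- (seq_along(x) - 1) / cfg$fs
  # fit amplitude & phase of a 10 Hz sinusoid; residual must vanish
  fit <- lm(x ~ sin(2 * pi * 10 * t_axis) + cos(2 * pi * 10 * t_axis) - 1)
  expect_lt(max(abs(resid(fit))), 1e-8)
  expect_equal(sqrt(sum(coef(fit)^2)), 1, tolerance = 1e-6)
  # non-occipital channels are silent in this degenerate configuration
  expect_equal(max(abs(e$data["Cz", ])), 0)
})

test_that("tasting epochs with zero gain follow the same law as rinse epochs", {
  em <- default_effect_map()
  for (a in names(em)) em[[a]]$gain <- 0
  cfg <- tiny_config(effect_map = em)
  s <- generate_panel(cfg)[[1]]
  tl <- synthesize_epoch(s, "TL", cfg, seed = 55, phase = "Be", trial = 1)
  wr <- synthesize_epoch(s, "WR", cfg, seed = 55)
  # identical seeds and identical generative law => identical samples
  expect_equal(tl$data, wr$data)
})

test_that("epochs round-trip through the binary + sidecar format", {
  cfg <- tiny_config()
  s <- generate_panel(cfg)[[1]]
  e <- synthesize_epoch(s, "WR", cfg, seed = 12)
  stem <- file.path(withr::local_tempdir(), "S01_WR_Be_1")
  write_epoch(e, stem)
  back <- read_epoch(stem)
  expect_identical(back$channel_names, e$channel_names)
  expect_identical(back$fs, e$fs)
  expect_identical(back$task, e$task)
  # float32 quantization bound
  expect_lt(max(abs(back$data - e$data)), 1e-4 * max(abs(e$data)))
})

test_that("corrupt or incomplete epoch files raise explicit errors", {
  cfg <- tiny_config()
  s <- generate_panel(cfg)[[1]]
  e <- synthesize_epoch(s, "WR", cfg, seed = 12)
  dir <- withr::local_tempdir()
  stem <- file.path(dir, "epochfile")
  write_epoch(e, stem)
  # truncated payload
  full <- readBin(paste0(stem, ".f32"), "raw", n = 1e9)
  writeBin(full[seq_len(length(full) - 64)], paste0(stem, ".f32"))
  expect_error(read_epoch(stem), "truncated")
  # missing sidecar
  file.remove(paste0(stem, ".json"))
  expect_error(read_epoch(stem), "sidecar")
})
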