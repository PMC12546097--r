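test_that("IAF estimation matches analytic spectra", {
  # pure 10 Hz occipital tone: center of gravity within one 1 Hz bin
  e <- sine_epoch(10, dur = 10, channels = c("O1", "Oz", "O2"))
  expect_lte(abs(estimate_iaf(e) - 10), 1)
  # two tones symmetric about 10 Hz inside the alpha window
  t_axis <- (0:5119) / 512
  x <- sin(2 * pi * 8.5 * t_axis) + sin(2 * pi * 11.5 * t_axis)
  e2 <- epoch(matrix(rep(x, 3), 3, byrow = TRUE), 512,
              c("O1", "Oz", "O2"), "BSL")
  expect_equal(estimate_iaf(e2), 10, tolerance = 0.05)
  # missing occipital channels / all-zero band are errors
  expect_error(estimate_iaf(sine_epoch(10, channels = "Cz")), "occipital")
  silent <- epoch(matrix(0, 3, 5120), 512, c("O1", "Oz", "O2"), "BSL")
  expect_error(estimate_iaf(silent), "center of gravity")
})

test_that("IAF-anchored bands partition [0, IAF+25] exactly", {
  b <- define_bands(10)
  expect_equal(b$intervals$delta, c(0, 4))
  expect_equal(b$intervals$theta, c(4, 8))
  expect_equal(b$intervals$alpha, c(8, 12))
  expect_equal(b$intervals$beta, c(12, 26))
  expect_equal(b$intervals$gamma, c(26, 35))
  expect_equal(define_bands(8.5)$intervals$alpha, c(6.5, 10.5))
  expect_error(define_bands(6), "delta")
  # partition property for arbitrary IAFs: consecutive edges shared exactly
  for (iaf in c(7.3, 8.5, 9.97, 11.2, 12.49)) {
    iv <- define_bands(iaf)$intervals
    for (k in seq_len(length(iv) - 1))
      expect_identical(iv[[k]][2], iv[[k + 1]][1])
    expect_identical(iv$delta[1], 0)
    expect_equal(iv$gamma[2], iaf + 25)
  }
})

test_that("normalized band powers reproduce flat-spectrum ratios exactly", {
  # flat density on [0, 40] Hz (grid ends at 40 => fs/2 = 40)
  psd <- psd_estimate(0:40, rep(1, 41), "Cz")
  bp <- band_powers(psd, define_bands(10))
  expect_equal(unname(bp["Cz", "alpha"]), 4 / 40)
  expect_equal(unname(sum(bp["Cz", ])), 35 / 40)
  # density entirely inside alpha
  dens <- ifelse(0:40 >= 8 & 0:40 <= 12, 1, 0)
  dens[c(9, 13)] <- 0   # keep the trapezoid mass strictly inside [8,12]
  bp2 <- band_powers(psd_estimate(0:40, dens, "Cz"), define_bands(10))
  expect_equal(unname(bp2["Cz", "alpha"]), 1)
  expect_equal(unname(sum(bp2["Cz", c("delta", "theta", "beta", "gamma")])), 0)
  # zero total power is an error
  expect_error(band_powers(psd_estimate(0:40, rep(0, 41)), define_bands(10)),
               "zero total power")
})

test_that("band powers stay in [0,1], sum to at most 1, and truncate at Nyquist", {
  withr::with_seed(11, {
    for (rep in 1:5) {
      e <- epoch(matrix(rnorm(2 * 2048), 2), 512, c("Cz", "Pz"), "TL")
      bp <- band_powers(welch_psd(e), define_bands(runif(1, 7.5, 12.5)))
      expect_true(all(bp >= 0 & bp <= 1))
      expect_true(all(rowSums(bp) <= 1 + 1e-9))
    }
  })
  # gamma upper edge above fs/2: truncated with a warning
  e <- sine_epoch(10, fs = 64, dur = 4)
  expect_warning(band_powers(welch_psd(e), define_bands(10)), "truncated")
})

test_that("Hjorth parameters match sinusoid closed forms", {
  e <- sine_epoch(freq = 10, fs = 512, dur = 10, amp = 2)
  h <- hjorth(e)
  expect_equal(unname(h[1, "A"]), 2^2 / 2, tolerance = 0.02)
  expect_equal(unname(h[1, "M"]), 2 * pi * 10, tolerance = 0.02)
  expect_equal(unname(h[1, "C"]), 1, tolerance = 0.02)
})

test_that("Hjorth mobility and complexity are scale-invariant, activity quadratic", {
  e <- withr::with_seed(8, epoch(matrix(rnorm(2048), 1), 512, "Cz", "TL"))
  h1 <- hjorth(e)
  e2 <- epoch(e$data * 3.7, e$fs, e$channel_names, e$task)
  h2 <- hjorth(e2)
  expect_equal(unname(h2[1, "A"]), unname(h1[1, "A"]) * 3.7^2)
  expect_equal(unname(h2[1, "M"]), unname(h1[1, "M"]))
  expect_equal(unname(h2[1, "C"]), unname(h1[1, "C"]))
  # white noise is broader than any sinusoid: complexity exceeds 1
  expect_gt(unname(h1[1, "C"]), 1)
  # constant signal is an error
  expect_error(hjorth(epoch(matrix(1, 1, 512), 512, "Cz", "TL")), "constant")
})

test_that("per-epoch feature vectors are channel-major with documented names", {
  cfg <- tiny_config()
  s <- generate_panel(cfg)[[1]]
  e <- synthesize_epoch(s, "WR", cfg, seed = 2)
  fx <- extract_epoch_features(e, define_bands(10))
  expect_length(fx, 38 * 8)
  expect_identical(names(fx)[1:5],
                   paste0(cfg$channel_names[1], ".p_",
                          c("delta", "theta", "alpha", "beta", "gamma")))
  expect_identical(names(fx)[38 * 5 + 1:3],
                   paste0(cfg$channel_names[1], ".hjorth_", c("A", "M", "C")))
})

test_that("IAF recovery on synthetic baselines is within half a hertz", {
  cfg <- tiny_config(n_subjects = 4, seed = 33)
  panel <- generate_panel(cfg)
  for (s in panel) {
    bsl <- synthesize_epoch(s, "BSL", cfg,
                            seed = derive_seed(cfg$seed, s$subject_id, "BSL"))
    expect_lt(abs(estimate_iaf(bsl) - s$true_iaf), 0.5)
  }
})
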