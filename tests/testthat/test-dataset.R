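test_that("rinse normalization is elementwise relative change with a zero guard", {
  expect_equal(wr_normalize(c(2, 3, 4), c(1, 2, 4)), c(1.0, 0.5, 0.0))
  y <- c(0.5, 1.2, 3)
  expect_equal(wr_normalize(y, y), c(0, 0, 0))
  expect_error(wr_normalize(c(1, 2, 3), c(1, 0, 3)), "indices")
  expect_error(wr_normalize(1:3, 1:2), "equal length")
})

test_that("rating transform is log(1+y) with an exact inverse", {
  expect_equal(transform_targets(0), 0)
  expect_equal(transform_targets(10), log(11))
  expect_equal(transform_targets(10), 2.3979, tolerance = 1e-4)
  y <- 0:10
  expect_equal(invert_targets(transform_targets(y)), y)
  expect_error(transform_targets(-1), "nonnegative")
})

test_that("assembled datasets have the design's shapes and ordering", {
  cfg <- tiny_config(n_subjects = 3, seed = 9)
  d <- build_panel_datasets(cfg)
  expect_equal(dim(d$tables$Be$X), c(3 * 4, 306))
  expect_equal(dim(d$tables$Co$X), c(3 * 4, 306))
  expect_equal(dim(d$tables$BeCo$X), c(2 * 3 * 4, 306))
  # column layout: 190 spectral, 114 temporal, then age and group
  cn <- colnames(d$tables$Be$X)
  expect_equal(sum(grepl("\\.p_", cn)), 190)
  expect_equal(sum(grepl("\\.hjorth_", cn)), 114)
  expect_identical(cn[305:306], c("age", "group"))
  expect_true(all(d$tables$Be$X[, "group"] %in% c(0, 1)))
  # BeCo is the vertical concatenation of Be then Co
  expect_equal(d$tables$BeCo$X[1:12, ], d$tables$Be$X, ignore_attr = TRUE)
  expect_equal(d$tables$BeCo$X[13:24, ], d$tables$Co$X, ignore_attr = TRUE)
  # targets are transformed ratings
  expect_true(all(d$tables$Be$y >= 0 & d$tables$Be$y <= log(11)))
})

test_that("a missing trial is reported by subject, phase and trial", {
  cfg <- tiny_config(n_subjects = 3, seed = 9)
  d <- build_panel_datasets(cfg)
  rec <- d$records[!(d$records$subject_id == "S02" & d$records$phase == "Be" &
                       d$records$trial == 3), ]
  expect_error(assemble_dataset(rec, d$ratings, d$demographics, "Be"),
               "S02.*Be.*3")
})

test_that("feature tables round-trip through CSV plus manifest", {
  tb <- toy_table(n_subjects = 3, n_trials = 2, p = 4, seed = 71)
  stem <- file.path(withr::local_tempdir(), "be_table")
  write_feature_table(tb, stem)
  back <- read_feature_table(stem)
  expect_equal(back$meta, tb$meta)
  expect_equal(back$X, tb$X)
  expect_equal(back$y, tb$y)
  expect_identical(back$tag, tb$tag)
})

test_that("subject-wise standardizers hit their definitions", {
  tb <- toy_table(n_subjects = 3, n_trials = 4, p = 5)
  # none: identity
  expect_identical(standardize_features(tb, "none"), tb)
  # z-score: per subject, per feature mean 0 / sd 1
  z <- standardize_features(tb, "zscore")
  for (sid in unique(z$meta$subject_id)) {
    sub <- z$X[z$meta$subject_id == sid, , drop = FALSE]
    expect_equal(unname(colMeans(sub)), rep(0, 5), tolerance = 1e-12)
    expect_equal(unname(apply(sub, 2, sd)), rep(1, 5), tolerance = 1e-12)
  }
  # min-max: per subject, per feature range [0, 1]
  mm <- standardize_features(tb, "minmax")
  for (sid in unique(mm$meta$subject_id)) {
    sub <- mm$X[mm$meta$subject_id == sid, , drop = FALSE]
    expect_equal(unname(apply(sub, 2, min)), rep(0, 5))
    expect_equal(unname(apply(sub, 2, max)), rep(1, 5))
  }
  # median: squashed into (0, 1)
  md <- standardize_features(tb, "median")
  expect_true(all(md$X > 0 & md$X < 1))
  # shapes always conserved
  for (m in c("zscore", "minmax", "median", "none"))
    expect_equal(dim(standardize_features(tb, m)$X), dim(tb$X))
})

test_that("standardization never crosses subjects (LOSO safety)", {
  tb <- toy_table(n_subjects = 4, n_trials = 3, p = 6, seed = 3)
  for (m in c("zscore", "minmax", "median")) {
    full <- standardize_features(tb, m)
    # deleting any other subject leaves a subject's standardized rows unchanged
    reduced <- standardize_features(subset_subjects(tb, c("S01", "S03")), m)
    expect_equal(full$X[full$meta$subject_id == "S01", ],
                 reduced$X[reduced$meta$subject_id == "S01", ])
  }
})

test_that("the categorical group column passes through standardization untouched", {
  cfg <- tiny_config(n_subjects = 3, seed = 9)
  d <- build_panel_datasets(cfg)
  z <- suppressWarnings(standardize_features(d$tables$Be, "zscore"))
  expect_identical(z$X[, "group"], d$tables$Be$X[, "group"])
  # age is constant within subject: zero scale leaves it centered (all zero)
  expect_warning(standardize_features(d$tables$Be, "zscore"), "centered only")
})
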