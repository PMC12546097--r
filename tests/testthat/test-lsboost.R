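test_that("hyperparameter bounds are enforced", {
  expect_error(lsboost_hp(0, 0.5, 1, 1), "n must be")
  expect_error(lsboost_hp(501, 0.5, 1, 1), "n must be")
  expect_error(lsboost_hp(10, 0.005, 1, 1), "rho")
  expect_error(lsboost_hp(10, 1.2, 1, 1), "rho")
  expect_error(lsboost_hp(10, 0.5, 0, 1), "leaf_min")
  expect_error(lsboost_hp(10, 0.5, 101, 1), "leaf_min")
  expect_error(lsboost_hp(10, 0.5, 1, 0), "max_splits")
})

test_that("training MSE is non-increasing across boosting iterations", {
  withr::with_seed(2, {
    for (rho in c(0.05, 0.3, 1)) {
      X <- matrix(rnorm(40 * 6), 40, 6)
      y <- X[, 1] - 2 * X[, 3] + rnorm(40, 0, 0.5)
      m <- fit_lsboost(X, y, lsboost_hp(60, rho, 2, 8))
      expect_true(all(diff(m$train_mse) <= 1e-10))
    }
  })
})

test_that("unconstrained trees interpolate small distinct-row datasets exactly", {
  withr::with_seed(5, {
    X <- matrix(runif(10 * 3), 10, 3)
    y <- rnorm(10)
    m <- fit_lsboost(X, y, lsboost_hp(300, 1, 1, 100))
    expect_lt(max(abs(predict(m, X) - y)), 1e-8)
    expect_lt(tail(m$train_mse, 1), 1e-16)
  })
})

test_that("a leaf-only ensemble is the constant-mean predictor", {
  withr::with_seed(6, {
    X <- matrix(rnorm(8 * 2), 8, 2)
    y <- rnorm(8)
    # leaf_min above half the rows admits no split
    m <- fit_lsboost(X, y, lsboost_hp(5, 1, 8, 10))
    expect_equal(predict(m, X), rep(mean(y), 8))
    expect_equal(predict(m, matrix(rnorm(6), 3, 2)), rep(mean(y), 3))
  })
})

test_that("prediction contracts hold: constants, duplicates, row order, shapes", {
  withr::with_seed(7, {
    X <- matrix(rnorm(12 * 2), 12, 2)
    # constant targets are reproduced exactly
    mc <- fit_lsboost(X, rep(3.5, 12), lsboost_hp(10, 0.5, 2, 4))
    expect_equal(predict(mc, X), rep(3.5, 12))
    # a single duplicated training point is predicted exactly
    X1 <- X[rep(1, 6), ]
    m1 <- fit_lsboost(X1, rep(-1.25, 6), lsboost_hp(3, 1, 1, 2))
    expect_equal(predict(m1, X1[1, , drop = FALSE]), -1.25)
    # permutation of prediction rows permutes predictions
    m <- fit_lsboost(X, X[, 1] + rnorm(12, 0, 0.1), lsboost_hp(30, 0.3, 2, 5))
    perm <- sample(12)
    expect_equal(predict(m, X[perm, ]), predict(m, X)[perm])
    # feature-count mismatch is an error
    expect_error(predict(m, matrix(rnorm(9), 3, 3)), "features")
  })
})

test_that("impurity importance is normalized, equivariant, and finds the signal", {
  withr::with_seed(8, {
    X <- matrix(rnorm(60 * 5), 60, 5,
                dimnames = list(NULL, paste0("f", 1:5)))
    y <- 4 * X[, 3] + rnorm(60, 0, 0.2)
    m <- fit_lsboost(X, y, lsboost_hp(80, 0.2, 2, 6))
    imp <- feature_importance(m)
    expect_equal(sum(imp), 1, tolerance = 1e-9)
    expect_true(all(imp >= 0))
    expect_gt(imp["f3"], 0.5)
    # permuting feature columns permutes the scores (up to the documented
    # lowest-feature-index tie-break, which can flip exactly tied splits in
    # tiny leaves)
    perm <- c(4, 2, 5, 1, 3)
    m2 <- fit_lsboost(X[, perm], y, lsboost_hp(80, 0.2, 2, 6))
    expect_equal(unname(feature_importance(m2)), unname(imp[perm]),
                 tolerance = 0.01)
    # split-free model: zero vector with a warning
    m0 <- fit_lsboost(X, y, lsboost_hp(3, 1, 60, 10))
    expect_warning(imp0 <- feature_importance(m0), "no splits")
    expect_equal(unname(imp0), rep(0, 5))
  })
})

test_that("fitting is deterministic and serializes to JSON", {
  withr::with_seed(9, {
    X <- matrix(rnorm(30 * 4), 30, 4)
    y <- rnorm(30)
  })
  m1 <- fit_lsboost(X, y, lsboost_hp(20, 0.5, 2, 5))
  m2 <- fit_lsboost(X, y, lsboost_hp(20, 0.5, 2, 5))
  expect_equal(predict(m1, X), predict(m2, X))
  path <- file.path(withr::local_tempdir(), "model.json")
  write_lsboost_json(m1, path)
  obj <- jsonlite::read_json(path)
  expect_equal(obj$f0, m1$f0)
  expect_length(obj$trees, 20)
})
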