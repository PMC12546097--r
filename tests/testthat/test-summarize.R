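fake_combo <- function(dataset, target, ls_mae, me_mae, lr_mae) {
  mk <- function(v) list(fold_mae = v, mean = mean(v), sd = sd(v),
                         objective = mean(v))
  ls <- mk(ls_mae); me <- mk(me_mae); lr <- mk(lr_mae)
  list(dataset = dataset, target = target, lsboost = ls, me = me, lr = lr,
       d_me = cohens_d(me_mae, ls_mae), d_lr = cohens_d(lr_mae, ls_mae))
}

test_that("summarize_performance aggregates per-model summaries", {
  df <- data.frame(dataset = c("Be", "Co"), target = c("bitter", "acid"),
                   mae_mean = c(0.4, 0.6), mae_sd = c(0.1, 0.2),
                   d_me = c(1.0, 0.6), d_lr = c(1.2, 0.8))
  rep <- summarize_performance(df)
  expect_equal(rep$n_models, 2)
  expect_equal(unname(rep$overall_mae), c(0.5, sd(c(0.4, 0.6))))
  expect_equal(unname(rep$overall_mae_antilog["mean"]),
               mean(expm1(c(0.4, 0.6))))
  expect_equal(unname(rep$d_me), c(0.8, sd(c(1.0, 0.6))))
  expect_error(summarize_performance(df[, -3]), "columns")
})

test_that("summarize_models keeps only doubly-significant improvements", {
  withr::with_seed(30, {
    good_ls <- runif(15, 0.2, 0.3)
    bad_bench <- runif(15, 0.55, 0.7)
    close_bench <- good_ls + rnorm(15, 0.01, 0.1)
  })
  sig <- fake_combo("Be", "bitter", good_ls, bad_bench, bad_bench + 0.02)
  nonsig <- fake_combo("Co", "sweet", good_ls, close_bench, close_bench)
  expect_true(sig$d_me$significant && sig$d_lr$significant)
  rep <- summarize_models(list(sig, nonsig))
  expect_false(rep$no_significant_models)
  expect_equal(rep$n_models, 1)
  expect_equal(rep$per_model$target, "bitter")
  expect_equal(unname(rep$overall_mae["mean"]), mean(good_ls))
  # no significant model: empty report with the explicit flag
  rep0 <- summarize_models(list(nonsig))
  expect_true(rep0$no_significant_models)
  expect_equal(rep0$n_models, 0L)
  expect_true(is.na(rep0$overall_mae["mean"]))
})

test_that("importance aggregation collapses channels and builds a topography", {
  feats <- {
    cfg <- panel_config(n_subjects = 2, seed = 1)
    c(as.vector(t(outer(cfg$channel_names,
                        paste0("p_", band_names()), paste, sep = "."))),
      as.vector(t(outer(cfg$channel_names,
                        paste0("hjorth_", c("A", "M", "C")), paste, sep = "."))),
      "age", "group")
  }
  # concentration: everything on Cz alpha power
  conc <- setNames(rep(0, 306), feats)
  conc["Cz.p_alpha"] <- 1
  agg <- aggregate_importance(list(list(dataset = "Be", target = "bitter",
                                        importance = conc)))
  expect_equal(agg$class_table$p_alpha, 1)
  expect_equal(sum(agg$class_table[, -(1:2)]), 1)
  expect_equal(agg$topography$score[agg$topography$channel == "Cz"], 1)
  expect_equal(sum(agg$topography$score), 1)
  # uniform importance: bands and Hjorth classes get 38/306, demographics 1/306
  unif <- setNames(rep(1 / 306, 306), feats)
  agg_u <- aggregate_importance(list(list(dataset = "Co", target = "acid",
                                          importance = unif)))
  expect_equal(agg_u$class_table$p_delta, 38 / 306)
  expect_equal(agg_u$class_table$hjorth_M, 38 / 306)
  expect_equal(agg_u$class_table$age, 1 / 306)
  expect_equal(agg_u$class_table$group, 1 / 306)
  # class scores plus demographics always total 1
  expect_equal(sum(agg_u$class_table[, -(1:2)]), 1)
  # unnormalized vectors are rejected
  expect_error(aggregate_importance(list(list(dataset = "Be", target = "b",
                                              importance = conc * 2))),
               "not normalized")
})
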