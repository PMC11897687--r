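test_that("leave-one-mouse-out splits partition the trials", {
  ds <- simulate_feature_experiment(n_mice = 8, n_features = 12,
                                    n_informative = 0, seed = 1)
  splits <- lomo_splits(ds)
  expect_length(splits, 8)
  held <- sort(unlist(lapply(splits, `[[`, "test")))
  expect_equal(held, seq_along(ds$mouse_ids))   # covers all trials once
  for (sp in splits) {
    expect_length(intersect(ds$mouse_ids[sp$train], ds$mouse_ids[sp$test]), 0)
  }
  tiny <- experiment_dataset(matrix(rnorm(8), 4, 2,
                                    dimnames = list(NULL, c("a", "b"))),
                             c("A", "A", "B", "B"),
                             c("m1", "m1", "m2", "m2"))
  expect_error(lomo_splits(tiny), "at least 3 mice")
})

test_that("z-scoring is fit on train only, with the n-1 SD convention", {
  train <- matrix(c(1, 3, 10, 10), 2, 2, dimnames = list(NULL, c("f", "g")))
  test <- matrix(c(2, 10), 1, 2, dimnames = list(NULL, c("f", "g")))
  z <- zscore_fit_apply(train, test)
  expect_equal(z$train[, "f"], c(-1, 1) / sqrt(2))
  expect_equal(unname(z$train[, "g"]), c(0, 0))     # constant -> zeros
  expect_identical(z$constant, "g")
  expect_equal(unname(z[[2]][1, ]), c(0, 0))        # test row at train mean
  # the binary sex column passes through untouched
  train2 <- matrix(c(0, 1, 1, 5, 7, 9), 3, 2,
                   dimnames = list(NULL, c("sex", "f")))
  z2 <- zscore_fit_apply(train2)
  expect_equal(unname(z2$train[, "sex"]), c(0, 1, 1))
})

test_that("consensus ranking weighs occurrence before mean rank", {
  l <- list(letters[1:5], letters[1:5], letters[1:5])
  expect_identical(consensus_rank(l, 5), letters[1:5])
  # a feature ranked first everywhere is consensus rank 1
  l2 <- list(c("x", "b", "c"), c("x", "c", "b"), c("x", "d", "b"))
  expect_identical(consensus_rank(l2, 1), "x")
  # occurrence dominates: f_b in 4/4 lists at rank 40 beats f_a in 3/4 at 2
  lists <- lapply(1:4, function(i) {
    filler <- sprintf("z%02d_%d", 1:45, i)   # unique per list
    c(paste0("top", i), filler[1:38], "f_b", filler[39:45])
  })
  for (i in 1:3) lists[[i]][2] <- "f_a"
  cons <- consensus_rank(lists, 50)
  expect_lt(match("f_b", cons), match("f_a", cons))
  expect_error(consensus_rank(list()), "at least one")
})

test_that("hyperparameter mode takes majorities and breaks ties smallest", {
  grid <- list(max_depth = c(3, 5, 0))
  sets <- list(list(max_depth = 3), list(max_depth = 3), list(max_depth = 5))
  m <- mode_hyperparams(sets, grid)
  expect_equal(m$max_depth, 3)
  expect_length(attr(m, "ties"), 0)
  tie <- mode_hyperparams(list(list(max_depth = 3), list(max_depth = 5)),
                          grid)
  expect_equal(tie$max_depth, 3)           # grid order breaks the tie
  expect_identical(attr(tie, "ties"), "max_depth")
  expect_error(mode_hyperparams(list(list(a = 1), list(b = 1)), grid),
               "inconsistent")
})

test_that("Wilcoxon against chance matches the exact sign-flip oracle", {
  w <- wilcoxon_vs_chance(rep(1, 16))
  expect_equal(w$W, 136)                    # 16 * 17 / 2
  expect_lt(w$p, 0.001)
  expect_lt(oracle_signed_rank_p(rep(0.5, 16)), 0.001)

  deg <- wilcoxon_vs_chance(rep(0.5, 16))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)

  # accuracies symmetric about chance: p far from significance
  acc <- 0.5 + c(-0.4, -0.3, -0.2, -0.1, 0.1, 0.2, 0.3, 0.4)
  ws <- wilcoxon_vs_chance(acc)
  expect_gt(ws$p, 0.9)
  expect_equal(oracle_signed_rank_p(acc - 0.5), 1)
})

test_that("RFE keeps planted features and errors on impossible targets", {
  ds <- simulate_feature_experiment(n_mice = 10, n_features = 40,
                                    n_informative = 4, effect_size = 3,
                                    seed = 5)
  cfg <- fast_cv_config(seed = 5, n_select = 15)
  z <- zscore_fit_apply(ds$features)
  sel <- rfe_select(z$train, factor(ds$labels), cfg, seed = 1)
  expect_length(sel, 15)
  expect_true(all(ds$informative %in% sel))
  cfg_bad <- fast_cv_config(n_select = 40)
  expect_error(rfe_select(z$train, factor(ds$labels), cfg_bad, seed = 1),
               "n_select")
})

test_that("nested LOMO recovers a planted effect and stays reproducible", {
  ds <- simulate_feature_experiment(n_mice = 10, n_features = 60,
                                    n_informative = 5, effect_size = 3,
                                    seed = 21)
  cfg <- fast_cv_config(seed = 21)
  res <- run_nested_lomo(ds, cfg)
  expect_gte(res$mean_accuracy, 0.9)
  expect_true(all(ds$informative %in% res$consensus_features))
  expect_true(all(res$per_animal$accuracy %in% c(0, 0.5, 1)))
  expect_equal(nrow(res$per_animal), 10)
  expect_length(res$consensus_features, cfg$n_select)
  # same seed, same result, regardless of global RNG state
  set.seed(4242); runif(3)
  res2 <- run_nested_lomo(ds, cfg)
  expect_identical(res$per_animal, res2$per_animal)
  expect_identical(res$consensus_features, res2$consensus_features)
  expect_identical(res$final_hyperparams, res2$final_hyperparams)
})

test_that("identical candidate grids give identical tuning outcomes", {
  ds <- simulate_feature_experiment(n_mice = 6, n_features = 30,
                                    n_informative = 2, effect_size = 2,
                                    seed = 3)
  cfg <- fast_cv_config(seed = 3, n_select = 10)
  i1 <- inner_select_and_tune(ds$features, ds$labels, ds$mouse_ids, cfg, 1L)
  i2 <- inner_select_and_tune(ds$features, ds$labels, ds$mouse_ids, cfg, 1L)
  expect_identical(i1$hypers, i2$hypers)
  expect_identical(i1$ranked_lists, i2$ranked_lists)
})

test_that("held-out rows cannot influence their own split's selection", {
  ds <- simulate_feature_experiment(n_mice = 8, n_features = 40,
                                    n_informative = 3, effect_size = 2,
                                    seed = 9)
  cfg <- fast_cv_config(seed = 9, n_select = 15)
  splits <- lomo_splits(ds)
  sp <- splits[[3]]
  run_inner <- function(features)
    inner_select_and_tune(features[sp$train, , drop = FALSE],
                          ds$labels[sp$train], ds$mouse_ids[sp$train],
                          cfg, seed_base = 3L)
  before <- run_inner(ds$features)
  perturbed <- ds$features
  perturbed[sp$test, ] <- perturbed[sp$test, ] + 1e6
  after <- run_inner(perturbed)
  expect_identical(before$ranked_lists, after$ranked_lists)
  expect_identical(before$hypers, after$hypers)
})

test_that("cohort transfer reuses cohort-A statistics on cohort B", {
  cfg <- fast_cv_config(seed = 13)
  a <- simulate_feature_experiment(n_mice = 10, n_features = 60,
                                   n_informative = 5, effect_size = 3,
                                   seed = 13)
  b <- simulate_feature_experiment(n_mice = 10, n_features = 60,
                                   n_informative = 5, effect_size = 3,
                                   seed = 14)
  tr <- transfer_predict(a, b, cfg)
  expect_gte(tr$mean_accuracy, 0.9)
  expect_equal(nrow(tr$per_animal), 10)
  # mismatched manifests are rejected
  b2 <- b
  colnames(b2$features)[1] <- "renamed"
  expect_error(transfer_predict(a, b2, cfg), "manifest")
})
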