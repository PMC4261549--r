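# small separable problem: two Gaussian blobs far apart in 6 dimensions
separable_toy <- function(seed = 1, n = 30) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    x <- matrix(rnorm(n * 6, sd = 0.2), n, 6) + outer(y, rep(4, 6))
    list(x = x, y = y)
  })
}

test_that("hyperparameter grid search honours its contracts", {
  toy <- separable_toy()
  # 1x1 grid is returned directly, no inner CV
  hp <- grid_search_svm(toy$x, toy$y, C_grid = 2, gamma_grid = 0.5)
  expect_equal(hp, list(cost = 2, gamma = 0.5, auc = NA_real_))

  hp2 <- grid_search_svm(toy$x, toy$y, C_grid = c(1, 8), gamma_grid = c(0.05, 0.5),
                         inner_folds = 3, seed = 4)
  expect_equal(hp2$auc, 1)   # separable: inner-CV AUC 1 at the selected pair
  hp3 <- grid_search_svm(toy$x, toy$y, C_grid = c(1, 8), gamma_grid = c(0.05, 0.5),
                         inner_folds = 3, seed = 4)
  expect_identical(hp2, hp3) # same seed, same selection

  expect_error(grid_search_svm(toy$x, rep(1, nrow(toy$x)), 1, 1),
               class = "vitabind_label_error")
  expect_error(grid_search_svm(toy$x, toy$y, numeric(0), 1),
               class = "vitabind_input_error")
})

test_that("subspace SVMs train on the reduced columns and rank separable data", {
  toy <- separable_toy()
  all_cols <- vitabind:::new_feature_subspace(1:6, "fisher")
  hp <- list(cost = 1, gamma = 1 / 6)
  m <- train_subspace_svm(toy$x, all_cols, hp, y = toy$y)
  sc <- score_model(m, toy$x)
  expect_true(all(sc >= 0 & sc <= 1))
  expect_gt(min(sc[toy$y == 1]), max(sc[toy$y == 0]))   # separable ranking
  # identity subspace equals an unreduced fit
  m2 <- train_subspace_svm(toy$x, all_cols, hp, y = toy$y)
  expect_equal(score_model(m2, toy$x), sc, tolerance = 1e-12)

  sub2 <- vitabind:::new_feature_subspace(c(2, 5), "fisher")
  mr <- train_subspace_svm(toy$x, sub2, hp, y = toy$y)
  expect_equal(mr$svm$tot.nSV <= nrow(toy$x), TRUE)
  expect_error(train_subspace_svm(toy$x, all_cols, hp, y = rep(0, 30)),
               class = "vitabind_label_error")
})

test_that("ensemble scores are unweighted member means with bounded range", {
  toy <- separable_toy(3)
  ens <- train_ensemble(toy$x, selectors = c("fisher", "variance"), y = toy$y,
                        k = 4, C_grid = 1, gamma_grid = 1 / 6)
  expect_length(ens$members, 2)
  sc <- predict_scores(ens, toy$x)
  m1 <- score_model(ens$members[[1]], toy$x)
  m2 <- score_model(ens$members[[2]], toy$x)
  expect_equal(sc, (m1 + m2) / 2)
  expect_true(all(sc >= pmin(m1, m2) - 1e-12 & sc <= pmax(m1, m2) + 1e-12))

  # identical members average to the single-member score
  ens3 <- train_ensemble(toy$x, selectors = c("fisher", "fisher", "fisher"),
                         y = toy$y, k = 4, C_grid = 1, gamma_grid = 1 / 6)
  expect_equal(predict_scores(ens3, toy$x), score_model(ens3$members[[1]], toy$x))

  # single-selector ensemble is the identity on its member
  ens1 <- train_ensemble(toy$x, selectors = "fisher", y = toy$y, k = 4,
                         C_grid = 1, gamma_grid = 1 / 6)
  expect_equal(predict_scores(ens1, toy$x), score_model(ens1$members[[1]], toy$x))

  expect_error(predict_scores(ens, toy$x[, 1:3]), class = "vitabind_input_error")
  expect_error(train_ensemble(toy$x, selectors = character(0), y = toy$y),
               class = "vitabind_input_error")
})

test_that("the default heterogeneous trio yields three recorded subspaces", {
  ds <- tiny_dataset(seed = 21, n = 5)
  prop <- compute_binding_propensities(ds$records)
  fm <- build_feature_matrix(ds$records, ds$profiles, ds$ss, prop)
  ens <- train_ensemble(fm, C_grid = 1, gamma_grid = 1 / 408, seed = 2)
  expect_equal(tidy(ens)$selector, c("jlfwl", "fisher", "laplacian"))
  subs <- lapply(ens$members, function(m) m$subspace$indices)
  expect_false(identical(subs[[1]], subs[[2]]) && identical(subs[[2]], subs[[3]]))
  # fixed-size members inherit the jlfwl-determined size
  expect_equal(tidy(ens)$subspace_size[2], ens$members[[1]]$subspace$k)
  expect_equal(tidy(ens)$subspace_size[3], ens$members[[1]]$subspace$k)
})

test_that("threshold calibration stores strategy and controls calls, not scores", {
  toy <- separable_toy(5)
  ens <- train_ensemble(toy$x, selectors = "fisher", y = toy$y, k = 4,
                        C_grid = 1, gamma_grid = 1 / 6)
  sc <- predict_scores(ens, toy$x)
  ens_b <- calibrate_threshold(ens, sc, toy$y, "balanced")
  expect_equal(ens_b$strategy, "balanced")
  expect_false(is.na(ens_b$threshold))
  ens_f <- calibrate_threshold(ens, sc, toy$y, "fixed", threshold = 0.9)
  expect_equal(ens_f$threshold, 0.9)
  expect_equal(predict_scores(ens_f, toy$x), sc)   # threshold never alters scores
})

test_that("training, persistence and prediction round-trip end to end", {
  ds <- tiny_dataset(seed = 31, n = 5)
  model <- train_predictor(ds$records, ds$profiles, ds$ss, selectors = "fisher",
                           strategy = "maxmcc", seed = 3)
  pred <- predict_residues(model, ds$records, ds$profiles, ds$ss)
  expect_equal(nrow(pred), sum(nchar(ds$records$sequence)))
  expect_true(all(pred$score >= 0 & pred$score <= 1))
  expect_equal(pred$call, classify(pred$score, model$ensemble$threshold))

  # threshold override changes calls only
  pred2 <- predict_residues(model, ds$records, ds$profiles, ds$ss, threshold = 1)
  expect_equal(pred2$score, pred$score)
  expect_true(all(pred2$call == 0))

  # empty input -> empty, well-formed tibble
  empty <- predict_residues(model, ds$records[0, ], ds$profiles, ds$ss)
  expect_equal(nrow(empty), 0)
  expect_equal(names(empty), c("sequence_id", "position", "residue", "score", "call"))

  arc <- tempfile(fileext = ".rds")
  save_model(model, arc)
  model2 <- load_model(arc)
  expect_equal(predict_residues(model2, ds$records, ds$profiles, ds$ss)$score,
               pred$score)
  # version guard
  model_bad <- model; model_bad$version <- "0.0.0"
  saveRDS(model_bad, arc)
  expect_error(load_model(arc), class = "vitabind_version_error")
})
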