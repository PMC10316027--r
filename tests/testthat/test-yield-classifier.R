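small_grid <- list(nrounds = c(60), max_depth = c(3, 5), eta = c(0.2),
                   subsample = c(1), colsample_bytree = c(1))

test_that("the 7:3 split of 210 records gives exactly 147 and 63", {
  ds <- simulate_yield_dataset(n = 210, seed = 1)
  sp <- split_dataset(ds, 0.7, seed = 2)
  expect_equal(nrow(sp$train$features), 147L)
  expect_equal(nrow(sp$test$features), 63L)
  expect_equal(sort(c(sp$train_idx, setdiff(1:210, sp$train_idx))), 1:210)
})

test_that("splits are stratified, disjoint, exhaustive and deterministic", {
  ds <- simulate_yield_dataset(n = 210, seed = 3)
  sp1 <- split_dataset(ds, 0.7, seed = 7)
  sp2 <- split_dataset(ds, 0.7, seed = 7)
  expect_identical(sp1$train_idx, sp2$train_idx)
  # class proportions preserved within one record
  tr_tab <- table(sp1$train$labels)
  expect_equal(unname(round(101 * 0.7)), unname(tr_tab[["high"]]), tolerance = 1)
  small <- simulate_yield_dataset(n = 10, class_counts = c(high = 4,
                                                           medium = 3, low = 3),
                                  seed = 1)
  sps <- split_dataset(small, 0.7, seed = 1)
  expect_equal(nrow(sps$train$features), 7L)
  expect_equal(nrow(sps$test$features), 3L)
})

test_that("grid search honours the argmax contract and grid order", {
  ds <- simulate_yield_dataset(n = 120, class_counts = c(high = 50,
                                                         medium = 50, low = 20),
                               seed = 5)
  one_point <- list(nrounds = 40, max_depth = 3, eta = 0.3, subsample = 1,
                    colsample_bytree = 1)
  m1 <- grid_search_cv(ds, one_point, k = 3, seed = 1)
  expect_equal(m1$best_params$max_depth, 3)
  expect_equal(nrow(m1$cv_results), 1L)

  m2 <- grid_search_cv(ds, small_grid, k = 3, seed = 1)
  expect_true(m2$best_params$max_depth %in% small_grid$max_depth)
  expect_equal(m2$cv_score, max(m2$cv_results$cv_accuracy))
  expect_error(grid_search_cv(ds, small_grid, k = 25),
               class = "aircanopy_argument_error")
  expect_error(grid_search_cv(ds, c(small_grid, list(eta2 = numeric(0))), k = 3),
               class = "aircanopy_argument_error")
})

test_that("probabilities normalize and an overfit model recovers its labels", {
  ds <- simulate_yield_dataset(n = 90, class_counts = c(high = 30, medium = 30,
                                                        low = 30), seed = 6)
  m <- grid_search_cv(ds, list(nrounds = 150, max_depth = 5, eta = 0.3,
                               subsample = 1, colsample_bytree = 1),
                      k = 3, seed = 2)
  pred <- classify_yield(m, ds$features)
  expect_equal(rowSums(as.matrix(pred[, c("high", "medium", "low")])),
               rep(1, 90), tolerance = 1e-6)
  expect_gte(mean(pred$.pred_class == ds$labels), 0.99)
  expect_error(classify_yield(m, ds$features[, 1:5]),
               class = "aircanopy_validation_error")
})

test_that("well-separated synthetic classes are recovered with >=0.9 accuracy", {
  ds <- simulate_yield_dataset(n = 210, seed = 11)
  sp <- split_dataset(ds, 0.7, seed = 11)
  m <- grid_search_cv(sp$train, small_grid, k = 3, seed = 11)
  expect_gte(m$cv_score, 0.9)
  pred <- classify_yield(m, sp$test$features)
  acc <- mean(pred$.pred_class == sp$test$labels)
  expect_gte(acc, 0.9)
})

test_that("importances are normalized and concentrate on informative traits", {
  ds1 <- simulate_yield_dataset(n = 240, class_counts = c(high = 80,
                                                          medium = 80, low = 80),
                                informative = "snpm2", seed = 12)
  m1 <- grid_search_cv(ds1, small_grid, k = 3, seed = 12)
  imp1 <- feature_importance(m1)
  expect_equal(sum(imp1$importance), 1, tolerance = 1e-9)
  expect_gt(imp1$importance[imp1$trait == "snpm2"], 0.6)

  ds3 <- simulate_yield_dataset(n = 240, class_counts = c(high = 80,
                                                          medium = 80, low = 80),
                                informative = c("snpm2", "ndyi", "asm"),
                                seed = 13)
  m3 <- grid_search_cv(ds3, small_grid, k = 3, seed = 13)
  imp3 <- feature_importance(m3)
  joint <- sum(imp3$importance[imp3$trait %in% c("snpm2", "ndyi", "asm")])
  expect_gt(joint, 0.7)
})

test_that("tidy and glance expose importances and the tuning summary", {
  ds <- simulate_yield_dataset(n = 90, class_counts = c(high = 30, medium = 30,
                                                        low = 30), seed = 14)
  m <- grid_search_cv(ds, list(nrounds = 50, max_depth = 3, eta = 0.3,
                               subsample = 1, colsample_bytree = 1),
                      k = 3, seed = 14)
  td <- generics::tidy(m)
  expect_named(td, c("trait", "importance"))
  expect_equal(nrow(td), 7L)
  gl <- generics::glance(m)
  expect_true(all(c("cv_accuracy", "nrounds", "max_depth") %in% names(gl)))
  expect_equal(gl$n_train, 90L)
})

test_that("the tuning pipeline is deterministic under a fixed seed", {
  ds <- simulate_yield_dataset(n = 90, class_counts = c(high = 30, medium = 30,
                                                        low = 30), seed = 15)
  m1 <- grid_search_cv(ds, small_grid, k = 3, seed = 4)
  m2 <- grid_search_cv(ds, small_grid, k = 3, seed = 4)
  expect_identical(m1$cv_results$cv_accuracy, m2$cv_results$cv_accuracy)
  expect_identical(m1$importances, m2$importances)
})
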