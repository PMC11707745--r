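test_that("stratified split hits 80/10/10 within one record and partitions the data", {
  ds <- stratified_split(label_only_dataset(1000), seed = 3)
  tb <- table(ds$split)
  expect_true(abs(tb[["train"]] - 800) <= 1)
  expect_true(abs(tb[["valid"]] - 100) <= 1)
  expect_true(abs(tb[["test"]] - 100) <= 1)
  expect_equal(sum(tb), 1000L)
  expect_false(anyNA(ds$split))
})

test_that("stratification keeps per-bin train fractions near the target ratio", {
  ds0 <- label_only_dataset(1000, seed = 9)
  ds <- stratified_split(ds0, seed = 4, n_bins = 10L)
  bins <- cut(ds0$records$label,
              quantile(ds0$records$label, seq(0, 1, 0.1)), include.lowest = TRUE)
  frac <- tapply(ds$split == "train", bins, mean)
  expect_true(all(abs(frac - 0.8) <= 0.05))
})

test_that("splitting is seed-reproducible and fails on tiny datasets", {
  d1 <- stratified_split(label_only_dataset(50), seed = 5)
  d2 <- stratified_split(label_only_dataset(50), seed = 5)
  d3 <- stratified_split(label_only_dataset(50), seed = 6)
  expect_identical(d1$split, d2$split)
  expect_false(identical(d1$split, d3$split))
  expect_error(stratified_split(label_only_dataset(9)),
               class = "bcstools_too_small_error")
})

test_that("regression metrics match the closed-form definitions", {
  y <- c(0, 0, 2, 2); p <- c(0, 1, 1, 2)
  m <- compute_metrics(y, p)
  expect_equal(m$mae, 0.5)
  expect_equal(m$rmse, 1 / sqrt(2))
  expect_equal(m$r2, 0.5)
  perfect <- compute_metrics(1:5, 1:5)
  expect_equal(c(perfect$r2, perfect$mae, perfect$rmse), c(1, 0, 0))
  mean_pred <- compute_metrics(1:5, rep(3, 5))
  expect_equal(mean_pred$r2, 0)
  expect_error(compute_metrics(rep(1, 5), rnorm(5)),
               class = "bcstools_degenerate_error")
  expect_error(compute_metrics(1:4, 1:3), class = "bcstools_length_mismatch_error")
})

test_that("metrics agree with brute-force oracles to 1e-12 and obey RMSE >= MAE", {
  for (i in 1:20) {
    y <- withr::with_seed(100 + i, rnorm(50))
    p <- withr::with_seed(200 + i, y + rnorm(50, 0, 0.5))
    m <- compute_metrics(y, p)
    expect_equal(m$r2, oracle_r2(y, p), tolerance = 1e-12)
    expect_equal(m$mae, oracle_mae(y, p), tolerance = 1e-12)
    expect_equal(m$rmse, oracle_rmse(y, p), tolerance = 1e-12)
    expect_gte(m$rmse, m$mae)
    expect_lte(m$r2, 1)
  }
})

test_that("the GBDT recovers a planted descriptor signal on held-out data", {
  ds <- shared_qspr_dataset()   # n = 250, noise_sd = 0.1
  bundle <- train_regressor(ds, seed = 7)
  expect_gte(bundle$metrics$test$r2, 0.9)
  expect_equal(bundle$representation, "fingerprint+descriptors")
  expect_true("MW" %in% bundle$descriptor_names)
})

test_that("training is deterministic and rejects constant labels", {
  ds <- shared_qspr_dataset()
  b1 <- train_regressor(ds, seed = 3)
  b2 <- train_regressor(ds, seed = 3)
  expect_equal(b1$metrics$test$rmse, b2$metrics$test$rmse)
  expect_equal(b1$metrics$valid$r2, b2$metrics$valid$r2)
  flat <- ds
  flat$records$label <- rep(1, nrow(flat$records))
  expect_error(train_regressor(flat), class = "bcstools_degenerate_error")
})

test_that("hyperparameter search logs every trial and never loses to the default", {
  ds <- shared_qspr_dataset()
  tu <- tune_hyperparameters(ds, n_evals = 6, seed = 5)
  expect_equal(nrow(tu$trials), 6L)
  expect_equal(tu$trials$trial, 1:6)
  # trial 1 is the default configuration; the best cannot be worse
  expect_lte(tu$best_rmse, tu$trials$valid_rmse[1])
  tu2 <- tune_hyperparameters(ds, n_evals = 6, seed = 5)
  expect_identical(tu$best_params, tu2$best_params)
  expect_equal(tu$trials$valid_rmse, tu2$trials$valid_rmse)
})

test_that("cross-validation folds partition the train+valid pool and summarize spread", {
  ds <- shared_qspr_dataset()
  cv <- cross_validate(ds, k = 5, seed = 2)
  ns <- vapply(cv$fold_metrics, function(m) m$valid$n, 0L)
  pool_n <- sum(ds$split %in% c("train", "valid"))
  expect_equal(sum(ns), pool_n)
  expect_true(max(ns) - min(ns) <= 1)
  expect_setequal(cv$summary$metric, c("rmse", "mae", "r2"))
  expect_true(all(cv$summary$sd >= 0))
  expect_true(all(grepl("\\d\\.\\d{3}\\(\\d\\.\\d{3}\\)", cv$summary$formatted)))
  # cv mean held-out R2 close to the single-split estimate on the same data
  b <- train_regressor(ds, seed = 2)
  cv_r2 <- cv$summary$mean[cv$summary$partition == "valid" & cv$summary$metric == "r2"]
  expect_lt(abs(cv_r2 - b$metrics$test$r2), 0.05)
  expect_error(cross_validate(ds, k = 200), class = "bcstools_too_small_error")
})

test_that("model bundles reload with bit-identical predictions", {
  ds <- shared_qspr_dataset()
  bundle <- train_regressor(ds, seed = 1)
  probe <- cbind(ds$features$fingerprint, ds$features$descriptors)[1:20, ]
  colnames(probe) <- c(paste0("fp", 1:1024), colnames(ds$features$descriptors))
  dir <- withr::local_tempdir()
  save_model_bundle(bundle, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  reloaded <- load_model_bundle(dir)
  expect_identical(predict(bundle, probe), predict(reloaded, probe))
  expect_equal(reloaded$hyperparameters$eta, bundle$hyperparameters$eta)
  expect_equal(reloaded$descriptor_names, bundle$descriptor_names)
})

test_that("bundles predict directly from SMILES", {
  ds <- shared_qspr_dataset()
  bundle <- train_regressor(ds, seed = 1)
  p <- predict(bundle, ds$records$canonical_smiles[1:3])
  expect_length(p, 3L)
  expect_true(all(is.finite(p)))
  expect_identical(p, predict(bundle, ds$records$canonical_smiles[1:3]))
})

test_that("the regressor registry accepts plug-in backends", {
  register_regressor(
    "grand_mean",
    fit = function(X, y, Xval, yval, params, seed) mean(y),
    predict = function(model, X) rep(model, nrow(X))
  )
  expect_true("grand_mean" %in% list_regressors())
  ds <- shared_qspr_dataset()
  b <- train_regressor(ds, algorithm = "grand_mean")
  expect_equal(b$metrics$train$r2, 0, tolerance = 1e-8)
  register_ranger_regressor()
  rf <- train_regressor(ds, algorithm = "ranger", seed = 4)
  expect_gt(rf$metrics$test$r2, 0.5)
  expect_error(train_regressor(ds, algorithm = "no_such"),
               class = "bcstools_missing_model_error")
})

test_that("tuning and cross-validation never touch the test partition", {
  ds <- shared_qspr_dataset()
  # poison the test rows: if any stage consumed them, fits would degrade or err
  poisoned <- ds
  poisoned$records$label[poisoned$split == "test"] <- NA_real_
  tu <- tune_hyperparameters(poisoned, n_evals = 2, seed = 1)
  expect_true(all(is.finite(tu$trials$valid_rmse)))
  cv <- cross_validate(poisoned, k = 3, seed = 1)
  expect_true(all(is.finite(cv$summary$mean)))
  b <- train_regressor(ds, seed = 1)
  expect_identical(b$audit$fit_partitions, c("train", "valid"))
})
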