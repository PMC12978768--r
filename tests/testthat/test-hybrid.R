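test_that("z-scoring uses population statistics learned on the training data", {
  z <- zscore(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(z$train), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-4)
  expect_equal(as.numeric(z$train), c(-1.2247, 0, 1.2247), tolerance = 1e-4)

  Xtr <- matrix(stats::rnorm(40), 20, 2)
  Xap <- matrix(stats::rnorm(10), 5, 2)
  z2 <- zscore(Xtr, Xap)
  expect_equal(z2$apply, sweep(sweep(Xap, 2, z2$center), 2, z2$scale, "/"))
  expect_warning(z3 <- zscore(cbind(Xtr, 7)), "zero-variance")
  expect_equal(unname(z3$train[, 3]), rep(0, 20))
})

test_that("the GBM starts from the training mean and descends", {
  set.seed(61)
  X <- matrix(stats::rnorm(300), 100, 3)
  y <- sin(X[, 1]) + 0.5 * X[, 2] + stats::rnorm(100, 0, 0.1)
  g <- gbm_fit(X, y, n_stages = 40)
  expect_equal(g$init, mean(y))                 # squared-error argmin constant
  expect_true(all(diff(g$rss_trace) <= 1e-10))  # boosting descent
  # a 0-stage model predicts the constant
  g0 <- gbm_fit(X, y, n_stages = 1, learning_rate = 0)
  expect_equal(predict(g0, X), rep(mean(y), 100))
  # deterministic refit
  g2 <- gbm_fit(X, y, n_stages = 40)
  expect_identical(predict(g, X), predict(g2, X))
})

test_that("random-forest predictions average the individual trees", {
  set.seed(62)
  X <- matrix(stats::rnorm(200), 50, 4)
  y <- X[, 1] - X[, 2] + stats::rnorm(50, 0, 0.1)
  rf <- ecga4d:::rf_fit(X, y, seed = 5)
  per_tree <- stats::predict(rf, X, predict.all = TRUE)
  expect_equal(unname(rowMeans(per_tree$individual)),
               unname(per_tree$aggregate), tolerance = 1e-10)
  # averaging more trees shrinks prediction variance across refits
  set.seed(63)
  x0 <- matrix(stats::rnorm(4), 1, 4)
  p1 <- replicate(15, stats::predict(
    randomForest::randomForest(X, y, ntree = 1), x0))
  p100 <- replicate(15, stats::predict(
    randomForest::randomForest(X, y, ntree = 100), x0))
  expect_lt(stats::var(p100), stats::var(p1))
})

test_that("RFE keeps the requested count and retains planted signal", {
  set.seed(7)
  X <- matrix(stats::rnorm(120 * 50), 120, 50)
  beta <- c(3, -3, 2.5, 2, -2)
  y <- as.numeric(X[, 1:5] %*% beta) + stats::rnorm(120, 0, 0.5)
  sel <- rfe_select(X, y, n_keep = 10, seed = 7)
  expect_length(sel, 10)
  expect_true(all(1:5 %in% sel))
  # p == n_keep is the identity
  expect_equal(as.integer(rfe_select(X[, 1:10], y, n_keep = 10, seed = 1)), 1:10)
  expect_error(rfe_select(X[, 1:5], y, n_keep = 10), "fewer")
})

test_that("baseline learners fit with their default settings and report metrics", {
  set.seed(71)
  X <- matrix(stats::rnorm(300), 100, 3)
  y <- as.numeric(X %*% c(1, -1, 2)) + stats::rnorm(100, 0, 0.05)
  for (nm in c("linear", "dt", "rf", "gbm")) {
    b <- train_baseline(nm, X, y, seed = 2)
    expect_s3_class(b, "baseline_model")
    expect_true(is.finite(b$report$q2_kfold))
    expect_gt(b$report$r2, 0.5)
  }
  expect_gt(train_baseline("linear", X, y, seed = 2)$report$q2_kfold, 0.999)
  expect_error(train_baseline("svm", X, y), "unknown")
  expect_error(train_baseline("linear", X[1:5, ], y[1:5]), "at least 10")
})

test_that("the ANN baseline trains under its configured settings", {
  set.seed(72)
  X <- matrix(stats::rnorm(200), 100, 2)
  y <- X[, 1]^2 + stats::rnorm(100, 0, 0.1)
  cfg <- ml_config(ann = list(hidden = 10, maxit = 100))
  b <- train_baseline("ann", X, y, config = cfg, seed = 3, folds = 3)
  expect_gt(b$report$r2, 0.5)
})

test_that("stacking respects the feature contract and is reproducible", {
  sp <- synthetic_spec(seed = 11, n_obs = 120, p_descriptors = 6,
                       signal_indices = 1:4, noise_sd = 0.1)
  ml <- gen_ml_table(sp)
  st <- train_stack_gbm_rf(ml$X, ml$y, seed = 4)
  expect_equal(st$feature_layout$score_column, ncol(ml$X) + 1L)
  st2 <- train_stack_gbm_rf(ml$X, ml$y, seed = 4)
  expect_identical(predict(st, ml$X), predict(st2, ml$X))
  so <- train_stack_gbm_rf(ml$X, ml$y, mode = "score-only", seed = 4)
  expect_equal(so$feature_layout$score_column, 1L)
  expect_error(train_stack_gbm_rf(ml$X, rep(1, 120)), "degenerate")
})

test_that("naive stacking is optimistic relative to out-of-fold evaluation", {
  sp <- synthetic_spec(seed = 11, n_obs = 150, p_descriptors = 8,
                       signal_indices = 1:4, noise_sd = 0.2)
  ml <- gen_ml_table(sp)
  naive <- train_stack_gbm_rf(ml$X, ml$y, mode = "naive", seed = 6)
  r2_naive <- regression_metrics(ml$y, predict(naive, ml$X))$r2
  q2_oof <- q2_kfold(ecga4d:::stack_spec(seed = 6), ml$X, ml$y,
                     folds = 5, seed = 6)
  expect_gte(r2_naive, q2_oof)
})

test_that("model comparison tables are complete and reproducible", {
  set.seed(81)
  X <- matrix(stats::rnorm(240), 80, 3)
  y <- as.numeric(X %*% c(2, -1, 0.5))
  tab <- evaluate_models(X, y, models = c("linear", "dt"), seed = 9)
  expect_equal(names(tab), c("model", "R2", "MSE", "MAE", "RMSE", "Q2"))
  expect_equal(tab$model, c("linear", "dt"))
  # the perfect (noiseless linear) learner row
  expect_equal(tab$R2[1], 1, tolerance = 1e-10)
  expect_lt(tab$RMSE[1], 1e-10)
  tab2 <- evaluate_models(X, y, models = c("linear", "dt"), seed = 9)
  expect_identical(tab, tab2)
  expect_error(evaluate_models(X, y, models = "linear"), "at least 2")
})
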