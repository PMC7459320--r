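test_that("kernel identities hold for the laplacian kernel", {
  x <- c(1, 2, 3)
  expect_equal(laplacian_kernel(x, x, gamma = 0.5), 1)
  expect_equal(laplacian_kernel(c(0, 0), c(1, 0), gamma = 1), exp(-1))
  expect_equal(laplacian_kernel(c(0.5, 0.25, 0.25), c(0, 0, 0), gamma = 1),
               exp(-1))
})

test_that("adaboost interpolates a noiseless toy response", {
  set.seed(2)
  X <- matrix(runif(20 * 3), 20, 3, dimnames = list(NULL, c("x1", "x2", "x3")))
  y <- X[, 1]
  m <- train_model(model_spec("adaboost", list(n_estimators = 10L)), X, y,
                   seed = 3)
  expect_lt(mean(abs(predict(m, X) - y)), 0.05)
})

test_that("predictions are deterministic, row-equivariant, and 1-NN memorizes", {
  set.seed(6)
  X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- rnorm(40)
  m <- train_model(model_spec("knn", list(n_neighbours = 1L)), X, y, seed = 1)
  expect_equal(predict(m, X), y)
  ada <- train_model("adaboost", X, y, seed = 1)
  p1 <- predict(ada, X); p2 <- predict(ada, X)
  expect_identical(p1, p2)
  perm <- sample(40)
  expect_equal(predict(ada, X[perm, ]), p1[perm])
  expect_error(predict(ada, X[, 1:3]), class = "lanbind_feature_layout_error")
})

test_that("every algorithm of the zoo trains and predicts finite values", {
  set.seed(9)
  X <- matrix(runif(80 * 6), 80, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(80, 0, 0.1)
  small <- list(
    random_forest = list(n_estimators = 20L),
    knn = list(), svm_linear = list(C = 1), svm_rbf = list(C = 10, gamma = 0.1),
    krr_linear = list(), krr_poly = list(), krr_rbf = list(alpha = 0.01, gamma = 0.1),
    krr_laplacian = list(alpha = 0.01, gamma = 0.1),
    mlp = list(n1 = 8L, n2 = 8L, epochs = 300L),
    adaboost = list(n_estimators = 10L))
  for (alg in names(small)) {
    m <- train_model(model_spec(alg, small[[alg]]), X, y, seed = 4)
    p <- predict(m, X)
    expect_length(p, 80L)
    expect_true(all(is.finite(p)), info = alg)
    expect_lt(mean(abs(p - y)), sd(y), label = paste(alg, "train MAE"))
  }
  expect_error(model_spec("linear_regression"), class = "lanbind_model_error")
  expect_error(train_model("knn", cbind(c(1, NA)), c(1, 2)),
               class = "lanbind_model_error")
})

test_that("default specs carry the tuned hyperparameters and scalers", {
  ada <- model_spec("adaboost")
  expect_equal(ada$hyperparameters$n_estimators, 20L)
  expect_equal(ada$hyperparameters$max_depth, 40L)
  expect_equal(ada$scaler_method, "normal_quantile")
  rf <- model_spec("random_forest")
  expect_equal(rf$hyperparameters$n_estimators, 60L)
  expect_equal(rf$hyperparameters$min_samples_leaf, 2L)
  expect_equal(model_spec("krr_laplacian")$hyperparameters$gamma, 0.012)
  expect_equal(model_spec("svm_linear")$hyperparameters$C, 48)
  expect_equal(model_spec("mlp")$hyperparameters$n1, 700L)
})

test_that("evaluation metrics match hand arithmetic", {
  ev <- evaluate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ev$mae, 0); expect_equal(ev$rmse, 0); expect_equal(ev$r2, 1)
  # SS_res = 2, SS_tot = 2
  ev2 <- evaluate(c(0, 2), c(1, 1))
  expect_equal(ev2$mae, 1); expect_equal(ev2$rmse, 1); expect_equal(ev2$r2, 0)
  expect_message(ev3 <- evaluate(c(2, 2), c(1, 3)), "zero-variance")
  expect_true(is.na(ev3$r2))
  # error curve is the CDF of absolute errors
  ev4 <- evaluate(c(0, 0, 0, 0), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(ev4$error_curve$threshold, c(0.1, 0.2, 0.3, 0.4))
  expect_equal(ev4$error_curve$cumulative_fraction, c(0.25, 0.5, 0.75, 1))
  # per-cation grouping
  ev5 <- evaluate(c(1, 2, 3, 4), c(1, 3, 3, 6), cations = c("Eu", "Eu", "Gd", "Gd"))
  expect_equal(ev5$per_cation$mae[ev5$per_cation$cation == "Eu"], 0.5)
  expect_equal(ev5$per_cation$n, c(2L, 2L))
})

test_that("rmse >= mae on fuzzed evaluations", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(2:50, 1)
    ev <- evaluate(rnorm(n), rnorm(n))
    expect_gte(ev$rmse, ev$mae)
    expect_gte(ev$mae, 0)
    expect_lte(ev$r2, 1)
    expect_true(all(diff(ev$error_curve$cumulative_fraction) >= 0))
  }
})

test_that("grid search minimizes cross-validated MAE deterministically", {
  set.seed(12)
  X <- matrix(runif(120 * 4), 120, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- 3 * X[, 1] + rnorm(120, 0, 0.05)
  folds <- kfold(seq_len(120), k = 5, seed = 3)
  single <- grid_search("knn", list(list(n_neighbours = 3L)), X, y, folds)
  expect_equal(single$hyperparameters$n_neighbours, 3L)
  grid <- list(list(n_neighbours = 2L), list(n_neighbours = 60L))
  best <- grid_search("knn", grid, X, y, folds, seed = 1)
  cv <- attr(best, "cv_mae")
  expect_lt(min(cv), max(cv))  # the good point beats the degenerate one
  expect_equal(best$hyperparameters$n_neighbours, 2L)
  best2 <- grid_search("knn", grid, X, y, folds, seed = 1)
  expect_equal(best$hyperparameters, best2$hyperparameters)
  expect_error(grid_search("knn", list(), X, y, folds),
               class = "lanbind_model_error")
})

test_that("tree-ensemble predictions are invariant across monotone scalers", {
  set.seed(13)
  X <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1]^2 + X[, 2] + rnorm(100, 0, 0.1)
  preds <- lapply(c("minmax", "standard", "maxabs", "robust"), function(sc) {
    m <- train_model(model_spec("adaboost", list(n_estimators = 5L),
                                scaler_method = sc), X, y, seed = 2)
    predict(m, X)
  })
  for (k in 2:length(preds)) expect_equal(preds[[1]], preds[[k]], tolerance = 1e-9)
})

test_that("model bundles survive a save/load round trip", {
  set.seed(14)
  X <- matrix(runif(30 * 3), 30, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- rnorm(30)
  m <- train_model("krr_rbf", X, y, seed = 1)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_equal(predict(m2, X), predict(m, X))
  expect_identical(m2$feature_names, colnames(X))
})

test_that("the tuned boosted model generalizes on study-shaped data", {
  fx <- fx_synth()
  tr <- fx$train
  m <- fx_adaboost()
  ev <- evaluate(fx$y[!tr], predict(m, fx$X[!tr, ]),
                 fx$records$cation_symbol[!tr])
  expect_gt(ev$r2, 0.9)
  expect_gte(ev$rmse, ev$mae)
  expect_true(all(ev$per_cation$n > 0))
})
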