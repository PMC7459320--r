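test_that("impurity importance recovers the informative feature", {
  set.seed(21)
  X <- matrix(runif(1000 * 10), 1000, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  y <- 5 * X[, 1] + rnorm(1000, 0, 0.1)
  rf <- train_model(model_spec("random_forest", list(n_estimators = 30L)),
                    X, y, seed = 1)
  imp <- impurity_importance(rf)
  expect_equal(imp$ranking[1], "f1")
  expect_equal(sum(imp$scores), 1, tolerance = 1e-9)
  expect_true(all(imp$scores >= 0))
  ada <- train_model(model_spec("adaboost", list(n_estimators = 5L)), X, y,
                     seed = 1)
  impa <- impurity_importance(ada)
  expect_equal(impa$ranking[1], "f1")
  expect_equal(sum(impa$scores), 1, tolerance = 1e-9)
  # non-tree models are rejected
  knn <- train_model("knn", X[1:50, ], y[1:50], seed = 1)
  expect_error(impurity_importance(knn), class = "lanbind_unsupported_method")
})

test_that("a feature never used in any split scores zero", {
  set.seed(22)
  X <- cbind(f1 = runif(200), f2 = rep(1, 200))  # constant: unusable
  y <- X[, 1]
  ada <- train_model(model_spec("adaboost", list(n_estimators = 3L)), X, y,
                     seed = 1)
  imp <- impurity_importance(ada)
  expect_equal(unname(imp$scores["f2"]), 0)
})

test_that("permutation importance isolates model-relevant features", {
  set.seed(23)
  X <- matrix(runif(400 * 6), 400, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 4 * X[, 1] + rnorm(400, 0, 0.1)
  m <- train_model(model_spec("random_forest", list(n_estimators = 30L)),
                   X[1:300, ], y[1:300], seed = 2)
  pi <- permutation_importance(m, X[301:400, ], y[301:400], n_repeats = 10,
                               seed = 4)
  expect_equal(pi$ranking[1], "f1")
  # null features hover near zero: negligible next to the informative score
  # (tree ensembles fit noise features slightly, so the bound is relative)
  for (j in paste0("f", 2:6))
    expect_lt(abs(pi$scores[[j]]), 0.05 * pi$scores[["f1"]])
  # reproducible for a fixed seed; an identity shuffle changes nothing
  pi2 <- permutation_importance(m, X[301:400, ], y[301:400], n_repeats = 10,
                                seed = 4)
  expect_identical(pi$scores, pi2$scores)
  Xp <- X[301:400, ]
  Xp[, 2] <- Xp[order(seq_len(100)), 2]  # forced identity permutation
  expect_equal(mean(abs(predict(m, Xp) - y[301:400])) - pi$baseline_mae, 0)
  expect_error(permutation_importance(m, X, y, n_repeats = 0),
               class = "lanbind_model_error")
})

test_that("permutation importance runs on every algorithm (model-agnostic)", {
  set.seed(24)
  X <- matrix(runif(60 * 3), 60, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- 2 * X[, 1] + rnorm(60, 0, 0.05)
  for (alg in c("knn", "svm_rbf", "krr_laplacian", "mlp")) {
    hp <- switch(alg, mlp = list(n1 = 4L, n2 = 4L, epochs = 150L),
                 svm_rbf = list(C = 10, gamma = 0.5),
                 krr_laplacian = list(alpha = 0.01, gamma = 0.5), list())
    m <- train_model(model_spec(alg, hp), X, y, seed = 1)
    pi <- permutation_importance(m, X, y, n_repeats = 3, seed = 2)
    expect_equal(pi$ranking[1], "f1", info = alg)
  }
})

test_that("the MAE-dimensionality curve plateaus once informative features enter", {
  fm <- fx_matrix()
  tr <- seq_len(400)
  spec <- model_spec("adaboost", list(n_estimators = 10L))
  m <- train_model(spec, fm$X[tr, ], fm$y[tr], seed = 3)
  ranked <- impurity_importance(m)$ranking
  expect_true(all(fm$informative %in% ranked[1:5]))
  ks <- c(3, 5, 10, 20)
  curve <- mae_vs_dimensionality(ranked, fm$X[tr, ], fm$y[tr],
                                 fm$X[-tr, ], fm$y[-tr], spec = spec, ks = ks,
                                 seed = 3)
  expect_equal(curve$k, ks)
  expect_true(all(is.finite(curve$test_mae)))
  # plateau: top-5 model is already close to the all-features baseline
  expect_lt(curve$test_mae[curve$k == 5],
            2 * curve$test_mae[curve$k == 20] + 0.05)
  # k = full feature count reproduces the baseline evaluation for this seed
  base <- train_model(spec, fm$X[tr, ranked], fm$y[tr], seed = 3)
  base_mae <- mean(abs(predict(base, fm$X[-tr, ranked]) - fm$y[-tr]))
  expect_equal(curve$test_mae[curve$k == 20], base_mae, tolerance = 1e-9)
  expect_warning(
    mae_vs_dimensionality(ranked, fm$X[tr, ], fm$y[tr], fm$X[-tr, ],
                          fm$y[-tr], spec = spec, ks = c(5, 50), seed = 3),
    "truncated")
})

test_that("importance reports serialize to JSON and TSV", {
  set.seed(25)
  X <- matrix(runif(50 * 3), 50, 3, dimnames = list(NULL, paste0("f", 1:3)))
  m <- train_model(model_spec("adaboost", list(n_estimators = 3L)), X,
                   X[, 1], seed = 1)
  imp <- impurity_importance(m)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_importance(imp, jp)
  write_importance(imp, tp)
  back <- jsonlite::read_json(jp, simplifyVector = TRUE)
  expect_equal(back$ranking[1], imp$ranking[1])
  tsv <- read.delim(tp)
  expect_equal(tsv$feature[1], imp$ranking[1])
})
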