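train_mat <- function(n = 50, p = 4, seed = 8) {
  set.seed(seed)
  matrix(rnorm(n * p, sd = c(1, 10, 0.1, 100)), n, p, byrow = TRUE,
         dimnames = list(NULL, paste0("x", 1:p)))
}

test_that("each scaler satisfies its column-wise contract", {
  X <- train_mat()
  mm <- apply_scaler(fit_scaler(X, "minmax"), X)
  expect_equal(unname(apply(mm, 2, min)), rep(0, 4))
  expect_equal(unname(apply(mm, 2, max)), rep(1, 4))
  expect_equal(unname(apply_scaler(fit_scaler(cbind(a = c(0, 5, 10)),
                                              "minmax"),
                                   cbind(a = c(0, 5, 10)))[, 1]),
               c(0, 0.5, 1))
  st <- apply_scaler(fit_scaler(X, "standard"), X)
  expect_equal(unname(colMeans(st)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(st, 2, sd)), rep(1, 4), tolerance = 1e-12)
  ma <- apply_scaler(fit_scaler(X, "maxabs"), X)
  expect_equal(unname(apply(ma, 2, function(c) max(abs(c)))), rep(1, 4))
  rb <- apply_scaler(fit_scaler(X, "robust"), X)
  expect_equal(unname(apply(rb, 2, median)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(apply(rb, 2, IQR)), rep(1, 4), tolerance = 1e-12)
})

test_that("uniform quantile transform matches a sort-based rank oracle", {
  set.seed(3)
  x <- sample(rnorm(40))  # distinct values
  X <- cbind(a = x)
  u <- apply_scaler(fit_scaler(X, "uniform_quantile"), X)[, 1]
  oracle <- (rank(x) - 1) / (length(x) - 1)
  expect_equal(u, oracle, tolerance = 1e-9)
  # normal quantile composes with the standard normal inverse CDF
  nq <- apply_scaler(fit_scaler(X, "normal_quantile"), X)[, 1]
  expect_equal(nq, qnorm(pmin(pmax(oracle, 1e-7), 1 - 1e-7)), tolerance = 1e-9)
  # extrapolation clips to the boundary quantile
  beyond <- cbind(a = c(min(x) - 100, max(x) + 100))
  expect_equal(apply_scaler(fit_scaler(X, "uniform_quantile"), beyond)[, 1],
               c(0, 1))
})

test_that("scalers are strictly monotone, invertible where defined, and leak-free", {
  X <- train_mat()
  for (m in c("minmax", "standard", "maxabs", "robust", "uniform_quantile",
              "normal_quantile")) {
    sc <- fit_scaler(X, m)
    out <- apply_scaler(sc, X)
    for (j in 1:4) expect_identical(order(out[, j]), order(X[, j]))
    # fitted parameters are a pure function of the training matrix
    expect_identical(sc$params, fit_scaler(X, m)$params)
  }
  sc <- fit_scaler(X, "minmax")
  expect_equal(invert_scaler(sc, apply_scaler(sc, X)), X, tolerance = 1e-12)
  # constant column maps to 0 under scale-by-zero guard
  Xc <- cbind(const = rep(2, 10), v = rnorm(10))
  expect_message(scc <- fit_scaler(Xc, "standard"), "constant")
  expect_equal(unname(apply_scaler(scc, Xc)[, 1]), rep(0, 10))
})

test_that("scalers serialize to JSON and reload bit-compatibly", {
  X <- train_mat()
  for (m in c("minmax", "robust", "normal_quantile")) {
    sc <- fit_scaler(X, m)
    path <- withr::local_tempfile(fileext = ".json")
    write_scaler(sc, path)
    sc2 <- read_scaler(path)
    expect_equal(apply_scaler(sc2, X), apply_scaler(sc, X), tolerance = 1e-12)
  }
})

test_that("pca variance curve matches closed-form and sampling oracles", {
  # two perfectly correlated columns: one component explains everything
  x <- rnorm(30)
  curve <- pca_variance(cbind(x, 2 * x + 5))
  expect_equal(curve[1], 1, tolerance = 1e-9)
  # identity covariance: curve approximately k/5
  set.seed(4)
  Z <- matrix(rnorm(4000 * 5), 4000, 5)
  curve5 <- pca_variance(Z)
  expect_equal(curve5, (1:5) / 5, tolerance = 0.05)
  expect_true(all(diff(curve5) >= -1e-12))
  expect_equal(curve5[5], 1, tolerance = 1e-9)
  expect_error(pca_variance(Z[1, , drop = FALSE]), class = "lanbind_pca_error")
})

test_that("l1 selection recovers sparse signals and obeys penalty limits", {
  set.seed(5)
  X <- matrix(rnorm(500 * 10), 500, 10, dimnames = list(NULL, paste0("x", 1:10)))
  y <- 4 * X[, 3] + rnorm(500, 0, 0.5)
  sel <- l1_select(X, y)
  expect_true("x3" %in% sel$selected)
  expect_identical(l1_select(X, y, strength = 1e6)$selected, character(0))
  expect_setequal(l1_select(X, y, strength = 0)$selected, colnames(X))
  expect_error(l1_select(cbind(X[, 1], NA), y[1:500]),
               class = "lanbind_config_error")
})
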