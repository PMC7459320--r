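# The regressor zoo: ten algorithm variants with tuned default
# hyperparameters and their paired scaler, a uniform train/predict surface,
# evaluation metrics and cross-validated grid search.

ALGORITHMS <- c("random_forest", "knn", "svm_linear", "svm_rbf", "krr_linear",
                "krr_poly", "krr_rbf", "krr_laplacian", "mlp", "adaboost")

# Tuned defaults per algorithm (hyperparameters and normalization).
DEFAULT_MODEL_SPECS <- list(
  random_forest = list(hyperparameters = list(n_estimators = 60L, max_depth = 40L,
                                              min_samples_leaf = 2L),
                       scaler_method = "normal_quantile"),
  knn = list(hyperparameters = list(n_neighbours = 2L, p = 2),
             scaler_method = "robust"),
  svm_linear = list(hyperparameters = list(C = 48), scaler_method = "minmax"),
  svm_rbf = list(hyperparameters = list(C = 450, gamma = 0.073),
                 scaler_method = "uniform_quantile"),
  krr_linear = list(hyperparameters = list(alpha = 0.25), scaler_method = "robust"),
  krr_poly = list(hyperparameters = list(alpha = 0.030, gamma = 0.082, degree = 3L),
                  scaler_method = "uniform_quantile"),
  krr_rbf = list(hyperparameters = list(alpha = 0.002, gamma = 0.006),
                 scaler_method = "robust"),
  krr_laplacian = list(hyperparameters = list(alpha = 0.001, gamma = 0.012),
                       scaler_method = "uniform_quantile"),
  mlp = list(hyperparameters = list(n1 = 700L, n2 = 800L, epochs = 100L,
                                    learning_rate = 1e-3),
             scaler_method = "normal_quantile"),
  adaboost = list(hyperparameters = list(n_estimators = 20L, max_depth = 40L,
                                         loss = "linear"),
                  scaler_method = "normal_quantile"))

#' Construct a model specification
#'
#' @param algorithm One of `ALGORITHMS`.
#' @param hyperparameters Named list; omitted entries take the tuned
#'   defaults.
#' @param scaler_method One of `SCALER_METHODS`; default is the
#'   normalization paired with the algorithm.
#' @return A `lan_model_spec`.
#' @export
model_spec <- function(algorithm, hyperparameters = list(), scaler_method = NULL) {
  if (!algorithm %in% ALGORITHMS)
    lan_abort(paste0("unsupported algorithm: ", algorithm,
                     " (supported: ", paste(ALGORITHMS, collapse = ", "), ")"),
              "lanbind_model_error")
  def <- DEFAULT_MODEL_SPECS[[algorithm]]
  hp <- def$hyperparameters
  hp[names(hyperparameters)] <- hyperparameters
  structure(list(algorithm = algorithm, hyperparameters = hp,
                 scaler_method = scaler_method %||% def$scaler_method),
            class = "lan_model_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Train a regressor
#'
#' Fits the spec's scaler on the training matrix (original feature scale),
#' transforms, and fits the learner on the scaled features. The target
#' (logK1) is used untransformed.
#'
#' @param spec A `lan_model_spec` (or algorithm name).
#' @param X_train Numeric feature matrix on the original scale.
#' @param y_train Numeric response.
#' @param seed Integer seed controlling any stochastic fitting.
#' @return A `lan_model` carrying the fitted state, the fitted scaler and
#'   the feature-name layout.
#' @export
train_model <- function(spec, X_train, y_train, seed = 1L) {
  if (is.character(spec)) spec <- model_spec(spec)
  X_train <- as.matrix(X_train)
  if (any(!is.finite(X_train)) || any(!is.finite(y_train)))
    lan_abort("non-finite values in training data", "lanbind_model_error")
  scaler <- fit_scaler(X_train, spec$scaler_method)
  Xs <- apply_scaler(scaler, X_train)
  hp <- spec$hyperparameters
  fitted <- switch(spec$algorithm,
    random_forest = withr_seed(seed, randomForest::randomForest(
      x = Xs, y = y_train, ntree = hp$n_estimators,
      nodesize = hp$min_samples_leaf, importance = FALSE)),
    knn = fit_knn(Xs, y_train, k = hp$n_neighbours, p = hp$p),
    svm_linear = e1071::svm(x = Xs, y = y_train, type = "eps-regression",
                            kernel = "linear", cost = hp$C, scale = FALSE),
    svm_rbf = e1071::svm(x = Xs, y = y_train, type = "eps-regression",
                         kernel = "radial", cost = hp$C, gamma = hp$gamma,
                         scale = FALSE),
    krr_linear = fit_krr(Xs, y_train, "linear", alpha = hp$alpha),
    krr_poly = fit_krr(Xs, y_train, "poly", alpha = hp$alpha,
                       gamma = hp$gamma, degree = hp$degree %||% 3L),
    krr_rbf = fit_krr(Xs, y_train, "rbf", alpha = hp$alpha, gamma = hp$gamma),
    krr_laplacian = fit_krr(Xs, y_train, "laplacian", alpha = hp$alpha,
                            gamma = hp$gamma),
    mlp = fit_mlp(Xs, y_train, hidden = c(hp$n1, hp$n2),
                  epochs = hp$epochs %||% 100L,
                  learning_rate = hp$learning_rate %||% 1e-3, seed = seed),
    adaboost = fit_adaboost(Xs, y_train, n_estimators = hp$n_estimators,
                            max_depth = hp$max_depth,
                            loss = hp$loss %||% "linear", seed = seed))
  structure(list(spec = spec, fitted = fitted, scaler = scaler,
                 feature_names = colnames(X_train), training_seed = seed,
                 n_train = nrow(X_train)),
            class = "lan_model")
}

#' Predict with a trained regressor
#'
#' Expects features on the original (unscaled) scale; the model applies its
#' own fitted scaler.
#'
#' @param object A `lan_model`.
#' @param newdata Numeric feature matrix.
#' @param ... Unused.
#' @return Numeric predictions, one per row.
#' @export
predict.lan_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$feature_names) ||
      (!is.null(colnames(X)) && !is.null(object$feature_names) &&
       !identical(colnames(X), object$feature_names)))
    lan_abort("prediction matrix layout does not match the trained model",
              "lanbind_feature_layout_error")
  Xs <- apply_scaler(object$scaler, X)
  f <- object$fitted
  switch(object$spec$algorithm,
    random_forest = as.numeric(predict(f, Xs)),
    knn = predict_knn(f, Xs),
    svm_linear = ,
    svm_rbf = as.numeric(predict(f, Xs)),
    krr_linear = ,
    krr_poly = ,
    krr_rbf = ,
    krr_laplacian = predict_krr(f, Xs),
    mlp = predict_mlp(f, Xs),
    adaboost = predict_adaboost(f, Xs))
}

#' Regression evaluation report
#'
#' MAE, RMSE, R2, per-cation metrics and the regression-error curve (the
#' empirical CDF of absolute errors).
#'
#' @param y Observed values.
#' @param y_hat Predictions.
#' @param cations Optional per-row cation labels for grouped metrics.
#' @return List with `mae`, `rmse`, `r2` (NA with a message when y has zero
#'   variance), `per_cation` (data.frame) and `error_curve` (data.frame of
#'   threshold / cumulative fraction).
#' @export
evaluate <- function(y, y_hat, cations = NULL) {
  stopifnot(length(y) == length(y_hat), length(y) >= 1)
  e <- y_hat - y
  mae <- mean(abs(e))
  rmse <- sqrt(mean(e^2))
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    message("evaluate: zero-variance response; R2 undefined")
    NA_real_
  } else 1 - sum(e^2) / ss_tot
  per_cation <- NULL
  if (!is.null(cations)) {
    per_cation <- do.call(rbind, lapply(split(seq_along(y), cations), function(i) {
      data.frame(cation = cations[i[1]], mae = mean(abs(e[i])),
                 rmse = sqrt(mean(e[i]^2)), n = length(i),
                 stringsAsFactors = FALSE)
    }))
    rownames(per_cation) <- NULL
  }
  ae <- sort(abs(e))
  curve <- data.frame(threshold = ae,
                      cumulative_fraction = seq_along(ae) / length(ae))
  list(mae = mae, rmse = rmse, r2 = r2, per_cation = per_cation,
       error_curve = curve)
}

#' Cross-validated hyperparameter grid search
#'
#' Evaluates every grid point by k-fold cross-validation and returns the
#' spec minimizing mean CV MAE; ties break toward the earlier grid point.
#'
#' @param algorithm Algorithm name.
#' @param grid List of named hyperparameter lists (nonempty).
#' @param X,y Training data (original scale).
#' @param folds Fold list from [kfold()] whose ids index rows of `X`.
#' @param seed Integer seed passed to each fit.
#' @param scaler_method Optional scaler override.
#' @return The winning `lan_model_spec`, with `cv_mae` attached as an
#'   attribute.
#' @export
grid_search <- function(algorithm, grid, X, y, folds, seed = 1L,
                        scaler_method = NULL) {
  if (length(grid) == 0) lan_abort("empty hyperparameter grid",
                                   "lanbind_model_error")
  X <- as.matrix(X)
  cv_mae <- vapply(grid, function(hp) {
    spec <- model_spec(algorithm, hp, scaler_method)
    maes <- vapply(folds, function(f) {
      m <- train_model(spec, X[f$train_ids, , drop = FALSE], y[f$train_ids],
                       seed = seed)
      mean(abs(predict(m, X[f$test_ids, , drop = FALSE]) - y[f$test_ids]))
    }, 0)
    mean(maes)
  }, 0)
  best <- which.min(cv_mae)
  out <- model_spec(algorithm, grid[[best]], scaler_method)
  attr(out, "cv_mae") <- cv_mae
  out
}

#' Save / load a trained model bundle
#'
#' The bundle stores the spec, the fitted scaler, the fitted state and the
#' feature-name manifest.
#'
#' @param model A `lan_model`.
#' @param path Output file.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model`: the restored `lan_model`.
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  stopifnot(inherits(m, "lan_model"))
  m
}
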