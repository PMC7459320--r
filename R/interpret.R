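# Feature-importance analysis: impurity-based rankings for the tree
# ensembles, model-agnostic permutation importance, and the MAE-versus-
# dimensionality curve obtained by retraining on top-k ranked features.

#' Impurity-based feature importance
#'
#' Normalized mean decrease in impurity (variance, for regression) per
#' feature. Supported for the tree ensembles only (random forest and
#' AdaBoost; the AdaBoost score is the estimator-weight-weighted average of
#' per-tree importances).
#'
#' @param model A trained `lan_model` with algorithm `random_forest` or
#'   `adaboost`.
#' @return List with `method`, `scores` (named, nonnegative, summing to 1)
#'   and `ranking` (names by descending score).
#' @export
impurity_importance <- function(model) {
  alg <- model$spec$algorithm
  if (!alg %in% c("random_forest", "adaboost"))
    lan_abort("impurity importance requires a tree ensemble",
              "lanbind_unsupported_method")
  scores <- if (alg == "random_forest") {
    imp <- model$fitted$importance[, "IncNodePurity"]
    s <- setNames(as.numeric(imp), model$feature_names)
    if (sum(s) > 0) s / sum(s) else s
  } else {
    adaboost_impurity_importance(model$fitted, model$feature_names)
  }
  list(method = paste0(alg, "_impurity"), scores = scores,
       ranking = names(sort(scores, decreasing = TRUE)))
}

#' Permutation feature importance
#'
#' Mean increase in MAE when one feature column is randomly permuted,
#' averaged over `n_repeats` seeded shuffles. Model-agnostic: runs on every
#' algorithm of the zoo. Scores near zero (possibly slightly negative) mark
#' features the model does not rely on.
#'
#' @param model A trained `lan_model`.
#' @param X,y Evaluation data on the original feature scale (a held-out set
#'   is recommended).
#' @param n_repeats Number of shuffles per feature (default 10).
#' @param seed Integer seed.
#' @return List with `method`, `scores` (named; mean MAE increase),
#'   `scores_sd` and `ranking`.
#' @export
permutation_importance <- function(model, X, y, n_repeats = 10L, seed = 1L) {
  if (n_repeats < 1) lan_abort("n_repeats must be >= 1", "lanbind_model_error")
  X <- as.matrix(X)
  base_mae <- mean(abs(predict(model, X) - y))
  p <- ncol(X)
  scores <- matrix(0, n_repeats, p, dimnames = list(NULL, colnames(X)))
  perms <- withr_seed(seed, lapply(seq_len(n_repeats), function(r)
    sample(nrow(X))))
  for (r in seq_len(n_repeats)) {
    perm <- perms[[r]]
    for (j in seq_len(p)) {
      Xp <- X
      Xp[, j] <- X[perm, j]
      scores[r, j] <- mean(abs(predict(model, Xp) - y)) - base_mae
    }
  }
  m <- colMeans(scores)
  list(method = "permutation", scores = m,
       scores_sd = apply(scores, 2, sd),
       baseline_mae = base_mae,
       ranking = names(sort(m, decreasing = TRUE)))
}

#' MAE versus feature-space dimensionality
#'
#' Retrains the given spec on the top-k ranked features for each requested k
#' and records train and test MAE, reproducing the dimensionality sweep used
#' to check how many ranked descriptors are needed before the error
#' plateaus.
#'
#' @param ranked_names Feature names in descending importance order.
#' @param X_train,y_train,X_test,y_test Split data (original scale).
#' @param spec Model spec to retrain (default AdaBoost).
#' @param ks Integer vector of dimensionalities (default 5, 10, ..., p).
#' @param seed Integer seed.
#' @return Data.frame with columns `k`, `train_mae`, `test_mae`.
#' @export
mae_vs_dimensionality <- function(ranked_names, X_train, y_train, X_test,
                                  y_test, spec = model_spec("adaboost"),
                                  ks = NULL, seed = 1L) {
  p <- length(ranked_names)
  if (is.null(ks)) ks <- unique(c(seq(5L, p, by = 5L), p))
  if (any(ks > p)) {
    warning("k values exceeding the feature count were truncated")
    ks <- unique(pmin(ks, p))
  }
  out <- data.frame(k = ks, train_mae = NA_real_, test_mae = NA_real_)
  for (i in seq_along(ks)) {
    sel <- ranked_names[seq_len(ks[i])]
    m <- train_model(spec, X_train[, sel, drop = FALSE], y_train, seed = seed)
    out$train_mae[i] <- mean(abs(predict(m, X_train[, sel, drop = FALSE]) - y_train))
    out$test_mae[i] <- mean(abs(predict(m, X_test[, sel, drop = FALSE]) - y_test))
  }
  out
}

#' Write an importance report to JSON/TSV
#' @param report A report from [impurity_importance()] or
#'   [permutation_importance()].
#' @param path Output path; `.json` or `.tsv` by extension.
#' @export
write_importance <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(method = report$method,
                              scores = as.list(report$scores),
                              ranking = report$ranking),
                         path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    df <- data.frame(feature = names(report$scores),
                     score = as.numeric(report$scores))
    df <- df[order(-df$score), ]
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
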