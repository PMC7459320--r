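# Feature scaling (six methods), PCA variance diagnostics and L1-based
# sparse feature selection. Scalers are fitted on training columns only and
# serialize to plain JSON so a screening run can reuse the training-time
# transform bit-exactly.

SCALER_METHODS <- c("minmax", "standard", "maxabs", "robust",
                    "normal_quantile", "uniform_quantile")

N_QUANTILES <- 1000L

#' Fit a feature scaler
#'
#' Column-wise scaling contracts: `minmax` maps the training range to
#' \[0, 1\]; `standard` to mean 0 / sd 1; `maxabs` divides by the maximum
#' absolute value; `robust` centers by the median and scales by the IQR;
#' `uniform_quantile` maps the empirical CDF to \[0, 1\] over a 1000-point
#' quantile grid with linear interpolation and boundary clipping;
#' `normal_quantile` composes the uniform transform with the standard normal
#' inverse CDF. Constant columns under a scale-by-zero method map to 0.
#'
#' @param train_matrix Numeric training matrix (no non-finite entries).
#' @param method One of `SCALER_METHODS`.
#' @return A `lan_scaler` object.
#' @export
fit_scaler <- function(train_matrix, method = SCALER_METHODS) {
  method <- match.arg(method)
  X <- as.matrix(train_matrix)
  if (nrow(X) < 2) lan_abort("need at least 2 rows to fit a scaler",
                             "lanbind_scaler_error")
  if (any(!is.finite(X))) lan_abort("non-finite entries in training matrix",
                                    "lanbind_scaler_error")
  params <- switch(method,
    minmax = list(min = apply(X, 2, min), max = apply(X, 2, max)),
    standard = list(mean = colMeans(X), sd = apply(X, 2, sd)),
    maxabs = list(maxabs = apply(X, 2, function(c) max(abs(c)))),
    robust = list(median = apply(X, 2, median),
                  iqr = apply(X, 2, function(c) diff(quantile(c, c(0.25, 0.75))))),
    normal_quantile = ,
    uniform_quantile = {
      probs <- seq(0, 1, length.out = min(N_QUANTILES, nrow(X)))
      list(probs = probs,
           quantiles = apply(X, 2, quantile, probs = probs, names = FALSE))
    })
  degenerate <- switch(method,
    minmax = params$max - params$min == 0,
    standard = params$sd == 0,
    maxabs = params$maxabs == 0,
    robust = params$iqr == 0,
    rep(FALSE, ncol(X)))
  if (any(degenerate))
    message(sprintf("fit_scaler(%s): %d constant column(s) mapped to 0",
                    method, sum(degenerate)))
  structure(list(method = method, params = params,
                 feature_names = colnames(X), n_features = ncol(X)),
            class = "lan_scaler")
}

scale_column_quantile <- function(x, qs, probs) {
  # empirical CDF via the stored quantile grid; clip beyond the training range
  if (diff(range(qs)) == 0) return(ifelse(x < qs[1], 0, ifelse(x > qs[1], 1, 0.5)))
  approx(x = qs, y = probs, xout = x, ties = "ordered", rule = 2)$y
}

#' Apply a fitted scaler
#'
#' Transforms columns using only the fitted parameters (no re-fitting).
#' Quantile scalers clip values beyond the training range to the boundary
#' quantile.
#'
#' @param scaler A `lan_scaler`.
#' @param matrix Numeric matrix with the fitted column layout.
#' @return Transformed matrix.
#' @export
apply_scaler <- function(scaler, matrix) {
  X <- as.matrix(matrix)
  if (ncol(X) != scaler$n_features ||
      (!is.null(colnames(X)) && !is.null(scaler$feature_names) &&
       !identical(colnames(X), scaler$feature_names)))
    lan_abort("matrix layout does not match the fitted scaler",
              "lanbind_feature_layout_error")
  p <- scaler$params
  out <- switch(scaler$method,
    minmax = {
      rng <- p$max - p$min
      out <- sweep(sweep(X, 2, p$min), 2, ifelse(rng == 0, 1, rng), "/")
      out[, rng == 0] <- 0
      out
    },
    standard = {
      s <- ifelse(p$sd == 0, 1, p$sd)
      out <- sweep(sweep(X, 2, p$mean), 2, s, "/")
      out[, p$sd == 0] <- 0
      out
    },
    maxabs = {
      s <- ifelse(p$maxabs == 0, 1, p$maxabs)
      sweep(X, 2, s, "/")
    },
    robust = {
      s <- ifelse(p$iqr == 0, 1, p$iqr)
      out <- sweep(sweep(X, 2, p$median), 2, s, "/")
      out[, p$iqr == 0] <- 0
      out
    },
    uniform_quantile = {
      out <- X
      for (j in seq_len(ncol(X)))
        out[, j] <- scale_column_quantile(X[, j], p$quantiles[, j], p$probs)
      out
    },
    normal_quantile = {
      out <- X
      eps <- 1e-7
      for (j in seq_len(ncol(X))) {
        u <- scale_column_quantile(X[, j], p$quantiles[, j], p$probs)
        out[, j] <- qnorm(pmin(pmax(u, eps), 1 - eps))
      }
      out
    })
  dimnames(out) <- dimnames(X)
  out
}

#' Invert a minmax or standard transform
#'
#' @param scaler A `lan_scaler` with method minmax, standard, maxabs or
#'   robust.
#' @param matrix Scaled matrix.
#' @return Matrix on the original scale.
#' @export
invert_scaler <- function(scaler, matrix) {
  X <- as.matrix(matrix)
  p <- scaler$params
  out <- switch(scaler$method,
    minmax = sweep(sweep(X, 2, p$max - p$min, "*"), 2, p$min, "+"),
    standard = sweep(sweep(X, 2, p$sd, "*"), 2, p$mean, "+"),
    maxabs = sweep(X, 2, p$maxabs, "*"),
    robust = sweep(sweep(X, 2, p$iqr, "*"), 2, p$median, "+"),
    lan_abort("no closed-form inverse for quantile scalers",
              "lanbind_scaler_error"))
  dimnames(out) <- dimnames(X)
  out
}

#' Serialize a scaler to JSON
#' @param scaler A `lan_scaler`.
#' @param path Output path.
#' @export
write_scaler <- function(scaler, path) {
  obj <- list(method = scaler$method, feature_names = scaler$feature_names,
              n_features = scaler$n_features,
              params = lapply(scaler$params, function(x) unname(as.matrix(x))))
  # 17 significant digits: doubles survive the text round trip bit-exactly,
  # so tie structure inside quantile grids is preserved
  jsonlite::write_json(obj, path, digits = I(17), pretty = FALSE)
  invisible(path)
}

#' Load a scaler from JSON
#' @param path JSON path written by [write_scaler()].
#' @return A `lan_scaler`.
#' @export
read_scaler <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- obj$params
  if (obj$method %in% c("uniform_quantile", "normal_quantile")) {
    params$probs <- as.numeric(params$probs)
    params$quantiles <- as.matrix(params$quantiles)
  } else {
    params <- lapply(params, as.numeric)
  }
  structure(list(method = obj$method, params = params,
                 feature_names = obj$feature_names, n_features = obj$n_features),
            class = "lan_scaler")
}

#' Cumulative explained-variance curve of a PCA
#'
#' Standardizes the input internally (documented choice), then returns the
#' cumulative eigenvalue fractions of the covariance matrix in descending
#' eigenvalue order.
#'
#' @param matrix Numeric matrix (rows = observations).
#' @return Numeric vector: cumulative explained-variance fraction at k
#'   components, nondecreasing, ending at 1.
#' @export
pca_variance <- function(matrix) {
  X <- as.matrix(matrix)
  if (nrow(X) < 2) lan_abort("need at least 2 rows for PCA", "lanbind_pca_error")
  sds <- apply(X, 2, sd)
  X <- X[, sds > 0, drop = FALSE]
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  ev <- p$sdev^2
  cumsum(ev) / sum(ev)
}

#' L1 (lasso) sparse feature selection
#'
#' Fits an L1-penalized linear model at the given strength and returns the
#' features with nonzero coefficients. `strength = 0` retains every feature
#' (unpenalized fit); very large strengths select nothing. When
#' `strength = NULL` the default follows a median-coefficient threshold rule:
#' a lasso path is fitted, the λ minimizing 10-fold CV error is taken, and
#' features whose |coefficient| is at least the median nonzero magnitude are
#' kept.
#'
#' @param X Scaled feature matrix.
#' @param y Response vector.
#' @param strength L1 penalty (λ), or NULL for the default rule.
#' @return List with `selected` (names), `coefficients` (named magnitudes).
#' @export
l1_select <- function(X, y, strength = NULL) {
  X <- as.matrix(X)
  if (any(!is.finite(X)) || any(!is.finite(y)))
    lan_abort("non-finite inputs to l1_select", "lanbind_config_error")
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!is.null(strength) && strength == 0) {
    fit <- glmnet::glmnet(X, y, alpha = 1, lambda = 0)
    beta <- as.numeric(coef(fit))[-1]
    names(beta) <- colnames(X)
    return(list(selected = colnames(X), coefficients = abs(beta)))
  }
  if (is.null(strength)) {
    cvfit <- glmnet::cv.glmnet(X, y, alpha = 1, nfolds = 10)
    beta <- as.numeric(coef(cvfit, s = "lambda.min"))[-1]
    names(beta) <- colnames(X)
    nz <- abs(beta)[abs(beta) > 0]
    thr <- if (length(nz)) median(nz) else Inf
    sel <- names(beta)[abs(beta) >= thr & abs(beta) > 0]
    return(list(selected = sel, coefficients = abs(beta)))
  }
  fit <- glmnet::glmnet(X, y, alpha = 1, lambda = strength)
  beta <- as.numeric(coef(fit))[-1]
  names(beta) <- colnames(X)
  list(selected = names(beta)[abs(beta) > 0], coefficients = abs(beta))
}
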