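# Regressor internals. Kernel ridge regression, Minkowski k-nearest
# neighbours, AdaBoost.R2 over depth-limited regression trees and a small
# fully-connected network are implemented here; random forests and SVMs are
# delegated to randomForest and e1071.

# --- kernels -----------------------------------------------------------------

kernel_matrix <- function(kind, X, Y = X, gamma = 1, degree = 3, coef0 = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  switch(kind,
    linear = X %*% t(Y),
    poly = (gamma * (X %*% t(Y)) + coef0)^degree,
    rbf = {
      d2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
      exp(-gamma * pmax(d2, 0))
    },
    laplacian = {
      n <- nrow(X); m <- nrow(Y)
      D <- matrix(0, n, m)
      for (j in seq_len(m)) D[, j] <- colSums(abs(t(X) - Y[j, ]))
      exp(-gamma * D)
    },
    lan_abort(paste("unknown kernel:", kind), "lanbind_model_error"))
}

#' Laplacian kernel value
#'
#' k(x, x') = exp(-gamma * ||x - x'||_1), the kernel behind the best
#' kernel-ridge variant of the zoo.
#'
#' @param x,y Numeric vectors.
#' @param gamma Kernel width parameter.
#' @return Scalar kernel value.
#' @export
laplacian_kernel <- function(x, y, gamma = 1) exp(-gamma * sum(abs(x - y)))

fit_krr <- function(X, y, kind, alpha, gamma = 1, degree = 3) {
  K <- kernel_matrix(kind, X, gamma = gamma, degree = degree)
  dual <- solve(K + diag(alpha, nrow(K)), y)
  list(X = as.matrix(X), dual = dual, kind = kind, gamma = gamma,
       degree = degree)
}

predict_krr <- function(fit, X) {
  K <- kernel_matrix(fit$kind, as.matrix(X), fit$X, gamma = fit$gamma,
                     degree = fit$degree)
  as.numeric(K %*% fit$dual)
}

# --- k-nearest neighbours ----------------------------------------------------

fit_knn <- function(X, y, k, p = 2) {
  list(X = as.matrix(X), y = y, k = as.integer(k), p = p)
}

predict_knn <- function(fit, X) {
  X <- as.matrix(X)
  out <- numeric(nrow(X))
  for (r in seq_len(nrow(X))) {
    d <- colSums(abs(t(fit$X) - X[r, ])^fit$p)^(1 / fit$p)
    nn <- order(d)[seq_len(min(fit$k, length(d)))]
    out[r] <- mean(fit$y[nn])
  }
  out
}

# --- AdaBoost.R2 -------------------------------------------------------------

fit_adaboost <- function(X, y, n_estimators = 20L, max_depth = 40L,
                         loss = c("linear", "square", "exponential"),
                         seed = 1L) {
  loss <- match.arg(loss)
  n <- nrow(X)
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df$.y <- y
  # rpart caps tree depth at 30; deeper requests are clamped (inert at these
  # data sizes, where grown depth stays well below the cap)
  ctrl <- rpart::rpart.control(maxdepth = min(max_depth, 30L), minsplit = 2L,
                               minbucket = 1L, cp = 0, xval = 0L,
                               maxcompete = 0L, maxsurrogate = 0L,
                               usesurrogate = 0L)
  w <- rep(1 / n, n)
  trees <- list(); betas <- numeric(0)
  withr_seed(seed, {
    for (m in seq_len(n_estimators)) {
      fit <- rpart::rpart(.y ~ ., data = df, weights = w * n, method = "anova",
                          control = ctrl)
      pred <- predict(fit, df)
      e <- abs(pred - y)
      E <- max(e)
      if (E <= 0) {
        trees[[length(trees) + 1L]] <- fit
        betas <- c(betas, 1e-10)
        break
      }
      L <- switch(loss, linear = e / E, square = (e / E)^2,
                  exponential = 1 - exp(-e / E))
      errbar <- sum(w * L)
      if (errbar >= 0.5) {
        if (length(trees) == 0) {
          trees[[1L]] <- fit
          betas <- 0.999 / 0.001
        }
        break
      }
      beta <- errbar / (1 - errbar)
      trees[[length(trees) + 1L]] <- fit
      betas <- c(betas, beta)
      w <- w * beta^(1 - L)
      w <- w / sum(w)
    }
  })
  list(trees = trees, log_inv_beta = log(1 / betas),
       feature_names = names(df)[names(df) != ".y"], loss = loss)
}

# Weighted median across estimator predictions (the AdaBoost.R2 combiner).
predict_adaboost <- function(fit, X) {
  df <- as.data.frame(X)
  names(df) <- fit$feature_names
  P <- vapply(fit$trees, function(t) as.numeric(predict(t, df)), numeric(nrow(df)))
  if (nrow(df) == 1L) P <- matrix(P, nrow = 1)
  w <- fit$log_inv_beta
  if (length(fit$trees) == 1L) return(as.numeric(P[, 1]))
  apply(P, 1, function(p) {
    o <- order(p)
    cw <- cumsum(w[o])
    p[o][which(cw >= 0.5 * sum(w))[1]]
  })
}

adaboost_impurity_importance <- function(fit, feature_names) {
  score <- setNames(numeric(length(feature_names)), feature_names)
  w <- fit$log_inv_beta
  w <- w / sum(w)
  for (m in seq_along(fit$trees)) {
    imp <- fit$trees[[m]]$variable.importance
    if (is.null(imp)) next
    imp <- imp / sum(imp)
    idx <- match(names(imp), paste0("f", seq_along(feature_names)))
    ok <- !is.na(idx)
    score[idx[ok]] <- score[idx[ok]] + w[m] * imp[ok]
  }
  if (sum(score) > 0) score <- score / sum(score)
  score
}

# --- multilayer perceptron ---------------------------------------------------

relu <- function(x) pmax(x, 0)

fit_mlp <- function(X, y, hidden = c(700L, 800L), epochs = 100L,
                    learning_rate = 1e-3, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  sizes <- c(p, hidden, 1L)
  L <- length(sizes) - 1L
  withr_seed(seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(sizes[l] * sizes[l + 1], 0, sqrt(2 / sizes[l])),
             sizes[l], sizes[l + 1]))
  })
  b <- lapply(seq_len(L), function(l) numeric(sizes[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  ym <- mean(y); ys <- sd(y); if (ys == 0) ys <- 1
  yt <- (y - ym) / ys
  for (t in seq_len(epochs)) {
    a <- list(X)
    z <- list()
    for (l in seq_len(L)) {
      z[[l]] <- sweep(a[[l]] %*% W[[l]], 2, b[[l]], "+")
      a[[l + 1]] <- if (l < L) relu(z[[l]]) else z[[l]]
    }
    delta <- 2 * (a[[L + 1]] - yt) / n
    for (l in rev(seq_len(L))) {
      gW <- t(a[[l]]) %*% delta
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(W[[l]])) * (z[[l - 1]] > 0)
      mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
      vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
      mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
      vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
      mhW <- mW[[l]] / (1 - beta1^t); vhW <- vW[[l]] / (1 - beta2^t)
      mhb <- mb[[l]] / (1 - beta1^t); vhb <- vb[[l]] / (1 - beta2^t)
      W[[l]] <- W[[l]] - learning_rate * mhW / (sqrt(vhW) + eps)
      b[[l]] <- b[[l]] - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  list(W = W, b = b, y_mean = ym, y_sd = ys)
}

predict_mlp <- function(fit, X) {
  a <- as.matrix(X)
  L <- length(fit$W)
  for (l in seq_len(L)) {
    a <- sweep(a %*% fit$W[[l]], 2, fit$b[[l]], "+")
    if (l < L) a <- relu(a)
  }
  as.numeric(a) * fit$y_sd + fit$y_mean
}
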