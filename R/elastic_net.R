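# Weighted elastic net: cyclic coordinate descent over a descending lambda
# path (compiled core in src/coord_descent.cpp), with observation weights that
# enter every moment, so integer weights are exactly equivalent to row
# duplication.

#' Fit a weighted elastic net along a lambda path
#'
#' Minimizes, with normalized weights `v_i = w_i / sum(w)`,
#' `(1/2) * sum_i v_i * (y_i - b0 - x_i'b)^2 +
#'  lambda * (alpha * ||b||_1 + (1 - alpha)/2 * ||b||_2^2)`
#' by cyclic coordinate descent with warm starts down the lambda path.
#' Features are standardized internally to weighted mean 0 / weighted
#' mean-square 1; coefficients are returned on the original scale and the
#' standardization constants are kept for prediction.
#'
#' @param X Numeric matrix, samples x features (column names required).
#' @param y Numeric response (age in years).
#' @param weights Positive observation weights (default all 1).
#' @param alpha Elastic-net mixing in `[0, 1]` (1 = lasso, 0 = ridge).
#' @param lambda Optional user lambda sequence (descending). By default a
#'   100-value log-spaced grid from `lambda_max` (smallest lambda with an
#'   all-zero solution) down to `lambda_min_ratio * lambda_max`.
#' @param nlambda,lambda_min_ratio Grid size and ratio for the default grid.
#' @param tol Convergence tolerance on the maximum coefficient change
#'   (standardized scale).
#' @param max_iter Iteration cap per lambda.
#' @return An object of class `wen_fit`: `a0` (intercepts), `beta` (features x
#'   lambdas, original scale), `lambda`, `alpha`, `feature_means`,
#'   `feature_sds`, `converged`.
#' @export
fit_weighted_elastic_net <- function(X, y, weights = NULL, alpha = 0.5,
                                     lambda = NULL, nlambda = 100,
                                     lambda_min_ratio = 1e-4,
                                     tol = 1e-7, max_iter = 1e5) {
  X <- as.matrix(X)
  stop_if(is.null(colnames(X)), "X needs column names (feature ids)")
  stop_if(length(y) != nrow(X), "length(y) must match nrow(X)")
  stop_if(alpha < 0 || alpha > 1, "alpha must lie in [0, 1]")
  weights <- weights %||% rep(1, nrow(X))
  stop_if(any(weights <= 0), "weights must be positive")
  v <- weights / sum(weights)

  mu <- as.numeric(crossprod(X, v))
  Xc <- sweep(X, 2, mu)
  sds <- sqrt(as.numeric(crossprod(Xc^2, v)))
  stop_if(any(sds == 0), "zero-variance feature retained; drop constant columns")
  Xs <- sweep(Xc, 2, sds, "/")
  ybar <- sum(v * y)
  yc <- y - ybar

  if (is.null(lambda)) {
    lam_max <- max(abs(as.numeric(crossprod(Xs, v * yc)))) / max(alpha, 1e-3)
    lambda <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                      length.out = nlambda))
  } else {
    stop_if(any(lambda < 0), "lambda must be >= 0")
    lambda <- sort(lambda, decreasing = TRUE)
  }

  fit <- cd_elastic_net_path(Xs, yc, v, lambda, alpha, tol, as.integer(max_iter))
  if (!all(fit$converged))
    rlang::warn(sprintf("coordinate descent hit the iteration cap for %d lambda value(s)",
                        sum(!fit$converged)))
  beta_std <- fit$beta
  beta <- beta_std / sds
  a0 <- ybar - as.numeric(crossprod(beta, mu))
  dimnames(beta) <- list(colnames(X), NULL)
  structure(list(a0 = a0, beta = beta, lambda = lambda, alpha = alpha,
                 feature_means = setNames(mu, colnames(X)),
                 feature_sds = setNames(sds, colnames(X)),
                 converged = fit$converged, iters = fit$iters),
            class = "wen_fit")
}

#' Predict from a weighted elastic-net path fit
#' @param object A `wen_fit`.
#' @param newx Matrix of samples x features containing the fit's features.
#' @param s Index into the lambda path (default: last, smallest lambda).
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.wen_fit <- function(object, newx, s = length(object$lambda), ...) {
  feats <- rownames(object$beta)
  stop_if(!all(feats %in% colnames(newx)), "newx is missing fitted features")
  as.numeric(newx[, feats, drop = FALSE] %*% object$beta[, s]) + object$a0[s]
}

#' Karush-Kuhn-Tucker residuals of an elastic-net solution
#'
#' For the solution at path index `s`, computes (on the standardized scale)
#' the gradient `g_j = sum_i v_i x_ij r_i` and returns the per-feature KKT
#' violation: active features must satisfy
#' `g_j - lambda * (1 - alpha) * b_j = lambda * alpha * sign(b_j)`; inactive
#' features `|g_j| <= lambda * alpha`.
#'
#' @param fit A `wen_fit`.
#' @param X,y,weights The training data the fit was produced from.
#' @param s Path index.
#' @return Numeric vector of violations (0 = condition met exactly).
#' @export
kkt_violation <- function(fit, X, y, weights = NULL, s = length(fit$lambda)) {
  weights <- weights %||% rep(1, nrow(X))
  v <- weights / sum(weights)
  X <- as.matrix(X)[, rownames(fit$beta), drop = FALSE]
  Xs <- sweep(sweep(X, 2, fit$feature_means), 2, fit$feature_sds, "/")
  b_std <- fit$beta[, s] * fit$feature_sds
  yc <- y - sum(v * y)
  r <- yc - as.numeric(Xs %*% b_std)
  g <- as.numeric(crossprod(Xs, v * r))
  lam <- fit$lambda[s]
  active <- b_std != 0
  viol <- numeric(length(g))
  viol[active] <- abs(g[active] - lam * (1 - fit$alpha) * b_std[active] -
                        lam * fit$alpha * sign(b_std[active]))
  viol[!active] <- pmax(0, abs(g[!active]) - lam * fit$alpha)
  viol
}

#' Select lambda by weighted K-fold cross-validation
#'
#' Splits samples into `n_folds` near-equal random folds (seeded), refits the
#' path on each training part, and returns the lambda minimizing the weighted
#' mean out-of-fold squared error (ties go to the larger lambda).
#'
#' @inheritParams fit_weighted_elastic_net
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold assignment.
#' @return A list: `lambda` (selected value), `cv` (tibble `lambda`, `mse`).
#' @export
select_lambda_cv <- function(X, y, weights = NULL, alpha = 0.5, lambda = NULL,
                             nlambda = 100, lambda_min_ratio = 1e-4,
                             n_folds = 10, seed = 1L) {
  stop_if(n_folds < 2, "n_folds must be >= 2")
  X <- as.matrix(X)
  weights <- weights %||% rep(1, nrow(X))
  if (is.null(lambda)) {
    # fix the grid on the full data so every fold scores the same lambdas
    full <- fit_weighted_elastic_net(X, y, weights, alpha, nlambda = nlambda,
                                     lambda_min_ratio = lambda_min_ratio)
    lambda <- full$lambda
  }
  stop_if(length(lambda) == 0, "empty lambda grid")
  folds <- assign_folds(nrow(X), n_folds, seed)
  sse <- matrix(0, n_folds, length(lambda))
  wsum <- numeric(n_folds)
  for (k in seq_len(n_folds)) {
    tr <- folds != k
    fit <- fit_weighted_elastic_net(X[tr, , drop = FALSE], y[tr], weights[tr],
                                    alpha, lambda = lambda)
    pred <- sweep(X[!tr, rownames(fit$beta), drop = FALSE] %*% fit$beta,
                  2, fit$a0, "+")
    sse[k, ] <- colSums(weights[!tr] * (y[!tr] - pred)^2)
    wsum[k] <- sum(weights[!tr])
  }
  mse <- colSums(sse) / sum(wsum)
  best <- which(mse <= min(mse) + 1e-12)[1]  # path is descending: first = largest
  list(lambda = lambda[best],
       cv = tibble::tibble(lambda = lambda, mse = mse))
}

# seeded random partition into near-equal folds (sizes differ by <= 1)
assign_folds <- function(n, n_folds, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(n_folds), n))
}
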