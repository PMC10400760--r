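# Small fully-connected ReLU regressor trained by full-batch Adam on a
# weighted squared loss. The architecture is fixed a priori (not tuned per
# dataset); training is a deterministic function of the seed.

#' Fit a feed-forward neural-network age regressor
#'
#' Fully-connected network with ReLU hidden activations and a linear output,
#' trained with full-batch Adam on the weighted squared loss
#' `0.5 * sum_i v_i (y_i - f(x_i))^2` for a fixed epoch budget. Inputs are
#' standardized to weighted mean 0 / SD 1 and the response is standardized
#' internally; both sets of constants are stored in the model. With
#' `hidden_sizes = integer(0)` the network degenerates to an (unpenalized)
#' linear regression trained by the same optimizer.
#'
#' @param X Numeric matrix, samples x features (column names required).
#' @param y Numeric response (age in years).
#' @param weights Positive observation weights (default 1).
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param epochs Fixed training budget (full-batch gradient steps).
#' @param learning_rate Adam step size.
#' @param seed Integer seed for the (He) weight initialization.
#' @return An object of class `mlp_fit` with `layers` (list of `W`, `b`),
#'   standardization constants, and the training settings.
#' @export
fit_mlp <- function(X, y, weights = NULL, hidden_sizes = c(64L, 32L),
                    epochs = 600, learning_rate = 0.01, seed = 1L) {
  X <- as.matrix(X)
  stop_if(is.null(colnames(X)), "X needs column names (feature ids)")
  stop_if(length(y) != nrow(X), "length(y) must match nrow(X)")
  weights <- weights %||% rep(1, nrow(X))
  stop_if(any(weights <= 0), "weights must be positive")
  v <- weights / sum(weights)

  mu <- as.numeric(crossprod(X, v))
  Xc <- sweep(X, 2, mu)
  sds <- sqrt(as.numeric(crossprod(Xc^2, v)))
  stop_if(any(sds == 0), "zero-variance feature; drop constant columns")
  Xs <- sweep(Xc, 2, sds, "/")
  y_mu <- sum(v * y)
  y_sd <- sqrt(sum(v * (y - y_mu)^2))
  stop_if(y_sd == 0, "constant response")
  ys <- (y - y_mu) / y_sd

  sizes <- c(ncol(X), as.integer(hidden_sizes), 1L)
  set.seed(seed)
  layers <- lapply(seq_len(length(sizes) - 1), function(l) {
    fan_in <- sizes[l]
    list(W = matrix(rnorm(fan_in * sizes[l + 1], 0, sqrt(2 / fan_in)),
                    fan_in, sizes[l + 1]),
         b = rep(0, sizes[l + 1]))
  })
  nL <- length(layers)
  # Adam state
  m_st <- lapply(layers, function(l) list(W = l$W * 0, b = l$b * 0))
  v_st <- m_st
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  for (ep in seq_len(epochs)) {
    # forward
    acts <- vector("list", nL + 1)
    acts[[1]] <- Xs
    for (l in seq_len(nL)) {
      z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
      acts[[l + 1]] <- if (l < nL) pmax(z, 0) else z
    }
    pred <- acts[[nL + 1]][, 1]
    if (any(!is.finite(pred)))
      rlang::abort("NaN/Inf in network output; lower the learning rate")
    # backward
    delta <- matrix(v * (pred - ys), ncol = 1)
    for (l in rev(seq_len(nL))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(layers[[l]]$W)) * (acts[[l]] > 0)
      m_st[[l]]$W <- b1 * m_st[[l]]$W + (1 - b1) * gW
      m_st[[l]]$b <- b1 * m_st[[l]]$b + (1 - b1) * gb
      v_st[[l]]$W <- b2 * v_st[[l]]$W + (1 - b2) * gW^2
      v_st[[l]]$b <- b2 * v_st[[l]]$b + (1 - b2) * gb^2
      mhW <- m_st[[l]]$W / (1 - b1^ep); vhW <- v_st[[l]]$W / (1 - b2^ep)
      mhb <- m_st[[l]]$b / (1 - b1^ep); vhb <- v_st[[l]]$b / (1 - b2^ep)
      layers[[l]]$W <- layers[[l]]$W - learning_rate * mhW / (sqrt(vhW) + eps)
      layers[[l]]$b <- layers[[l]]$b - learning_rate * mhb / (sqrt(vhb) + eps)
    }
  }
  structure(list(layers = layers, feature_names = colnames(X),
                 feature_means = setNames(mu, colnames(X)),
                 feature_sds = setNames(sds, colnames(X)),
                 y_mean = y_mu, y_sd = y_sd,
                 hidden_sizes = as.integer(hidden_sizes), epochs = epochs,
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "mlp_fit")
}

#' @export
predict.mlp_fit <- function(object, newx, ...) {
  stop_if(!all(object$feature_names %in% colnames(newx)),
          "newx is missing fitted features")
  Xs <- sweep(sweep(as.matrix(newx[, object$feature_names, drop = FALSE]),
                    2, object$feature_means),
              2, object$feature_sds, "/")
  a <- Xs
  nL <- length(object$layers)
  for (l in seq_len(nL)) {
    z <- sweep(a %*% object$layers[[l]]$W, 2, object$layers[[l]]$b, "+")
    a <- if (l < nL) pmax(z, 0) else z
  }
  a[, 1] * object$y_sd + object$y_mean
}
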