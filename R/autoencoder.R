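#' Autoencoder configuration
#'
#' A symmetric bottleneck autoencoder over the one-hot matrix:
#' `23 -> hidden -> 2 -> hidden -> 23`, trained to minimize mean squared
#' reconstruction error by minibatch stochastic gradient descent over full
#' shuffled passes. The two bottleneck activations are the learned
#' representation. Hidden activations are rectifier, rectifier with dropout
#' (inverted dropout on the hidden layers only), or tanh; the bottleneck and
#' output are linear.
#'
#' @param hidden_units hidden-layer width, one of 10, 20, 30.
#' @param activation `"rectifier"`, `"rectifier_dropout"` or `"tanh"`.
#' @param epochs full passes over the data, one of 10, 20, 30.
#' @param dropout_rate hidden-unit drop probability (rectifier_dropout only).
#' @param learning_rate SGD step size.
#' @param batch_size minibatch size.
#' @param seed integer seed for weight initialization and shuffling.
#' @return An object of class `"autoencoder_config"`.
#' @export
autoencoder_config <- function(hidden_units = 20L,
                               activation = c("rectifier", "rectifier_dropout", "tanh"),
                               epochs = 20L, dropout_rate = 0.2,
                               learning_rate = 1e-3, batch_size = 16L,
                               seed = 1L) {
  activation <- match.arg(activation)
  if (!hidden_units %in% c(10L, 20L, 30L)) {
    stop("hidden_units must be one of 10, 20, 30", call. = FALSE)
  }
  if (!epochs %in% c(10L, 20L, 30L)) {
    stop("epochs must be one of 10, 20, 30", call. = FALSE)
  }
  if (dropout_rate < 0 || dropout_rate >= 1) {
    stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  }
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  structure(list(hidden_units = as.integer(hidden_units),
                 bottleneck_units = 2L, activation = activation,
                 epochs = as.integer(epochs), dropout_rate = dropout_rate,
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "autoencoder_config")
}

.act <- function(a, kind) if (kind == "tanh") tanh(a) else pmax(a, 0)
.act_grad <- function(a, kind) if (kind == "tanh") 1 - tanh(a)^2 else (a > 0) * 1

.ae_forward <- function(w, x, kind, drop_masks = NULL) {
  a1 <- sweep(x %*% w$W1, 2L, w$b1, `+`)
  h1 <- .act(a1, kind)
  if (!is.null(drop_masks)) h1 <- h1 * drop_masks$m1
  z  <- sweep(h1 %*% w$W2, 2L, w$b2, `+`)          # linear bottleneck
  a3 <- sweep(z %*% w$W3, 2L, w$b3, `+`)
  h3 <- .act(a3, kind)
  if (!is.null(drop_masks)) h3 <- h3 * drop_masks$m3
  xhat <- sweep(h3 %*% w$W4, 2L, w$b4, `+`)
  list(a1 = a1, h1 = h1, z = z, a3 = a3, h3 = h3, xhat = xhat)
}

#' Fit a bottleneck autoencoder on a one-hot matrix
#'
#' @param onehot n x 23 indicator matrix ([encode_onehot()]).
#' @param config an [autoencoder_config()].
#' @return An object of class `"autoencoder"` holding the trained weights,
#'   the per-epoch training loss (`loss_history`, with the pre-training loss
#'   first) and the config. Deterministic for a fixed config.
#' @export
fit_autoencoder <- function(onehot, config = autoencoder_config()) {
  stopifnot(inherits(config, "autoencoder_config"))
  x <- as.matrix(onehot) * 1.0
  n <- nrow(x); d <- ncol(x)
  if (n < 2L) stop("autoencoder needs at least 2 rows", call. = FALSE)
  h <- config$hidden_units; k <- config$bottleneck_units
  kind <- if (config$activation == "tanh") "tanh" else "relu"
  use_dropout <- config$activation == "rectifier_dropout"

  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  glorot <- function(nin, nout)
    matrix(stats::runif(nin * nout, -1, 1) * sqrt(6 / (nin + nout)), nin, nout)
  w <- list(W1 = glorot(d, h), b1 = numeric(h),
            W2 = glorot(h, k), b2 = numeric(k),
            W3 = glorot(k, h), b3 = numeric(h),
            W4 = glorot(h, d), b4 = numeric(d))

  mse <- function(w) mean((.ae_forward(w, x, kind)$xhat - x)^2)
  loss_history <- mse(w)
  lr <- config$learning_rate

  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x[idx, , drop = FALSE]
      m <- nrow(xb)
      masks <- NULL
      if (use_dropout) {
        keep <- 1 - config$dropout_rate
        masks <- list(
          m1 = matrix(stats::rbinom(m * h, 1L, keep), m, h) / keep,
          m3 = matrix(stats::rbinom(m * h, 1L, keep), m, h) / keep
        )
      }
      f <- .ae_forward(w, xb, kind, masks)
      # backprop of mean squared error over the batch
      d_xhat <- 2 * (f$xhat - xb) / (m * d)
      g_W4 <- crossprod(f$h3, d_xhat); g_b4 <- colSums(d_xhat)
      d_h3 <- d_xhat %*% t(w$W4)
      if (use_dropout) d_h3 <- d_h3 * masks$m3
      d_a3 <- d_h3 * .act_grad(f$a3, kind)
      g_W3 <- crossprod(f$z, d_a3); g_b3 <- colSums(d_a3)
      d_z <- d_a3 %*% t(w$W3)
      g_W2 <- crossprod(f$h1, d_z); g_b2 <- colSums(d_z)
      d_h1 <- d_z %*% t(w$W2)
      if (use_dropout) d_h1 <- d_h1 * masks$m1
      d_a1 <- d_h1 * .act_grad(f$a1, kind)
      g_W1 <- crossprod(xb, d_a1); g_b1 <- colSums(d_a1)

      w$W1 <- w$W1 - lr * g_W1; w$b1 <- w$b1 - lr * g_b1
      w$W2 <- w$W2 - lr * g_W2; w$b2 <- w$b2 - lr * g_b2
      w$W3 <- w$W3 - lr * g_W3; w$b3 <- w$b3 - lr * g_b3
      w$W4 <- w$W4 - lr * g_W4; w$b4 <- w$b4 - lr * g_b4
    }
    loss_history <- c(loss_history, mse(w))
    if (!is.finite(loss_history[length(loss_history)])) {
      stop("non-finite reconstruction loss at epoch ", ep,
           "; lower the learning rate", call. = FALSE)
    }
  }

  structure(list(weights = w, config = config, columns = colnames(x),
                 loss_history = loss_history),
            class = "autoencoder")
}

#' @export
print.autoencoder <- function(x, ...) {
  cfg <- x$config
  cat("Bottleneck autoencoder", paste0(length(x$columns), "->", cfg$hidden_units,
      "->", cfg$bottleneck_units, "->", cfg$hidden_units, "->", length(x$columns)),
      "(", cfg$activation, ")\n")
  lh <- x$loss_history
  cat("  reconstruction MSE:", format(lh[1]), "->", format(lh[length(lh)]),
      "over", cfg$epochs, "epoch(s)\n")
  invisible(x)
}

#' Bottleneck representation of indicator rows
#'
#' @param encoder a fitted `"autoencoder"`.
#' @param onehot indicator matrix with the columns seen at fit time.
#' @return n x 2 matrix of bottleneck activations (columns `AE1`, `AE2`);
#'   attribute `encoding_kind = "autoencoder"`. Dropout is disabled at
#'   transform time.
#' @export
transform_autoencoder <- function(encoder, onehot) {
  stopifnot(inherits(encoder, "autoencoder"))
  x <- as.matrix(onehot) * 1.0
  if (!identical(colnames(x), encoder$columns)) {
    x <- x[, encoder$columns, drop = FALSE]
  }
  kind <- if (encoder$config$activation == "tanh") "tanh" else "relu"
  z <- .ae_forward(encoder$weights, x, kind)$z
  colnames(z) <- c("AE1", "AE2")
  structure(z, encoding_kind = "autoencoder")
}
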