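# Compact feed-forward network (three fully connected layers, hidden width
# 128, leaky-ReLU slope 0.2 on the first two layers, dropout 0.5, sigmoid
# output for binary targets) trained with Adam and manual backpropagation.
# Epochs are chosen by inner cross-validation up to the configured maximum.

#' Feed-forward network specification
#'
#' @param hidden Hidden width of both hidden layers (default 128).
#' @param dropout Dropout probability during training (default 0.5).
#' @param leaky_slope Negative slope of the leaky-ReLU activations
#'   (default 0.2).
#' @param max_epochs Maximum training epochs; the number actually used is
#'   selected by inner cross-validation (default 50).
#' @param lr Adam learning rate (default 1e-3).
#' @param batch_size Minibatch size (default 32).
#' @param inner_folds Folds of the epoch-selection inner CV (default 3).
#' @return An `mlp_spec` list.
#' @export
mlp_spec <- function(hidden = 128L, dropout = 0.5, leaky_slope = 0.2,
                     max_epochs = 50L, lr = 1e-3, batch_size = 32L,
                     inner_folds = 3L) {
  structure(list(hidden = as.integer(hidden), dropout = dropout,
                 leaky_slope = leaky_slope, max_epochs = as.integer(max_epochs),
                 lr = lr, batch_size = as.integer(batch_size),
                 inner_folds = as.integer(inner_folds)),
            class = "mlp_spec")
}

lrelu <- function(a, slope) ifelse(a > 0, a, slope * a)
lrelu_grad <- function(a, slope) ifelse(a > 0, 1, slope)
sigmoid <- function(a) 1 / (1 + exp(-a))

mlp_init <- function(d, spec) {
  h <- spec$hidden
  init <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                     nin, nout)
  list(W1 = init(d, h), b1 = numeric(h),
       W2 = init(h, h), b2 = numeric(h),
       W3 = init(h, 1), b3 = numeric(1))
}

mlp_forward <- function(par, X, spec, drop_masks = NULL) {
  A1 <- sweep(X %*% par$W1, 2, par$b1, "+")
  H1 <- lrelu(A1, spec$leaky_slope)
  if (!is.null(drop_masks)) H1 <- H1 * drop_masks$m1
  A2 <- sweep(H1 %*% par$W2, 2, par$b2, "+")
  H2 <- lrelu(A2, spec$leaky_slope)
  if (!is.null(drop_masks)) H2 <- H2 * drop_masks$m2
  out <- drop(H2 %*% par$W3 + par$b3)
  list(A1 = A1, H1 = H1, A2 = A2, H2 = H2, out = out)
}

# one Adam step on a minibatch; returns updated parameters and state
mlp_step <- function(par, adam, X, y, spec, binary, step_t) {
  n <- nrow(X)
  keep <- 1 - spec$dropout
  masks <- list(
    m1 = matrix(rbinom(n * spec$hidden, 1, keep), n) / keep,
    m2 = matrix(rbinom(n * spec$hidden, 1, keep), n) / keep)
  fw <- mlp_forward(par, X, spec, masks)
  if (binary) {
    p <- sigmoid(fw$out)
    dout <- (p - y) / n                 # BCE with sigmoid output
  } else {
    dout <- 2 * (fw$out - y) / n        # MSE
  }
  dW3 <- crossprod(fw$H2, dout); db3 <- sum(dout)
  dH2 <- (matrix(dout, ncol = 1) %*% t(par$W3)) * masks$m2
  dA2 <- dH2 * lrelu_grad(fw$A2, spec$leaky_slope)
  dW2 <- crossprod(fw$H1, dA2); db2 <- colSums(dA2)
  dH1 <- (dA2 %*% t(par$W2)) * masks$m1
  dA1 <- dH1 * lrelu_grad(fw$A1, spec$leaky_slope)
  dW1 <- crossprod(X, dA1); db1 <- colSums(dA1)
  grads <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
  b1c <- 1 - 0.9^step_t; b2c <- 1 - 0.999^step_t
  for (nm in names(par)) {
    adam$m[[nm]] <- 0.9 * adam$m[[nm]] + 0.1 * grads[[nm]]
    adam$v[[nm]] <- 0.999 * adam$v[[nm]] + 0.001 * grads[[nm]]^2
    par[[nm]] <- par[[nm]] - spec$lr * (adam$m[[nm]] / b1c) /
      (sqrt(adam$v[[nm]] / b2c) + 1e-8)
  }
  list(par = par, adam = adam)
}

mlp_train_epochs <- function(X, y, spec, binary, n_epochs, seed,
                             X_val = NULL, y_val = NULL) {
  with_seed(seed, {
    par <- mlp_init(ncol(X), spec)
    adam <- list(m = lapply(par, function(p) p * 0),
                 v = lapply(par, function(p) p * 0))
    n <- nrow(X)
    step_t <- 0
    val_loss <- rep(NA_real_, n_epochs)
    for (ep in seq_len(n_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = spec$batch_size)) {
        idx <- ord[start:min(start + spec$batch_size - 1, n)]
        step_t <- step_t + 1
        upd <- mlp_step(par, adam, X[idx, , drop = FALSE], y[idx], spec,
                        binary, step_t)
        par <- upd$par; adam <- upd$adam
      }
      if (!is.null(X_val)) {
        out <- mlp_forward(par, X_val, spec)$out
        val_loss[ep] <- if (binary) {
          p <- pmin(pmax(sigmoid(out), 1e-12), 1 - 1e-12)
          -mean(y_val * log(p) + (1 - y_val) * log(1 - p))
        } else mean((out - y_val)^2)
      }
    }
    if (any(!is.finite(mlp_forward(par, X, spec)$out)))
      stop_sfgc("non-finite network output after training")
    list(par = par, val_loss = val_loss)
  })
}

#' Train the feed-forward network
#'
#' Seeded initialization and minibatch order make training deterministic
#' given the seed. The epoch count is chosen by inner cross-validation
#' (minimum mean validation loss across inner folds, up to the maximum),
#' then the network is retrained on the full training set for that many
#' epochs.
#'
#' @param X_train Standardized training features.
#' @param y_train Outcome (0/1 for binary).
#' @param spec An [mlp_spec()].
#' @param binary Train with a sigmoid output and cross-entropy loss.
#' @param seed Integer seed.
#' @return An `mlp_model` with `par`, `spec`, `binary`, `epochs`.
#' @export
fit_mlp <- function(X_train, y_train, spec = mlp_spec(), binary = FALSE,
                    seed = 1L) {
  X_train <- as.matrix(X_train)
  n <- nrow(X_train)
  n_epochs <- spec$max_epochs
  if (spec$inner_folds >= 2 && n >= 2 * spec$inner_folds) {
    fold_id <- with_seed(derive_seed(seed, "mlp-inner"),
                         sample(rep_len(seq_len(spec$inner_folds), n)))
    losses <- matrix(NA_real_, spec$inner_folds, spec$max_epochs)
    for (f in seq_len(spec$inner_folds)) {
      tr <- fold_id != f
      res <- mlp_train_epochs(X_train[tr, , drop = FALSE], y_train[tr],
                              spec, binary, spec$max_epochs,
                              derive_seed(seed, paste0("mlp-f", f)),
                              X_train[!tr, , drop = FALSE], y_train[!tr])
      losses[f, ] <- res$val_loss
    }
    n_epochs <- which.min(colMeans(losses))
  }
  res <- mlp_train_epochs(X_train, y_train, spec, binary, n_epochs,
                          derive_seed(seed, "mlp-final"))
  structure(list(par = res$par, spec = spec, binary = binary,
                 epochs = n_epochs),
            class = "mlp_model")
}

#' @export
predict.mlp_model <- function(object, newdata, ...) {
  out <- mlp_forward(object$par, as.matrix(newdata), object$spec)$out
  if (object$binary) sigmoid(out) else out
}

#' Saliency-map feature importance of the network
#'
#' Mean over subjects of the gradient of the network output (probability
#' for binary models) with respect to the input features, computed in
#' inference mode (no dropout) by exact backpropagation through the trained
#' weights.
#'
#' @param model A fitted `mlp_model`.
#' @param X Inputs at which the gradients are evaluated.
#' @return Numeric vector of length d.
#' @export
mlp_saliency <- function(model, X) {
  X <- as.matrix(X)
  par <- model$par; spec <- model$spec
  fw <- mlp_forward(par, X, spec)
  dout <- if (model$binary) {
    p <- sigmoid(fw$out)
    p * (1 - p)
  } else rep(1, nrow(X))
  dH2 <- matrix(dout, ncol = 1) %*% t(par$W3)
  dA2 <- dH2 * lrelu_grad(fw$A2, spec$leaky_slope)
  dH1 <- dA2 %*% t(par$W2)
  dA1 <- dH1 * lrelu_grad(fw$A1, spec$leaky_slope)
  dX <- dA1 %*% t(par$W1)
  colMeans(dX)
}
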