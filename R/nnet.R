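# Dense feed-forward network engine used by the fragment-count model.
#
# Architecture (fixed shape, sizes configurable): input -> n_relu hidden
# layers (ReLU) -> inverted dropout -> one hidden layer with exponential
# activation -> linear output. Trained with mini-batch Adamax on a mean
# absolute error loss. Everything is plain matrix algebra so the whole
# model is reproducible from a seed with no external runtime.

mlp_init <- function(input_size, output_size, hidden = 500, n_relu = 10,
                     dropout = 0.2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dims <- c(input_size, rep(hidden, n_relu), hidden, output_size)
  n_layers <- length(dims) - 1L
  w <- vector("list", n_layers)
  b <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    fan_in <- dims[i]
    # He initialization for the ReLU stack; small-variance init for the
    # exponential and output layers to keep early activations tame.
    sd0 <- if (i <= n_relu) sqrt(2 / fan_in) else sqrt(0.5 / fan_in)
    w[[i]] <- matrix(rnorm(dims[i] * dims[i + 1], sd = sd0),
                     nrow = dims[i])
    b[[i]] <- rep(0, dims[i + 1])
  }
  list(w = w, b = b, dims = dims, n_relu = n_relu, dropout = dropout)
}

# Forward pass. `training = TRUE` applies inverted dropout after the last
# ReLU layer. Returns the output and, when `keep = TRUE`, the per-layer
# activations needed for backprop.
mlp_forward <- function(net, x, training = FALSE, keep = FALSE) {
  n_layers <- length(net$w)
  exp_layer <- n_layers - 1L
  acts <- if (keep) vector("list", n_layers + 1L) else NULL
  masks <- NULL
  a <- x
  if (keep) acts[[1]] <- a
  for (i in seq_len(n_layers)) {
    z <- sweep(a %*% net$w[[i]], 2, net$b[[i]], "+")
    if (i <= net$n_relu) {
      a <- z * (z > 0)
      if (i == net$n_relu && training && net$dropout > 0) {
        mask <- matrix(runif(length(a)) >= net$dropout, nrow = nrow(a)) /
          (1 - net$dropout)
        a <- a * mask
        masks <- mask
      }
    } else if (i == exp_layer) {
      a <- exp(pmin(z, 30))
    } else {
      a <- z
    }
    if (keep) acts[[i + 1L]] <- a
  }
  list(out = a, acts = acts, mask = masks)
}

# Backward pass for the MAE loss: returns gradients for every weight and
# bias. `fw` is a forward pass run with keep = TRUE.
mlp_backward <- function(net, fw, y) {
  n_layers <- length(net$w)
  exp_layer <- n_layers - 1L
  n <- nrow(y)
  gw <- vector("list", n_layers)
  gb <- vector("list", n_layers)
  delta <- sign(fw$out - y) / (n * ncol(y))
  for (i in rev(seq_len(n_layers))) {
    a_prev <- fw$acts[[i]]
    gw[[i]] <- crossprod(a_prev, delta)
    gb[[i]] <- colSums(delta)
    if (i > 1) {
      delta <- delta %*% t(net$w[[i]])
      a_here <- fw$acts[[i]]
      if ((i - 1L) <= net$n_relu) {
        if ((i - 1L) == net$n_relu && !is.null(fw$mask)) {
          delta <- delta * fw$mask
        }
        delta <- delta * (a_here > 0)
      } else if ((i - 1L) == exp_layer) {
        delta <- delta * a_here # d exp(z)/dz = exp(z)
      }
    }
  }
  list(w = gw, b = gb)
}

adamax_state <- function(net) {
  list(
    mw = lapply(net$w, function(x) x * 0), uw = lapply(net$w, function(x) x * 0),
    mb = lapply(net$b, function(x) x * 0), ub = lapply(net$b, function(x) x * 0),
    t = 0L
  )
}

adamax_step <- function(net, grads, state, lr = 0.001, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr <- lr / (1 - beta1^state$t)
  for (i in seq_along(net$w)) {
    state$mw[[i]] <- beta1 * state$mw[[i]] + (1 - beta1) * grads$w[[i]]
    state$uw[[i]] <- pmax(beta2 * state$uw[[i]], abs(grads$w[[i]]))
    net$w[[i]] <- net$w[[i]] - corr * state$mw[[i]] / (state$uw[[i]] + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$b[[i]]
    state$ub[[i]] <- pmax(beta2 * state$ub[[i]], abs(grads$b[[i]]))
    net$b[[i]] <- net$b[[i]] - corr * state$mb[[i]] / (state$ub[[i]] + eps)
  }
  list(net = net, state = state)
}

mlp_loss_mae <- function(net, x, y) {
  mean(abs(mlp_forward(net, x)$out - y))
}

# Train one network; returns the network and the per-epoch training MAE
# (evaluated on the full training set with dropout off).
mlp_train <- function(net, x, y, epochs, batch_size = 32, lr = 0.001,
                      track_loss = TRUE) {
  n <- nrow(x)
  state <- adamax_state(net)
  losses <- numeric(0)
  for (ep in seq_len(epochs)) {
    idx <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      take <- idx[start:min(start + batch_size - 1L, n)]
      xb <- x[take, , drop = FALSE]
      yb <- y[take, , drop = FALSE]
      fw <- mlp_forward(net, xb, training = TRUE, keep = TRUE)
      if (!all(is.finite(fw$out))) {
        stop("non-finite activations during training (epoch ", ep, "); ",
             "check input scaling")
      }
      grads <- mlp_backward(net, fw, yb)
      upd <- adamax_step(net, grads, state, lr = lr)
      net <- upd$net
      state <- upd$state
    }
    if (track_loss) {
      l <- mlp_loss_mae(net, x, y)
      if (!is.finite(l)) stop("non-finite training loss at epoch ", ep)
      losses <- c(losses, l)
    }
  }
  list(net = net, losses = losses)
}
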