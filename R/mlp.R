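# Minimal feed-forward network engine: dense layers, ReLU / linear /
# softmax activations, Adam optimizer, mini-batches, optional input
# corruption (denoising), optional early stopping on a validation
# carve-out.  Pure matrix code; problem sizes here (n in the thousands,
# widths in the tens) do not warrant compiled kernels.
#
# Conventions: X is n x p; weights[[l]] is d_{l-1} x d_l; the
# activation of the final layer is set by `output` ("linear" for
# reconstruction, "softmax" for classification); all hidden layers are
# ReLU except layers listed in `linear_layers` (bottleneck codes are
# kept linear so their activations form an unconstrained real-valued
# representation).

mlp_new <- function(sizes, output = c("softmax", "linear"),
                    linear_layers = integer(0)) {
  output <- match.arg(output)
  L <- length(sizes) - 1L
  weights <- vector("list", L)
  biases <- vector("list", L)
  for (l in seq_len(L)) {
    # He-style initialization for ReLU stacks
    weights[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1L],
                                 sd = sqrt(2 / sizes[l])),
                           sizes[l], sizes[l + 1L])
    biases[[l]] <- numeric(sizes[l + 1L])
  }
  list(sizes = sizes, weights = weights, biases = biases,
       output = output, linear_layers = as.integer(linear_layers))
}

mlp_act <- function(net, l) {
  L <- length(net$weights)
  if (l == L) net$output
  else if (l %in% net$linear_layers) "linear"
  else "relu"
}

softmax_rows <- function(Z) {
  Z <- Z - Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z)
  E / rowSums(E)
}

# add per-column bias without sweep()'s overhead (Z is column-major)
add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# forward pass; returns list of post-activation matrices (A[[1]] = X)
mlp_forward <- function(net, X) {
  A <- vector("list", length(net$weights) + 1L)
  A[[1L]] <- X
  for (l in seq_along(net$weights)) {
    Z <- add_bias(A[[l]] %*% net$weights[[l]], net$biases[[l]])
    A[[l + 1L]] <- switch(mlp_act(net, l),
                          relu = {Z[Z < 0] <- 0; Z},
                          linear = Z,
                          softmax = softmax_rows(Z))
  }
  A
}

# activations of layer `layer` (1-based over weight layers); used to
# extract bottleneck codes
mlp_layer_output <- function(net, X, layer) {
  mlp_forward(net, X)[[layer + 1L]]
}

# mean loss; Y is the target matrix (one-hot for softmax)
mlp_loss <- function(net, X, Y) {
  out <- mlp_forward(net, X)[[length(net$weights) + 1L]]
  if (net$output == "softmax") {
    -mean(rowSums(Y * log(pmax(out, 1e-12))))
  } else {
    mean((out - Y)^2)
  }
}

# single Adam step on one (possibly corrupted) batch; returns updated
# state = list(net, m, v, t)
mlp_step <- function(state, X, Y, lr) {
  net <- state$net
  L <- length(net$weights)
  A <- mlp_forward(net, X)
  n <- nrow(X)
  # output-layer error signal dLoss/dZ_L
  if (net$output == "softmax") {
    delta <- (A[[L + 1L]] - Y) / n
  } else {
    delta <- 2 * (A[[L + 1L]] - Y) / (n * ncol(Y))
  }
  gW <- vector("list", L)
  gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- delta %*% t(net$weights[[l]])
      if (mlp_act(net, l - 1L) == "relu")
        delta <- delta * (A[[l]] > 0)
    }
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  corr <- sqrt(1 - b2^state$t) / (1 - b1^state$t)
  for (l in seq_len(L)) {
    state$mW[[l]] <- b1 * state$mW[[l]] + (1 - b1) * gW[[l]]
    state$vW[[l]] <- b2 * state$vW[[l]] + (1 - b2) * gW[[l]]^2
    net$weights[[l]] <- net$weights[[l]] -
      lr * corr * state$mW[[l]] / (sqrt(state$vW[[l]]) + eps)
    state$mb[[l]] <- b1 * state$mb[[l]] + (1 - b1) * gb[[l]]
    state$vb[[l]] <- b2 * state$vb[[l]] + (1 - b2) * gb[[l]]^2
    net$biases[[l]] <- net$biases[[l]] -
      lr * corr * state$mb[[l]] / (sqrt(state$vb[[l]]) + eps)
  }
  state$net <- net
  state
}

# Train a network.  All randomness (init, batch order, input
# corruption, validation carve-out) is drawn from the caller's RNG
# stream; wrap in with_seed() for reproducibility.
#
# corrupt_sd > 0 adds fresh Gaussian noise to each input batch while
# targets stay clean (denoising objective).  val_frac > 0 holds out a
# fraction of rows for early stopping with the given patience; the
# best-validation weights are restored.
mlp_train <- function(X, Y, sizes, output, linear_layers = integer(0),
                      epochs = 100L, lr = 0.01, batch_size = 32L,
                      corrupt_sd = 0, val_frac = 0.1, patience = 15L) {
  if (epochs < 1L) config_stop("epochs must be at least 1")
  n <- nrow(X)
  net <- mlp_new(sizes, output, linear_layers)
  state <- list(
    net = net, t = 0L,
    mW = lapply(net$weights, function(w) w * 0),
    vW = lapply(net$weights, function(w) w * 0),
    mb = lapply(net$biases, function(b) b * 0),
    vb = lapply(net$biases, function(b) b * 0))

  n_val <- if (val_frac > 0 && n >= 50L) floor(val_frac * n) else 0L
  if (n_val > 0L) {
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]

  best_val <- Inf; best_net <- state$net; since_best <- 0L
  train_loss <- numeric(epochs)
  for (e in seq_len(epochs)) {
    ord <- sample.int(nrow(Xtr))
    starts <- seq(1L, nrow(Xtr), by = batch_size)
    for (s in starts) {
      idx <- ord[s:min(s + batch_size - 1L, nrow(Xtr))]
      Xb <- Xtr[idx, , drop = FALSE]
      if (corrupt_sd > 0)
        Xb <- Xb + matrix(rnorm(length(Xb), sd = corrupt_sd),
                          nrow(Xb), ncol(Xb))
      state <- mlp_step(state, Xb, Ytr[idx, , drop = FALSE], lr)
    }
    train_loss[e] <- mlp_loss(state$net, Xtr, Ytr)
    if (n_val > 0L) {
      vl <- mlp_loss(state$net, X[val_idx, , drop = FALSE],
                     Y[val_idx, , drop = FALSE])
      if (vl < best_val - 1e-9) {
        best_val <- vl; best_net <- state$net; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= patience) {
          train_loss <- train_loss[seq_len(e)]
          break
        }
      }
    }
  }
  net <- if (n_val > 0L) best_net else state$net
  net$train_loss <- train_loss
  net
}

# one-hot encode a factor into an n x nlevels indicator matrix
one_hot <- function(f) {
  f <- as.factor(f)
  M <- matrix(0, length(f), nlevels(f),
              dimnames = list(NULL, levels(f)))
  M[cbind(seq_along(f), as.integer(f))] <- 1
  M
}
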