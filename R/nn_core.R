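# Minimal seeded neural-network core used by the GCAN autoencoder and the
# pair classifiers. Everything is dense base-R matrix algebra: the data
# sizes this package targets (hundreds of drugs, thousands of pairs) make
# full explicit forward/backward passes both fast and exactly reproducible.

sigmoid <- function(x) 1 / (1 + exp(-x))

# Activation table; derivative is expressed in terms of the activation
# output, which is all the backward pass stores.
act_forward <- function(z, act) {
  switch(act,
    tanh = tanh(z),
    sigmoid = sigmoid(z),
    relu = pmax(z, 0),
    linear = z,
    abort(sprintf("Unknown activation '%s'.", act))
  )
}

act_backward <- function(a, act) {
  switch(act,
    tanh = 1 - a^2,
    sigmoid = a * (1 - a),
    relu = (a > 0) * 1,
    linear = array(1, dim(a)),
    abort(sprintf("Unknown activation '%s'.", act))
  )
}

# Glorot/Xavier uniform initialization (draws from the current RNG stream).
glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Mean per-bit binary cross-entropy and its gradient w.r.t. the logits
# (p - y) / N for sigmoid outputs, with probability clamping for stability.
bce_loss <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# L2 penalty over a flat list of parameter tensors named W* (biases exempt).
l2_penalty <- function(params, l2_rate) {
  if (l2_rate <= 0) return(0)
  l2_rate * sum(vapply(params, function(layer) sum(layer$W^2), numeric(1)))
}

# --- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(layer) {
    list(
      mW = array(0, dim(layer$W)), vW = array(0, dim(layer$W)),
      mb = numeric(length(layer$b)), vb = numeric(length(layer$b)),
      mU = if (!is.null(layer$U)) array(0, dim(layer$U)),
      vU = if (!is.null(layer$U)) array(0, dim(layer$U))
    )
  })
}

adam_step_tensor <- function(theta, g, m, v, lr, t, beta1 = 0.9,
                             beta2 = 0.999, eps = 1e-8) {
  m <- beta1 * m + (1 - beta1) * g
  v <- beta2 * v + (1 - beta2) * g^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

# One Adam update over all layers; L2 regularization enters as a gradient
# contribution 2 * l2 * W on weight matrices only.
adam_update <- function(params, grads, state, lr, t, l2_rate = 0) {
  for (i in seq_along(params)) {
    gW <- grads[[i]]$W + 2 * l2_rate * params[[i]]$W
    s <- adam_step_tensor(params[[i]]$W, gW, state[[i]]$mW, state[[i]]$vW, lr, t)
    params[[i]]$W <- s$theta; state[[i]]$mW <- s$m; state[[i]]$vW <- s$v
    s <- adam_step_tensor(params[[i]]$b, grads[[i]]$b, state[[i]]$mb,
                          state[[i]]$vb, lr, t)
    params[[i]]$b <- s$theta; state[[i]]$mb <- s$m; state[[i]]$vb <- s$v
    if (!is.null(params[[i]]$U)) {
      gU <- grads[[i]]$U + 2 * l2_rate * params[[i]]$U
      s <- adam_step_tensor(params[[i]]$U, gU, state[[i]]$mU, state[[i]]$vU, lr, t)
      params[[i]]$U <- s$theta; state[[i]]$mU <- s$m; state[[i]]$vU <- s$v
    }
  }
  list(params = params, state = state)
}

# --- (graph-)MLP forward / backward ---------------------------------------

# Forward pass through a stack of dense layers, each optionally preceded by
# a fixed graph propagation H <- A %*% H (A row-stochastic). Inverted
# dropout with the given masks is applied to the *output* of every layer
# except the last. Returns activations needed for the backward pass.
mlp_forward <- function(params, X, A = NULL, dropout_masks = NULL) {
  n_layers <- length(params)
  inputs <- vector("list", n_layers)   # post-graph input M_l = A H_{l-1}
  outputs <- vector("list", n_layers)  # post-activation (pre-dropout)
  H <- X
  for (l in seq_len(n_layers)) {
    M <- if (is.null(A)) H else A %*% H
    inputs[[l]] <- M
    Z <- sweep(M %*% params[[l]]$W, 2, params[[l]]$b, "+")
    Aout <- act_forward(Z, params[[l]]$act)
    outputs[[l]] <- Aout
    H <- Aout
    if (l < n_layers && !is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
      H <- H * dropout_masks[[l]]
    }
  }
  list(inputs = inputs, outputs = outputs, final = H)
}

# Backward pass matching mlp_forward; dTop is dLoss/dOutput of the last
# layer's activation. Returns per-layer gradients and dLoss/dX.
mlp_backward <- function(params, cache, dTop, A = NULL, dropout_masks = NULL) {
  n_layers <- length(params)
  grads <- vector("list", n_layers)
  dH <- dTop
  for (l in rev(seq_len(n_layers))) {
    if (l < n_layers && !is.null(dropout_masks) && !is.null(dropout_masks[[l]])) {
      dH <- dH * dropout_masks[[l]]
    }
    dZ <- dH * act_backward(cache$outputs[[l]], params[[l]]$act)
    grads[[l]] <- list(
      W = crossprod(cache$inputs[[l]], dZ),
      b = colSums(dZ)
    )
    dM <- tcrossprod(dZ, params[[l]]$W)
    dH <- if (is.null(A)) dM else crossprod(A, dM)
  }
  list(grads = grads, dX = dH)
}

# Sigmoid-BCE shortcut: for p = sigmoid(z), dLoss/dz = (p - y) / length(y).
# mlp_backward expects dLoss/dActivation, so divide out the sigmoid
# derivative (guarded away from 0).
bce_dtop <- function(p, y) {
  dZ <- (p - y) / length(y)
  dact <- pmax(p * (1 - p), 1e-12)
  dZ / dact
}

# Fresh inverted-dropout masks for hidden layers (NULL when rate is 0 or at
# inference). Draws from the current RNG stream.
dropout_masks_for <- function(dims, rate) {
  if (rate <= 0) return(NULL)
  lapply(dims, function(d) {
    matrix((runif(prod(d)) >= rate) / (1 - rate), d[1], d[2])
  })
}
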