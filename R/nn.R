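# Minimal feed-forward network engine: linear layers, optional batch
# normalization, ReLU/sigmoid/linear outputs, with explicit forward caches and
# hand-derived backward passes. Matrices are cells x features throughout, so
# every heavy operation is a BLAS matmul.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

# Internally activations are held feature-major (features x cells): R recycles
# a length-d vector down the columns of a d x n matrix, so every per-feature
# batchnorm/bias broadcast is a single fused vector op with no intermediate
# allocation. The public matrices stay cells x features; mlp_forward /
# mlp_backward / mlp_infer transpose once at their boundaries.

# He-normal initialization; consumes the current RNG stream.
nn_layer_init <- function(n_in, n_out, batchnorm, activation) {
  list(
    W = matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out),
    b = rep(0, n_out),
    bn = if (batchnorm) {
      list(gamma = rep(1, n_out), beta = rep(0, n_out),
           rmean = rep(0, n_out), rvar = rep(1, n_out))
    },
    act = activation
  )
}

# dims = c(n_in, hidden..., n_out). Hidden layers get `hidden_act` (+ BN when
# requested); the output layer gets `out_act` and never BN.
mlp_init <- function(dims, batchnorm = FALSE, hidden_act = "relu",
                     out_act = "linear", bn_out = FALSE) {
  n_layers <- length(dims) - 1
  layers <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    last <- i == n_layers
    layers[[i]] <- nn_layer_init(
      dims[i], dims[i + 1],
      batchnorm = batchnorm && (!last || bn_out),
      activation = if (last && !bn_out) out_act else hidden_act
    )
  }
  structure(list(layers = layers, dims = dims), class = "mlp")
}

apply_act <- function(a, act) {
  switch(act,
         relu = a * (a > 0),
         sigmoid = 1 / (1 + exp(-a)),
         linear = a,
         stop("unknown activation: ", act))
}

# Forward pass. In training mode batch statistics are used for BN and running
# statistics are updated (the updated network is returned in $net); in eval
# mode the stored running statistics make the pass deterministic.
mlp_forward_fm <- function(net, H, training = FALSE) {
  r <- cpp_mlp_forward_fm(net$layers, H, training)
  if (training) {
    for (i in seq_along(net$layers)) {
      st <- r$rstats[[i]]
      if (!is.null(st)) {
        net$layers[[i]]$bn$rmean <- st$rmean
        net$layers[[i]]$bn$rvar <- st$rvar
      }
    }
  }
  list(out = r$out, caches = r$caches, net = net)
}

mlp_forward <- function(net, X, training = FALSE) {
  r <- mlp_forward_fm(net, t(X), training)
  r$out <- t(r$out)
  r
}

# Backward pass: dOut is the loss gradient w.r.t. the forward output. Returns
# the gradient w.r.t. the input X and per-layer parameter gradients.
mlp_backward_fm <- function(net, caches, dH) {
  cpp_mlp_backward_fm(net$layers, caches, dH)
}

mlp_backward <- function(net, caches, dOut) {
  r <- mlp_backward_fm(net, caches, t(dOut))
  r$dX <- t(r$dX)
  r
}

# Inference-only forward: no caches, eval-mode BN folded into a single affine
# transform per layer. Used for prediction and for scoring VAT candidate
# perturbations, where no gradients are needed.
mlp_infer_fm <- function(net, H) {
  cpp_mlp_infer_fm(net$layers, H)
}

mlp_infer <- function(net, X) {
  t(mlp_infer_fm(net, t(X)))
}

# --- gradient bookkeeping -------------------------------------------------

grads_zero <- function(net) {
  lapply(net$layers, function(ly) {
    list(W = matrix(0, nrow(ly$W), ncol(ly$W)), b = rep(0, length(ly$b)),
         gamma = if (!is.null(ly$bn)) rep(0, length(ly$bn$gamma)),
         beta = if (!is.null(ly$bn)) rep(0, length(ly$bn$beta)))
  })
}

grads_add <- function(acc, g, scale = 1) {
  if (is.null(acc)) return(g)
  for (i in seq_along(acc)) {
    if (is.null(g[[i]])) next
    acc[[i]]$W <- acc[[i]]$W + scale * g[[i]]$W
    acc[[i]]$b <- acc[[i]]$b + scale * g[[i]]$b
    if (!is.null(acc[[i]]$gamma)) {
      acc[[i]]$gamma <- acc[[i]]$gamma + scale * g[[i]]$gamma
      acc[[i]]$beta <- acc[[i]]$beta + scale * g[[i]]$beta
    }
  }
  acc
}

# SGD with momentum and decoupled-from-nothing L2 weight decay, matching the
# common torch formulation: v <- mu*v + (grad + wd*param); param <- param - lr*v.
# Weight decay applies to linear weights only (not biases or BN parameters).
sgd_state_init <- function(net) {
  lapply(net$layers, function(ly) {
    list(W = matrix(0, nrow(ly$W), ncol(ly$W)), b = rep(0, length(ly$b)),
         gamma = if (!is.null(ly$bn)) rep(0, length(ly$bn$gamma)),
         beta = if (!is.null(ly$bn)) rep(0, length(ly$bn$beta)))
  })
}

sgd_step <- function(net, grads, state, lr, momentum, weight_decay) {
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    g <- grads[[i]]
    st <- state[[i]]
    st$W <- momentum * st$W + (g$W + weight_decay * ly$W)
    ly$W <- ly$W - lr * st$W
    st$b <- momentum * st$b + g$b
    ly$b <- ly$b - lr * st$b
    if (!is.null(ly$bn)) {
      st$gamma <- momentum * st$gamma + g$gamma
      ly$bn$gamma <- ly$bn$gamma - lr * st$gamma
      st$beta <- momentum * st$beta + g$beta
      ly$bn$beta <- ly$bn$beta - lr * st$beta
    }
    net$layers[[i]] <- ly
    state[[i]] <- st
  }
  list(net = net, state = state)
}

# Flatten / restore trainable parameters (used by finite-difference tests).
mlp_get_params <- function(net) {
  unlist(lapply(net$layers, function(ly) {
    c(as.numeric(ly$W), ly$b,
      if (!is.null(ly$bn)) c(ly$bn$gamma, ly$bn$beta))
  }))
}

mlp_set_params <- function(net, theta) {
  pos <- 0L
  take <- function(n) {
    out <- theta[(pos + 1L):(pos + n)]
    pos <<- pos + n
    out
  }
  for (i in seq_along(net$layers)) {
    ly <- net$layers[[i]]
    nw <- length(ly$W)
    ly$W <- matrix(take(nw), nrow(ly$W), ncol(ly$W))
    ly$b <- take(length(ly$b))
    if (!is.null(ly$bn)) {
      ly$bn$gamma <- take(length(ly$bn$gamma))
      ly$bn$beta <- take(length(ly$bn$beta))
    }
    net$layers[[i]] <- ly
  }
  stopifnot(pos == length(theta))
  net
}

mlp_flatten_grads <- function(net, grads) {
  unlist(lapply(seq_along(grads), function(i) {
    g <- grads[[i]]
    c(as.numeric(g$W), g$b,
      if (!is.null(net$layers[[i]]$bn)) c(g$gamma, g$beta))
  }))
}

softmax_rows <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# column-wise softmax for feature-major (classes x cells) logits
softmax_cols <- function(logits) {
  mx <- logits[1, ]
  for (r in seq_len(nrow(logits))[-1]) mx <- pmax(mx, logits[r, ])
  e <- exp(logits - rep(mx, each = nrow(logits)))
  e / rep(.colSums(e, nrow(e), ncol(e)), each = nrow(logits))
}

# column-wise KL divergence sum_c p log(p/q) for classes x cells matrices
kl_cols <- function(p, q) {
  p <- pmax(p, 1e-12)
  q <- pmax(q, 1e-12)
  .colSums(p * (log(p) - log(q)), nrow(p), ncol(p))
}
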