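# Minimal fully connected network with manual backprop and Adam, on BLAS
# matrix ops. Layers: affine + ReLU on all but the last (linear) layer.
# Shared by the contrastive encoder and the classification head.

mlp_init <- function(sizes) {
  layers <- vector("list", length(sizes) - 1L)
  for (i in seq_along(layers)) {
    fan_in <- sizes[i]
    layers[[i]] <- list(
      W = matrix(stats::rnorm(fan_in * sizes[i + 1L], sd = sqrt(2 / fan_in)),
                 fan_in, sizes[i + 1L]),
      b = rep(0, sizes[i + 1L])
    )
  }
  structure(list(layers = layers, sizes = sizes), class = "mlp")
}

mlp_stack <- function(a, b) {
  structure(list(layers = c(a$layers, b$layers),
                 sizes = c(a$sizes, b$sizes[-1L])), class = "mlp")
}

# forward pass; returns output and per-layer activations for backprop
mlp_forward <- function(net, X) {
  acts <- vector("list", length(net$layers) + 1L)
  acts[[1L]] <- X
  nl <- length(net$layers)
  for (i in seq_len(nl)) {
    Z <- sweep(acts[[i]] %*% net$layers[[i]]$W, 2, net$layers[[i]]$b, `+`)
    acts[[i + 1L]] <- if (i < nl) pmax(Z, 0) else Z
  }
  list(out = acts[[nl + 1L]], acts = acts)
}

# backprop from the gradient w.r.t. the network output
mlp_backward <- function(net, acts, G) {
  nl <- length(net$layers)
  grads <- vector("list", nl)
  for (i in rev(seq_len(nl))) {
    if (i < nl) G <- G * (acts[[i + 1L]] > 0)
    grads[[i]] <- list(W = crossprod(acts[[i]], G), b = colSums(G))
    if (i > 1L) G <- G %*% t(net$layers[[i]]$W)
  }
  grads
}

adam_init <- function(net) {
  lapply(net$layers, function(l) list(
    mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(net, grads, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (i in seq_along(net$layers)) {
    s <- state[[i]]; g <- grads[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    # decoupled (AdamW-style) weight decay on weights only
    net$layers[[i]]$W <- net$layers[[i]]$W -
      lr * ((s$mW / bc1) / (sqrt(s$vW / bc2) + eps) +
              weight_decay * net$layers[[i]]$W)
    net$layers[[i]]$b <- net$layers[[i]]$b -
      lr * (s$mb / bc1) / (sqrt(s$vb / bc2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# rows to unit L2 norm, with gradient helper
l2_normalize <- function(Z) {
  nrm <- sqrt(rowSums(Z^2)) + 1e-12
  list(U = Z / nrm, nrm = nrm)
}
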