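# Minimal dense neural-network machinery: fully connected layers with ReLU
# hidden activations, inverted dropout, manual backpropagation and Adam.
# Kept deliberately small -- the set encoder only needs multilayer
# perceptrons operating on row-batched matrices.

mlp_init <- function(dims) {
  # dims: c(in, h1, ..., out); uniform fan-in scaling (U[-1/sqrt(fan), 1/sqrt(fan)])
  layers <- vector("list", length(dims) - 1L)
  for (k in seq_along(layers)) {
    fan <- dims[k]
    lim <- 1 / sqrt(fan)
    layers[[k]] <- list(
      W = matrix(stats::runif(fan * dims[k + 1L], -lim, lim), fan, dims[k + 1L]),
      b = stats::runif(dims[k + 1L], -lim, lim)
    )
  }
  layers
}

# Forward pass on a row-batch X (n x in). ReLU after every layer except the
# last (linear output); dropout applied to hidden activations when training.
mlp_forward <- function(layers, X, dropout = 0, training = FALSE) {
  caches <- vector("list", length(layers))
  H <- X
  nl <- length(layers)
  for (k in seq_len(nl)) {
    Z <- H %*% layers[[k]]$W
    Z <- Z + rep(layers[[k]]$b, each = nrow(Z))
    cache <- list(X = H)
    if (k < nl) {
      mask <- Z > 0
      A <- Z * mask
      cache$relu <- mask
      if (training && dropout > 0) {
        keep <- matrix(stats::runif(length(A)) >= dropout, nrow(A), ncol(A))
        A <- A * keep / (1 - dropout)
        cache$drop <- keep / (1 - dropout)
      }
      H <- A
    } else {
      H <- Z
    }
    caches[[k]] <- cache
  }
  list(out = H, caches = caches)
}

# Backward pass; dOut is the gradient at the (linear) output.
# Returns gradient w.r.t. the input batch and per-layer parameter grads.
mlp_backward <- function(layers, caches, dOut) {
  nl <- length(layers)
  grads <- vector("list", nl)
  dH <- dOut
  for (k in rev(seq_len(nl))) {
    cache <- caches[[k]]
    if (k < nl) {
      if (!is.null(cache$drop)) dH <- dH * cache$drop
      dH <- dH * cache$relu
    }
    grads[[k]] <- list(W = crossprod(cache$X, dH), b = colSums(dH))
    dH <- tcrossprod(dH, layers[[k]]$W)
  }
  list(dX = dH, grads = grads)
}

# ---- parameter-tree utilities (params are nested lists of numeric arrays) --

tree_map <- function(f, a) {
  if (is.list(a)) lapply(a, function(x) tree_map(f, x)) else f(a)
}

tree_map2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (k in seq_along(a)) out[[k]] <- tree_map2(f, a[[k]], b[[k]])
    out
  } else f(a, b)
}

tree_zeros <- function(a) tree_map(function(x) x * 0, a)

adam_init <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g * g, state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- tree_map2(function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps),
                   state$m, state$v)
  params <- tree_map2(`-`, params, upd)
  list(params = params, state = state)
}

clamp_prob <- function(p, eps = 1e-7) pmin(pmax(p, eps), 1 - eps)

bce <- function(p, y, eps = 1e-7) {
  p <- clamp_prob(p, eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}
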