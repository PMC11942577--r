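# Minimal dense-network engine used by the transfer models.
#
# A network is a list of layers; each layer is list(W, b, act) with W of
# shape (in x out) and act one of "relu", "sigmoid", "linear", "softmax".
# Forward passes cache pre-activation inputs so gradients can be pushed
# back through arbitrary compositions (needed for the gradient reversal
# layer, the staged freezing protocol and integrated gradients).
# All heavy lifting is BLAS matrix products; batches are rows.

nnLayer <- function(nIn, nOut, act) {
  # Uniform init scaled by fan-in; caller controls the RNG stream.
  a <- 1 / sqrt(nIn)
  list(W = matrix(runif(nIn * nOut, -a, a), nIn, nOut),
       b = numeric(nOut), act = act)
}

# dims: c(n_in, hidden..., n_out); acts: activation per non-input layer
nnInit <- function(dims, acts, seed = NULL) {
  stopifnot(length(acts) == length(dims) - 1L)
  build <- function() {
    lapply(seq_along(acts), function(i) nnLayer(dims[i], dims[i + 1], acts[i]))
  }
  if (is.null(seed)) build() else withSeed(seed, build())
}

nnActivate <- function(z, act) {
  switch(act,
    relu = pmax(z, 0),
    sigmoid = 1 / (1 + exp(-z)),
    linear = z,
    softmax = {
      e <- exp(z - apply(z, 1, max))
      e / rowSums(e)
    },
    stopf("unknown activation '%s'", act))
}

# Returns list(out, cache); cache holds per-layer inputs and activations.
nnForward <- function(net, X, cache = TRUE) {
  X <- as.matrix(X)
  caches <- if (cache) vector("list", length(net))
  a <- X
  for (i in seq_along(net)) {
    ly <- net[[i]]
    if (ncol(a) != nrow(ly$W)) {
      stopf("layer %d expects %d inputs, got %d", i, nrow(ly$W), ncol(a))
    }
    z <- a %*% ly$W
    z <- sweep(z, 2, ly$b, "+")
    out <- nnActivate(z, ly$act)
    if (cache) caches[[i]] <- list(input = a, out = out)
    a <- out
  }
  if (cache) list(out = a, cache = caches) else list(out = a)
}

# gradOut: d loss / d output (post-activation), except for softmax layers
# where gradOut must already be d loss / d logits (softmax is only ever the
# final discriminator layer, paired with cross-entropy).
# Returns list(grads = per-layer list(dW, db), gradIn = d loss / d input).
nnBackward <- function(net, cache, gradOut) {
  grads <- vector("list", length(net))
  g <- as.matrix(gradOut)
  for (i in rev(seq_along(net))) {
    ly <- net[[i]]
    cc <- cache[[i]]
    dz <- switch(ly$act,
      relu = g * (cc$out > 0),
      sigmoid = g * cc$out * (1 - cc$out),
      linear = g,
      softmax = g,  # caller supplies logit-space gradient
      stopf("unknown activation '%s'", ly$act))
    grads[[i]] <- list(dW = crossprod(cc$input, dz), db = colSums(dz))
    g <- dz %*% t(ly$W)
  }
  list(grads = grads, gradIn = g)
}

# Adam optimizer state mirrors the network structure.
adamInit <- function(net) {
  lapply(net, function(ly) list(
    mW = ly$W * 0, vW = ly$W * 0,
    mb = ly$b * 0, vb = ly$b * 0))
}

adamStep <- function(net, grads, state, lr, t,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  c1 <- 1 - beta1^t
  c2 <- 1 - beta2^t
  for (i in seq_along(net)) {
    g <- grads[[i]]
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$dW
    s$vW <- beta2 * s$vW + (1 - beta2) * g$dW^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$db
    s$vb <- beta2 * s$vb + (1 - beta2) * g$db^2
    net[[i]]$W <- net[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    net[[i]]$b <- net[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(net = net, state = state)
}

# Scale gradients elementwise (used to zero or reverse branch contributions).
nnZeroGrads <- function(grads) {
  lapply(grads, function(g) list(dW = g$dW * 0, db = g$db * 0))
}
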