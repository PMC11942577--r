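#' Layer-wise pretraining of a stacked autoencoder
#'
#' Trains one autoencoder per encoder layer: the first reconstructs the
#' (min-max scaled) expression input through a `input -> h -> input`
#' bottleneck, each subsequent one reconstructs the previous layer's codes,
#' and the full stack is then fine-tuned end to end. Hidden activations are
#' ReLU; the final reconstruction layer is sigmoid because inputs live in
#' `[0, 1]`. Reconstruction loss is mean squared error. Only source-domain
#' data should be supplied in the transfer setting, so the target test
#' domain stays untouched during unsupervised pretraining.
#'
#' @param X numeric matrix (samples x features), scaled to `[0, 1]`.
#' @param config an [SAEConfig-class].
#' @return an [SAEModel-class] with per-layer and fine-tuning loss history.
#' @export
pretrainLayerwise <- function(X, config = SAEConfig()) {
  X <- unname(as.matrix(X))
  validObject(config)
  dims <- config@layerDims
  if (dims[1] >= ncol(X)) {
    # allowed, but the stack should compress; only strictly-decreasing
    # hidden dims are enforced by the config validity
  }
  codes <- X
  encoder <- vector("list", length(dims))
  decoder <- vector("list", length(dims))
  layerLoss <- vector("list", length(dims))

  for (l in seq_along(dims)) {
    nIn <- ncol(codes)
    decAct <- if (l == 1L) "sigmoid" else "relu"
    enc <- nnInit(c(nIn, dims[l]), "relu",
                  seed = deriveSeed(config@seed, "sae_enc_init", l))
    dec <- nnInit(c(dims[l], nIn), decAct,
                  seed = deriveSeed(config@seed, "sae_dec_init", l))
    ae <- c(enc, dec)
    st <- adamInit(ae)
    t <- 0L
    losses <- numeric(config@epochsPerLayer)
    n <- nrow(codes)
    for (ep in seq_len(config@epochsPerLayer)) {
      perm <- withSeed(deriveSeed(config@seed, "sae_shuffle", l, ep),
                       sample.int(n))
      epLoss <- 0
      nb <- 0L
      for (start in seq(1, n, by = config@batchSize)) {
        idx <- perm[start:min(start + config@batchSize - 1L, n)]
        B <- codes[idx, , drop = FALSE]
        fw <- nnForward(ae, B)
        resid <- fw$out - B
        loss <- mean(resid^2)
        if (!is.finite(loss)) stopf("non-finite reconstruction loss (layer %d)", l)
        bw <- nnBackward(ae, fw$cache, 2 * resid / length(resid))
        t <- t + 1L
        upd <- adamStep(ae, bw$grads, st, config@learningRate, t)
        ae <- upd$net
        st <- upd$state
        epLoss <- epLoss + loss
        nb <- nb + 1L
      }
      losses[ep] <- epLoss / nb
    }
    encoder[[l]] <- ae[[1]]
    decoder[[l]] <- ae[[2]]
    layerLoss[[l]] <- losses
    codes <- nnForward(list(ae[[1]]), codes, cache = FALSE)$out
  }

  # end-to-end fine-tune of the full stack (untied weights)
  stack <- c(encoder, rev(decoder))
  stackedLoss <- mean((nnForward(stack, X, cache = FALSE)$out - X)^2)
  st <- adamInit(stack)
  t <- 0L
  ftLoss <- numeric(config@finetuneEpochs)
  n <- nrow(X)
  for (ep in seq_len(config@finetuneEpochs)) {
    perm <- withSeed(deriveSeed(config@seed, "sae_finetune", ep), sample.int(n))
    epLoss <- 0
    nb <- 0L
    for (start in seq(1, n, by = config@batchSize)) {
      idx <- perm[start:min(start + config@batchSize - 1L, n)]
      B <- X[idx, , drop = FALSE]
      fw <- nnForward(stack, B)
      resid <- fw$out - B
      loss <- mean(resid^2)
      if (!is.finite(loss)) stopf("non-finite loss during SAE fine-tuning")
      bw <- nnBackward(stack, fw$cache, 2 * resid / length(resid))
      t <- t + 1L
      upd <- adamStep(stack, bw$grads, st, config@learningRate, t)
      stack <- upd$net
      st <- upd$state
      epLoss <- epLoss + loss
      nb <- nb + 1L
    }
    ftLoss[ep] <- epLoss / nb
  }
  L <- length(dims)
  # decoder slot is stored in decoding order (bottleneck -> input)
  new("SAEModel",
      encoder = stack[seq_len(L)],
      decoder = stack[L + seq_len(L)],
      inputDim = ncol(X),
      lossHistory = list(layerwise = layerLoss,
                         stackedBeforeFinetune = stackedLoss,
                         finetune = ftLoss))
}

#' Encode data with a trained stacked autoencoder
#'
#' @param model an [SAEModel-class].
#' @param X matrix with `inputDim` columns.
#' @return low-dimensional codes (samples x bottleneck width).
#' @export
saeEncode <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim) {
    stopf("input has %d features but the autoencoder expects %d",
          ncol(X), model@inputDim)
  }
  nnForward(model@encoder, X, cache = FALSE)$out
}

#' Reconstruct data with a trained stacked autoencoder
#'
#' @inheritParams saeEncode
#' @return reconstruction of `X` (same shape).
#' @export
saeReconstruct <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model@inputDim) {
    stopf("input has %d features but the autoencoder expects %d",
          ncol(X), model@inputDim)
  }
  nnForward(c(model@encoder, model@decoder), X, cache = FALSE)$out
}

#' Export the encoder as an initialization bundle
#'
#' The bundle initializes the gene feature extractor of the transfer models,
#' carrying the layer weights over bitwise.
#'
#' @param model a trained [SAEModel-class].
#' @return list with `layers` (dense layers) and `inputDim`.
#' @export
exportEncoder <- function(model) {
  stopifnot(is(model, "SAEModel"))
  list(layers = model@encoder, inputDim = model@inputDim)
}
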